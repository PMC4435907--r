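# shared fixtures, all generated in code

# moderate-information random PFM used for scan calibration: chosen so
# the discrete score lattice has an attainable tail probability within
# 0.01% of the 5e-7 operating threshold under a uniform background
calibration_pfm <- function() {
  set.seed(22)
  counts <- matrix(rgamma(4 * 20, 4), nrow = 4)
  counts <- round(counts / rep(colSums(counts), each = 4) * 100) + 1
  pfm(counts)
}

# small random PFM on a given seed (for DP-vs-enumeration oracles)
random_pfm <- function(seed, width) {
  set.seed(seed)
  pfm(matrix(runif(4 * width, 1, 60), nrow = 4))
}

random_dna <- function(n, seed, prob = rep(0.25, 4)) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# a hand-built 3-exon gene: + strand, exons [1000,1200) [1500,1700)
# [2000,2300)
three_exon_gene <- function(strand = "+") {
  gene_model("g1", "chr1", strand,
             exons = rbind(c(1000, 1200), c(1500, 1700), c(2000, 2300)),
             cds = rbind(c(1100, 1200), c(1500, 1700), c(2000, 2200)),
             utr5 = if (strand == "+") rbind(c(1000, 1100)) else
               rbind(c(2200, 2300)),
             utr3 = if (strand == "+") rbind(c(2200, 2300)) else
               rbind(c(1000, 1100)))
}

# unit-height pure-birth tree with n tips
unit_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length /
    max(ape::node.depth.edgelength(tr))
  tr
}

# independent transition-probability matrix via series expm (Matrix pkg)
expm_pmat <- function(Q, t) {
  as.matrix(Matrix::expm(Q * t))
}

# brute-force per-pattern likelihood for the rooted 3-taxon tree
# ((A:ta,B:tb):tab,C:tc); explicit double loop over ancestral states
brute_loglik_3taxa <- function(aln, ta, tb, tab, tc, kappa, omega, pi) {
  Q <- gy94_rate_matrix(kappa, omega, pi)$Q
  PA <- expm_pmat(Q, ta); PB <- expm_pmat(Q, tb)
  PAB <- expm_pmat(Q, tab); PC <- expm_pmat(Q, tc)
  idx <- function(s, i) match(substring(s, 3 * i - 2, 3 * i),
                              hibtarget:::SENSE_CODONS)
  ncod <- nchar(aln[[1]]) / 3
  total <- 0
  for (i in seq_len(ncod)) {
    a <- idx(aln[["A"]], i); b <- idx(aln[["B"]], i); c <- idx(aln[["C"]], i)
    lik <- 0
    for (root in 1:61) {
      inner <- 0
      for (anc in 1:61) {
        inner <- inner + PAB[root, anc] * PA[anc, a] * PB[anc, b]
      }
      lik <- lik + pi[root] * inner * PC[root, c]
    }
    total <- total + log(lik)
  }
  unname(total)
}
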