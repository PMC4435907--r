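uniform_pi <- function() {
  setNames(rep(1 / 61, 61), hibtarget:::SENSE_CODONS)
}

test_that("GY94 generator is reversible, zero-row-sum and unit-scaled", {
  pi <- codon_frequencies(c(a = strrep("ATGGCCAAATTTCCC", 10)))
  qq <- gy94_rate_matrix(kappa = 3, omega = 0.4, pi = pi)
  expect_lt(max(abs(rowSums(qq$Q))), 1e-12)
  expect_lt(max(abs(pi * qq$Q - t(pi * qq$Q))), 1e-15)
  expect_equal(-sum(pi * diag(qq$Q)), 1, tolerance = 1e-12)
  expect_equal(qq$rho_n + qq$rho_s, 1, tolerance = 1e-12)
  # omega = kappa = 1, uniform frequencies: all single-change rates equal
  qq1 <- gy94_rate_matrix(1, 1, uniform_pi())
  offdiag <- qq1$Q[hibtarget:::.codon_pair_structure$single]
  expect_lt(diff(range(offdiag)), 1e-14)
  # transition matrices are stochastic
  for (t in c(0.01, 0.1, 1)) {
    P <- expm_pmat(qq$Q, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_true(all(P > -1e-12))
  }
})

test_that("a single informative sequence gives the stationary density", {
  # second taxon fully gapped = missing: the likelihood collapses to
  # the root prior over the remaining sequence's codons
  tr <- ape::read.tree(text = "(A:0.1,B:0.2);")
  pi <- codon_frequencies(c(x = strrep("ATGGCCAAA", 5)))
  ll <- codon_loglik(tr, c(A = "ATGGCCAAA", B = "---------"),
                     list(kappa = 2, omega = 0.5, pi = pi))
  idx <- match(c("ATG", "GCC", "AAA"), hibtarget:::SENSE_CODONS)
  expect_equal(ll, sum(log(pi[idx])), tolerance = 1e-10)
})

test_that("two-taxon pruning matches the direct pairwise sum", {
  tr <- ape::read.tree(text = "(A:0.15,B:0.25);")
  sim <- simulate_codon_alignment(tr, list(kappa = 2.5, omega = 0.3),
                                  n_codons = 30, seed = 8)
  pi <- codon_frequencies(sim$aln)
  ll <- codon_loglik(tr, sim$aln, list(kappa = 2.5, omega = 0.3, pi = pi))
  Q <- gy94_rate_matrix(2.5, 0.3, pi)$Q
  P <- expm_pmat(Q, 0.4)  # reversibility collapses both branches
  idx <- function(s, i) match(substring(s, 3 * i - 2, 3 * i),
                              hibtarget:::SENSE_CODONS)
  oracle <- 0
  for (i in 1:30) {
    a <- idx(sim$aln[["A"]], i); b <- idx(sim$aln[["B"]], i)
    oracle <- oracle + log(pi[a] * P[a, b])
  }
  expect_equal(ll, unname(oracle), tolerance = 1e-8)
})

test_that("three-taxon pruning equals brute-force ancestral summation", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,C:0.3);")
  sim <- simulate_codon_alignment(tr, list(kappa = 2, omega = 0.3),
                                  n_codons = 15, seed = 3)
  pi <- codon_frequencies(sim$aln)
  ll <- codon_loglik(tr, sim$aln, list(kappa = 2, omega = 0.3, pi = pi))
  brute <- brute_loglik_3taxa(sim$aln, 0.1, 0.2, 0.15, 0.3,
                              kappa = 2, omega = 0.3, pi = pi)
  expect_equal(ll, brute, tolerance = 1e-8)
})

test_that("likelihood is invariant to re-rooting (reversible model)", {
  tr <- unit_tree(4, 9)
  sim <- simulate_codon_alignment(tr, list(kappa = 2, omega = 0.4),
                                  n_codons = 40, seed = 2)
  pi <- codon_frequencies(sim$aln)
  params <- list(kappa = 2, omega = 0.4, pi = pi)
  ll1 <- codon_loglik(tr, sim$aln, params)
  tr2 <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[3],
                   resolve.root = TRUE)
  ll2 <- codon_loglik(tr2, sim$aln, params)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("gapped codons act as missing data", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.2);")
  aln_gap <- c(A = "ATG---", B = "ATGGCC")
  pi <- uniform_pi()
  params <- list(kappa = 2, omega = 1, pi = pi)
  llg <- codon_loglik(tr, aln_gap, params)
  # the gapped column marginalizes to the stationary probability of B's
  # codon; the ungapped column is the usual pair term
  ll_pair <- codon_loglik(tr, c(A = "ATG", B = "ATG"), params)
  idx <- match("GCC", hibtarget:::SENSE_CODONS)
  expect_equal(llg, ll_pair + log(pi[[idx]]), tolerance = 1e-8)
})

test_that("nested models respect the likelihood ordering", {
  tr <- unit_tree(6, 4)
  tr$edge.length <- tr$edge.length * 0.4
  sim <- simulate_codon_alignment(tr, list(kappa = 2, omega = 0.3),
                                  n_codons = 120, seed = 6)
  f1 <- fit_branch_model(tr, sim$aln, "fixed_omega1")
  f0 <- fit_branch_model(tr, sim$aln, "one_ratio", init = f1)
  expect_gte(f0$lnL, f1$lnL - 1e-6)
  expect_equal(f1$np, f0$np - 1)
  ff <- suppressWarnings(
    fit_branch_model(tr, sim$aln, "free_ratio", init = f0,
                     max_rounds = 12))
  expect_gte(ff$lnL, f0$lnL - 1e-6)
  # branch table bookkeeping: expected substitution counts are positive
  # and split into nonsynonymous + synonymous parts
  bt <- f0$branch_table
  expect_true(all(bt$NdN >= 0) && all(bt$SdS >= 0))
  expect_equal(bt$NdN + bt$SdS, bt$length * f0$n_codons,
               tolerance = 1e-9)
})

test_that("two-ratio model separates labeled foreground branches", {
  tr <- unit_tree(6, 12)
  tr$edge.length <- tr$edge.length * 0.3
  lt <- labeled_tree(tr, edge_class = as.integer(
    seq_len(nrow(tr$edge)) <= 2))
  sim <- simulate_codon_alignment(
    lt, list(kappa = 2, omega = c(`0` = 0.6, `1` = 0.05)),
    n_codons = 200, seed = 10)
  fit <- fit_branch_model(lt, sim$aln, "two_ratio")
  expect_equal(sort(names(fit$omega)), c("0", "1"))
  expect_lt(fit$omega[["1"]], fit$omega[["0"]])
  expect_equal(fit$np, nrow(tr$edge) + 1 + 2)
  expect_error(fit_branch_model(tr, sim$aln, "two_ratio"), "labeled")
})

test_that("CODEML-style #1 tags are parsed from newick labels", {
  lt <- labeled_tree("((A#1:0.1,B:0.2)anc#2:0.1,C:0.3);")
  expect_equal(sum(lt$edge_class == 1), 1)
  expect_equal(sum(lt$edge_class == 2), 1)
  expect_true(all(lt$tree$tip.label %in% c("A", "B", "C")))
  tipA_edge <- which(lt$tree$edge[, 2] ==
                       which(lt$tree$tip.label == "A"))
  expect_equal(lt$edge_class[tipA_edge], 1L)
})

test_that("the LRT applies the chi-squared tail with np accounting", {
  a <- list(lnL = -5047.902, np = 35)
  e <- list(lnL = -5044.408, np = 36)
  res <- lrt(a, e)
  expect_equal(res$stat, 6.988, tolerance = 1e-9)
  expect_equal(res$df, 1)
  expect_equal(res$pvalue, pchisq(6.988, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # identical fits: stat 0, p 1
  res0 <- lrt(a, list(lnL = -5047.902, np = 36))
  expect_equal(res0$stat, 0)
  expect_equal(res0$pvalue, 1)
  # failure modes
  expect_error(lrt(e, a), "more parameters")
  expect_error(lrt(list(lnL = -100, np = 1), list(lnL = -150, np = 2)),
               "negative LRT")
})
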