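# --- simulators for codon alignments and correlated tip traits ---

#' Simulate a codon alignment under the GY94 branch model
#'
#' The root codon is drawn from the equilibrium frequencies and evolved
#' along each branch with the transition matrix of that branch's class
#' (so branch-specific dN/dS values are honored).  No internal stop
#' codons can arise because the state space is the 61 sense codons.
#'
#' @param tree `phylo` or [labeled_tree] with branch lengths.
#' @param params list with `kappa`, `omega` (scalar or named by branch
#'   class), optional `pi` (length 61; default uniform).
#' @param n_codons number of codon sites.
#' @param seed integer seed.
#' @return list with `aln` (named character vector of CDS strings),
#'   `tree`, `params`, `seed`.
#' @export
simulate_codon_alignment <- function(tree, params, n_codons, seed = 1) {
  lt <- .as_labeled_tree(tree)
  phy <- ape::reorder.phylo(lt$tree, "postorder")
  edge_class <- lt$edge_class[match(
    paste(phy$edge[, 1], phy$edge[, 2]),
    paste(lt$tree$edge[, 1], lt$tree$edge[, 2]))]
  pi <- params$pi
  if (is.null(pi)) pi <- setNames(rep(1 / N_SENSE, N_SENSE), SENSE_CODONS)
  omega <- params$omega
  omega_edge <- if (length(omega) == 1 && is.null(names(omega))) {
    rep(omega, nrow(phy$edge))
  } else {
    as.numeric(omega[as.character(edge_class)])
  }
  if (anyNA(omega_edge)) stop("missing omega for some branch class")
  eig <- list()
  for (w in unique(omega_edge)) {
    eig[[as.character(w)]] <- .codon_eigen(params$kappa, w, pi)
  }
  ntip <- length(phy$tip.label)
  root <- phy$edge[nrow(phy$edge), 1]
  .with_seed(seed, {
    states <- matrix(0L, nrow = max(phy$edge), ncol = n_codons)
    states[root, ] <- sample.int(N_SENSE, n_codons, replace = TRUE,
                                 prob = pi)
    # pre-order: reverse of postorder edge ordering
    for (e in rev(seq_len(nrow(phy$edge)))) {
      P <- .pmat(eig[[as.character(omega_edge[e])]], phy$edge.length[e])
      par_states <- states[phy$edge[e, 1], ]
      child <- integer(n_codons)
      for (s in unique(par_states)) {
        sel <- par_states == s
        child[sel] <- sample.int(N_SENSE, sum(sel), replace = TRUE,
                                 prob = P[s, ])
      }
      states[phy$edge[e, 2], ] <- child
    }
    aln <- vapply(seq_len(ntip), function(i) {
      paste(SENSE_CODONS[states[i, ]], collapse = "")
    }, character(1))
    names(aln) <- phy$tip.label
    list(aln = aln, tree = lt, params = params, seed = seed)
  })
}

#' Simulate correlated binary and continuous traits on a tree
#'
#' A liability and a value evolve as correlated Brownian motion
#' (liability variance 1, value variance `sigma^2`, correlation `r`);
#' the emitted binary state is 1 where the liability is positive.  If
#' the binary trait comes out constant, the draw is repeated with an
#' incremented sub-seed (up to 100 times).
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param r true liability-value correlation in [-1, 1].
#' @param seed integer seed.
#' @param sigma value-scale standard deviation (default 1).
#' @return list with `traits` (species/hibernator/value data.frame),
#'   `liability`, `r`, `seed_used`.
#' @export
simulate_threshold_traits <- function(tree, r, seed = 1, sigma = 1) {
  stopifnot(r >= -1, r <= 1)
  C <- ape::vcv(tree)
  n <- nrow(C)
  L <- t(chol(C))
  for (k in 0:99) {
    sub <- derive_seed(seed, k)
    res <- .with_seed(sub, {
      z1 <- rnorm(n); z2 <- rnorm(n)
      liab <- as.numeric(L %*% z1)
      value <- sigma * as.numeric(L %*% (r * z1 + sqrt(1 - r^2) * z2))
      list(liab = liab, value = value)
    })
    bin <- as.integer(res$liab > 0)
    if (length(unique(bin)) == 2) {
      return(list(
        traits = data.frame(species = rownames(C), hibernator = bin,
                            value = res$value, stringsAsFactors = FALSE),
        liability = setNames(res$liab, rownames(C)),
        r = r, seed_used = sub
      ))
    }
  }
  stop("binary trait degenerate in 100 attempts; ",
       "tree or correlation too extreme")
}
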