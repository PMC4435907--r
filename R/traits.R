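# --- correlating the binary hibernation trait with genome-derived scores ---

#' Read a species trait table
#'
#' @param path TSV with columns `species`, `hibernator` (0/1), `value`.
#' @return data.frame.
#' @export
read_trait_table <- function(path) {
  tt <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  validate_trait_table(tt)
  tt
}

#' Validate a trait table
#' @param traits data.frame with `species`, `hibernator`, `value`.
#' @return the table, invisibly.
#' @export
validate_trait_table <- function(traits) {
  stopifnot(all(c("species", "hibernator", "value") %in% names(traits)))
  if (anyDuplicated(traits$species)) stop("duplicate species in trait table")
  if (!all(traits$hibernator %in% c(0, 1))) {
    stop("hibernator must be 0/1")
  }
  invisible(traits)
}

#' Two-sample Student's t-test between trait groups
#'
#' Classic pooled-variance two-sample t-test (two-tailed) with
#' `df = n1 + n2 - 2`; a Welch variant is available via `var_equal`.
#'
#' @param values_h,values_n numeric values for the two groups (e.g.
#'   hibernators and non-hibernators).
#' @param var_equal pooled-variance Student test (default TRUE).
#' @return an object of class `ttest_result`: `t`, `df`, `pvalue`.
#' @export
students_t_test <- function(values_h, values_n, var_equal = TRUE) {
  if (length(values_h) < 2 || length(values_n) < 2) {
    stop("each group needs at least two values")
  }
  if (var(values_h) == 0 && var(values_n) == 0) {
    if (mean(values_h) == mean(values_n)) {
      return(structure(list(t = 0, df = length(values_h) +
                              length(values_n) - 2, pvalue = 1),
                       class = "ttest_result"))
    }
    stop("degenerate input: zero variance in both groups with unequal means")
  }
  tt <- t.test(values_h, values_n, var.equal = var_equal)
  structure(list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    pvalue = tt$p.value
  ), class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.4g, two-tailed p = %.4g\n",
              x$t, x$df, x$pvalue))
  invisible(x)
}

#' Simulate Brownian motion tip values on a tree
#'
#' Tips are multivariate normal with covariance `rate * C`, where `C`
#' holds shared root-to-tip path lengths.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param rate Brownian rate (variance per unit branch length).
#' @param seed integer seed.
#' @param n_rep number of replicate tip vectors.
#' @return numeric matrix (n_tips x n_rep), rownames = tip labels.
#' @export
brownian_simulate <- function(tree, rate = 1, seed = 1, n_rep = 1) {
  stopifnot(all(tree$edge.length >= 0))
  C <- ape::vcv(tree)
  n <- nrow(C)
  U <- chol(C)
  .with_seed(seed, {
    z <- matrix(rnorm(n * n_rep), n, n_rep)
    out <- sqrt(rate) * crossprod(U, z)
    rownames(out) <- rownames(C)
    out
  })
}

#' Simulation-based phylogenetic ANOVA
#'
#' One-way ANOVA of a continuous value on a binary group, with the null
#' F distribution obtained by simulating the trait under Brownian
#' motion on the phylogeny (rate estimated from the data by
#' phylogenetically independent contrasts).  The p-value uses the
#' add-one tail correction, so it is never exactly zero.
#'
#' @param tree an `ape::phylo`; tip labels must match `traits$species`.
#' @param traits trait table (`species`, `hibernator`, `value`).
#' @param n_sim number of null simulations (default 1000).
#' @param seed integer seed.
#' @return an object of class `phyl_anova_result`: `F_obs`, `p_phyl`,
#'   `p_param` (the non-phylogenetic parametric p), `n_sim`, `seed`,
#'   `F_sim_quantiles`.
#' @export
phyl_anova <- function(tree, traits, n_sim = 1000, seed = 1) {
  validate_trait_table(traits)
  if (n_sim < 1) stop("n_sim must be at least 1")
  if (!setequal(tree$tip.label, traits$species)) {
    stop("tree tips and trait species differ")
  }
  traits <- traits[match(tree$tip.label, traits$species), ]
  g <- factor(traits$hibernator, levels = c(0, 1))
  if (length(unique(traits$value)) == 1) {
    stop("degenerate input: constant trait value, F undefined")
  }
  if (nlevels(droplevels(g)) < 2) stop("both trait classes must be present")
  x <- traits$value

  f_stat <- function(xmat) {
    # vectorized one-way F over columns of xmat
    n <- nrow(xmat)
    n1 <- sum(g == "1"); n0 <- n - n1
    m1 <- colMeans(xmat[g == "1", , drop = FALSE])
    m0 <- colMeans(xmat[g == "0", , drop = FALSE])
    mall <- colMeans(xmat)
    ssb <- n1 * (m1 - mall)^2 + n0 * (m0 - mall)^2
    sst <- colSums(sweep(xmat, 2, mall)^2)
    ssw <- sst - ssb
    (ssb / 1) / (ssw / (n - 2))
  }
  F_obs <- f_stat(matrix(x, ncol = 1))

  # Brownian rate by REML-style GLS (equals the mean squared
  # phylogenetically independent contrast on dichotomous trees)
  C <- ape::vcv(tree)
  Cinv <- solve(C)
  one <- rep(1, nrow(C))
  mu <- as.numeric(one %*% Cinv %*% x) / as.numeric(one %*% Cinv %*% one)
  rate <- as.numeric((x - mu) %*% Cinv %*% (x - mu)) / (length(x) - 1)

  sims <- brownian_simulate(tree, rate = rate, seed = seed, n_rep = n_sim)
  F_sim <- f_stat(sims)
  p_phyl <- (1 + sum(F_sim >= F_obs)) / (n_sim + 1)
  n <- length(x)
  p_param <- pf(F_obs, 1, n - 2, lower.tail = FALSE)
  structure(list(
    F_obs = unname(F_obs), p_phyl = p_phyl, p_param = unname(p_param),
    n_sim = n_sim, seed = seed,
    F_sim_quantiles = quantile(F_sim, c(0.5, 0.9, 0.95, 0.99))
  ), class = "phyl_anova_result")
}

#' @export
print.phyl_anova_result <- function(x, ...) {
  cat(sprintf("Phylogenetic ANOVA: F = %.4f, p_phyl = %.4g (%d sims)\n",
              x$F_obs, x$p_phyl, x$n_sim))
  invisible(x)
}

#' Relative expression fold change by the delta-delta-Ct method
#'
#' `ddCt = (Ct_target_state - Ct_ref_state) - (Ct_target_base -
#' Ct_ref_base)`; fold change is `2^-ddCt`.
#'
#' @param ct_target_state,ct_ref_state target and reference-gene Ct in
#'   the state of interest (e.g. torpid).
#' @param ct_target_base,ct_ref_base the same in the baseline state
#'   (e.g. active).
#' @return an object of class `fold_change`: `dct_state`, `dct_base`,
#'   `ddct`, `fold`.
#' @export
ddct_fold_change <- function(ct_target_state, ct_ref_state,
                             ct_target_base, ct_ref_base) {
  stopifnot(is.finite(ct_target_state), is.finite(ct_ref_state),
            is.finite(ct_target_base), is.finite(ct_ref_base))
  dct_state <- ct_target_state - ct_ref_state
  dct_base <- ct_target_base - ct_ref_base
  ddct <- dct_state - dct_base
  structure(list(
    dct_state = dct_state, dct_base = dct_base,
    ddct = ddct, fold = 2^(-ddct)
  ), class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("ddCt = %.4f, fold change = %.4f\n", x$ddct, x$fold))
  invisible(x)
}
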