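test_that("pooled t-test matches the closed form and its symmetries", {
  res <- students_t_test(c(1, 2, 3), c(4, 5, 6))
  # hand computation: pooled s^2 = 1, se = sqrt(2/3), t = -3/se
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$pvalue, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  # group exchange flips t, preserves p
  swap <- students_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$pvalue, res$pvalue)
  # identical groups
  same <- students_t_test(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$pvalue, 1)
  expect_error(students_t_test(1, c(1, 2)), "at least two")
  expect_error(students_t_test(c(1, 1), c(2, 2)), "degenerate")
})

test_that("ddCt fold change follows the formula and its invariances", {
  expect_equal(ddct_fold_change(20, 20, 20, 20)$fold, 1)
  f <- ddct_fold_change(20, 18, 21, 18.5)
  expect_equal(f$ddct, -0.5)
  expect_equal(f$fold, 2^0.5, tolerance = 1e-12)
  # uniform Ct shift leaves the fold unchanged
  f2 <- ddct_fold_change(23, 21, 24, 21.5)
  expect_equal(f2$fold, f$fold)
  # swapping state and baseline inverts the fold
  f3 <- ddct_fold_change(21, 18.5, 20, 18)
  expect_equal(f3$fold, 1 / f$fold)
  expect_error(ddct_fold_change(NA, 1, 1, 1))
})

test_that("phylogenetic ANOVA is invariant to group relabeling", {
  tr <- unit_tree(32, 5)
  st <- simulate_threshold_traits(tr, r = 0.5, seed = 7)
  p1 <- phyl_anova(tr, st$traits, n_sim = 300, seed = 11)
  flipped <- st$traits
  flipped$hibernator <- 1 - flipped$hibernator
  p2 <- phyl_anova(tr, flipped, n_sim = 300, seed = 11)
  expect_equal(p1$F_obs, p2$F_obs, tolerance = 1e-12)
  expect_equal(p1$p_phyl, p2$p_phyl)
})

test_that("on a star phylogeny the simulation p matches parametric ANOVA", {
  star <- ape::stree(48, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  st <- simulate_threshold_traits(star, r = 0.55, seed = 13)
  pa <- phyl_anova(star, st$traits, n_sim = 4000, seed = 3)
  # Monte-Carlo standard error at p ~ pa$p_param
  se <- sqrt(pa$p_param * (1 - pa$p_param) / 4000)
  expect_lt(abs(pa$p_phyl - pa$p_param), 4 * se + 1e-3)
})

test_that("phylogenetic ANOVA rejects degenerate input", {
  tr <- unit_tree(16, 2)
  st <- simulate_threshold_traits(tr, r = 0, seed = 5)
  expect_error(phyl_anova(tr, st$traits, n_sim = 0, seed = 1), "n_sim")
  const <- st$traits
  const$value <- 1
  expect_error(phyl_anova(tr, const, n_sim = 10, seed = 1), "degenerate")
  onegrp <- st$traits
  onegrp$hibernator <- 0
  expect_error(phyl_anova(tr, onegrp, n_sim = 10, seed = 1))
})

test_that("trait table IO validates and round-trips", {
  tt <- data.frame(species = c("a", "b", "c", "d"),
                   hibernator = c(1, 0, 1, 0),
                   value = c(0.5, 0.4, 0.6, 0.3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tt, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_trait_table(f)
  expect_equal(back, tt)
  bad <- tt; bad$species[2] <- "a"
  expect_error(validate_trait_table(bad), "duplicate")
  bad2 <- tt; bad2$hibernator[1] <- 2
  expect_error(validate_trait_table(bad2), "0/1")
})
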