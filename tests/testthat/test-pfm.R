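test_that("read_pfm parses both dialects and preserves counts", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A: 10 20 5", "C: 30 1 15", "G: 40 9 60", "T: 20 70 20"), f)
  p <- read_pfm(f)
  expect_equal(p$width, 3)
  expect_equal(unname(colSums(p$counts)), c(100, 100, 100))
  expect_equal(unname(p$counts["T", ]), c(20, 70, 20))

  # transposed dialect gives the identical matrix
  ft <- withr::local_tempfile(fileext = ".txt")
  write.table(t(p$counts), ft, row.names = FALSE, col.names = FALSE)
  pt <- read_pfm(ft, dialect = "rows-are-positions")
  expect_equal(pt$counts, p$counts)

  # uniform case
  fu <- withr::local_tempfile(fileext = ".txt")
  writeLines(rep("25 25", 4), fu)
  pu <- read_pfm(fu)
  expect_equal(pu$width, 2)
  expect_equal(unname(colSums(pu$counts)), c(100, 100))
})

test_that("read_pfm and pfm reject malformed input", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2", "3 x", "5 6", "7 8"), f)
  expect_error(read_pfm(f), "non-numeric")
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2", "3 4", "5 6"), f2)
  expect_error(read_pfm(f2), "4 rows")
  expect_error(pfm(matrix(c(-1, 1, 1, 1), nrow = 4)), "negative")
  expect_error(pfm(matrix(0, nrow = 4, ncol = 2)), "zero total")
})

test_that("background estimation counts, smooths and floors correctly", {
  expect_equal(unname(build_background(strrep("ACGT", 50), 0)$prob),
               rep(0.25, 4))
  b <- build_background(strrep("A", 100), 0.01)
  expect_lt(b$prob[["A"]], 1)
  expect_true(all(b$prob[c("C", "G", "T")] > 0))
  expect_equal(sum(b$prob), 1)
  # GC-rich sequence recovered within sampling error
  s <- random_dna(1e4, seed = 5, prob = c(0.15, 0.35, 0.35, 0.15))
  b2 <- build_background(s, 0.01)
  expect_true(all(abs(b2$prob - c(0.15, 0.35, 0.35, 0.15)) < 0.02))
  # N excluded from counts
  b3 <- build_background(c("AANN", "AA"), 0)
  expect_equal(unname(b3$prob), c(1, 0, 0, 0))
  expect_error(build_background(character(0)), "empty")
})

test_that("log-odds weights follow the pseudocount formula and lattice", {
  bg <- uniform_background()
  p <- pfm(matrix(c(97, 1, 1, 1, 25, 25, 25, 25), nrow = 4))
  w <- pfm_to_pwm(p, bg, pseudocount = 1, decimals = 1)$weights
  # hand evaluation: round(log2(((97 + 0.25)/101)/0.25), 1) = 1.9
  expect_equal(unname(w["A", 1]), 1.9)
  expect_equal(unname(w[, 2]), rep(0, 4))
  # every weight a multiple of 0.1
  rpwm <- pfm_to_pwm(random_pfm(3, 8), bg, decimals = 1)
  expect_equal(rpwm$weights, round(rpwm$weights, 1))
  # zero pseudocount with a zero count is undefined
  p0 <- pfm(matrix(c(10, 0, 5, 5, 5, 5, 5, 5), nrow = 4))
  expect_error(pfm_to_pwm(p0, bg, pseudocount = 0), "log-odds undefined")
})

test_that("single-column score distribution enumerates exactly", {
  toy <- pwm(matrix(c(1, 0, 0, -1), nrow = 4))
  d <- score_distribution(toy)
  expect_equal(score_pvalue(d, 1.0), 0.25)
  expect_equal(score_pvalue(d, 0.0), 0.75)
  expect_equal(score_pvalue(d, -1.0), 1)
  expect_equal(d$prob[d$score == 0], 0.5)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
})

test_that("DP distribution equals brute-force enumeration (small widths)", {
  bg <- background_model(c(0.2, 0.3, 0.3, 0.2))
  for (seed in c(11, 12)) {
    for (w in c(2, 4)) {
      pw <- pfm_to_pwm(random_pfm(seed, w), bg)
      d <- score_distribution(pw)
      words <- as.matrix(expand.grid(rep(list(1:4), w)))
      sc <- integer(nrow(words))
      pr <- numeric(nrow(words))
      for (k in seq_len(nrow(words))) {
        sc[k] <- sum(pw$int_weights[cbind(words[k, ], 1:w)])
        pr[k] <- prod(bg$prob[words[k, ]])
      }
      enum <- tapply(pr, sc, sum)
      got <- d$prob[as.integer(names(enum)) - d$int_offset + 1]
      expect_equal(unname(got), unname(as.numeric(enum)), tolerance = 1e-12)
      expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    }
  }
})

test_that("tail p-values are monotone with correct boundaries", {
  bg <- uniform_background()
  pw <- pfm_to_pwm(random_pfm(7, 6), bg)
  d <- score_distribution(pw)
  expect_true(all(diff(d$pval) <= 1e-15))
  expect_equal(d$pval[1], 1)
  # p-value at the maximum equals the probability of per-column-argmax words
  expect_equal(d$pval[length(d$pval)], d$prob[length(d$prob)])
  # scores beyond the support
  expect_equal(score_pvalue(d, min(d$score) - 1), 1)
  expect_equal(score_pvalue(d, max(d$score) + 1), 0)
})
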