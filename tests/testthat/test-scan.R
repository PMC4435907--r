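test_that("sequences shorter than the motif yield no windows", {
  pw <- pfm_to_pwm(example_pfm(), uniform_background())
  hits <- scan_pwm(pw, c(s = "ACGTACGT"), pval_upper = 1)
  expect_equal(nrow(hits), 0)
})

test_that("a planted consensus word is recovered exactly once", {
  pw <- pfm_to_pwm(example_pfm(), uniform_background())
  bgseq <- random_dna(3000, seed = 4)
  s <- paste0(substr(bgseq, 1, 100), "AGGTCAAAGGTCA",
              substr(bgseq, 114, 3000))
  hits <- scan_pwm(pw, c(test = s), pval_upper = 5e-7)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 100)
  expect_equal(hits$end, 113)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, max_score(pw))
})

test_that("reverse-complementing the sequence mirrors hits across strands", {
  pw <- pfm_to_pwm(random_pfm(9, 8), uniform_background())
  s <- random_dna(2000, seed = 13)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h1 <- scan_pwm(pw, c(x = s), pval_upper = 1e-2)
  h2 <- scan_pwm(pw, c(x = rc), pval_upper = 1e-2)
  L <- nchar(s)
  mirrored <- data.frame(
    start = L - h1$end, end = L - h1$start,
    strand = ifelse(h1$strand == "+", "-", "+"),
    score = h1$score
  )
  o1 <- mirrored[order(mirrored$start, mirrored$strand), ]
  o2 <- h2[order(h2$start, h2$strand), c("start", "end", "strand", "score")]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("windows containing N are skipped, others unaffected", {
  pw <- pfm_to_pwm(example_pfm(), uniform_background())
  bgseq <- random_dna(1000, seed = 8)
  core <- paste0(substr(bgseq, 1, 50), "AGGTCAAAGGTCA",
                 substr(bgseq, 64, 500))
  broken <- core
  substr(broken, 55, 55) <- "N"  # inside the planted site
  expect_equal(nrow(scan_pwm(pw, c(a = core), 5e-7)), 1)
  expect_equal(nrow(scan_pwm(pw, c(a = broken), 5e-7)), 0)
  expect_error(scan_pwm(pw, c(a = "ACGTXACGT")), "alphabet")
})

test_that("scanning is deterministic and invariant to sequence order", {
  pw <- pfm_to_pwm(random_pfm(21, 7), uniform_background())
  seqs <- c(a = random_dna(500, 1), b = random_dna(500, 2))
  h1 <- scan_pwm(pw, seqs, pval_upper = 0.05)
  h2 <- scan_pwm(pw, rev(seqs), pval_upper = 0.05)
  expect_equal(h1, h2)
  expect_gt(nrow(h1), 0)
})

test_that("threshold is inclusive and hit p-values match the distribution", {
  pw <- pfm_to_pwm(random_pfm(33, 6), uniform_background())
  d <- score_distribution(pw)
  s <- random_dna(4000, seed = 3)
  th <- d$pval[which(d$pval <= 0.01)[1]]  # an attainable p-value
  hits <- scan_pwm(pw, c(x = s), pval_upper = th, dist = d)
  expect_true(all(hits$pvalue <= th))
  expect_equal(hits$pvalue, score_pvalue(d, hits$score))

  # inclusive boundary: a window whose p-value equals the threshold is kept
  toy <- pwm(matrix(c(1, 0, 0, -1), nrow = 4))
  h_inc <- scan_pwm(toy, c(x = "A"), pval_upper = 0.25, two_strand = FALSE)
  expect_equal(nrow(h_inc), 1)
  h_exc <- scan_pwm(toy, c(x = "A"), pval_upper = 0.2499,
                    two_strand = FALSE)
  expect_equal(nrow(h_exc), 0)
})
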