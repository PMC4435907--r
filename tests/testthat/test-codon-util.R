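test_that("translation follows the standard code with gap handling", {
  expect_equal(translate_cds("ATGAAA"), "MK")
  expect_equal(translate_cds("ATG---"), "M-")
})

test_that("translation error contracts", {
  expect_error(translate_cds("ATGTAAAAA"), "internal stop")
  expect_error(translate_cds("ATGA"), "partial codon")
  expect_error(translate_cds("ATGA--"), "partial codon gap")
  # trailing stop dropped
  expect_equal(translate_cds("ATGAAATAA"), "MK")
  expect_equal(translate_cds("ATGANA"), "MX")
})

test_that("alignment validation flags internal stops and ragged rows", {
  aln <- c(a = "ATGAAATGA", b = "ATGAAATGA")  # terminal stop only: fine
  expect_silent(validate_codon_alignment(aln))
  bad <- c(a = "ATGTAAAAA", b = "ATGAAAAAA")
  expect_error(validate_codon_alignment(bad), "internal stop")
  expect_error(validate_codon_alignment(c(a = "ATGAAA", b = "ATG")),
               "differ in length")
})

test_that("codon alignment FASTA IO round-trips", {
  tr <- unit_tree(4, 3)
  sim <- simulate_codon_alignment(tr, list(kappa = 2, omega = 0.2), 20,
                                  seed = 5)
  f <- withr::local_tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$aln), f)
  back <- read_codon_alignment(f)
  expect_equal(back, sim$aln)
})

test_that("conservation summary counts identical and variable columns", {
  aln <- c(s1 = "MKLV", s2 = "MKLV", s3 = "MKIV")
  cs <- conservation_summary(aln)
  expect_equal(cs$n_columns, 4)
  expect_equal(cs$n_identical, 3)
  expect_equal(cs$n_variable, 1)
  expect_equal(cs$percent_identity, 75)
  # all identical
  cs2 <- conservation_summary(c(a = "AAA", b = "AAA"))
  expect_equal(cs2$percent_identity, 100)
  expect_equal(cs2$n_variable, 0)
  # gaps are ignored when judging identity
  cs3 <- conservation_summary(c(a = "M-K", b = "MLK", c = "MLK"))
  expect_equal(cs3$n_identical, 3)
  # region restriction
  cs4 <- conservation_summary(aln, region = c(3, 4))
  expect_equal(cs4$n_columns, 2)
  expect_equal(cs4$n_identical, 1)
  expect_error(conservation_summary(aln, region = c(0, 4)), "region")
})

test_that("group classification matches a per-column brute check", {
  # columns: 1 same everywhere; 2 conserved in A, divergent in B;
  # 3 conserved in A, fixed-different in B; 4 variable in A
  aln <- c(a1 = "MKLV", a2 = "MKLV", b1 = "MALV", b2 = "MTRV")
  groups <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  cs <- conservation_summary(aln, groups = groups)
  expect_equal(cs$group_sites$conserved_A_different_B, c(2, 3))
  # brute force over all columns and both directions
  chars <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(chars) <- names(aln)
  brute <- function(A, B) {
    which(vapply(1:4, function(j) {
      va <- chars[A, j]; vb <- chars[B, j]
      identA <- length(unique(va[va != "-"])) <= 1
      identB <- length(unique(vb[vb != "-"])) <= 1
      identA && (!identB || (vb[1] != va[1]))
    }, logical(1)))
  }
  expect_equal(cs$group_sites$conserved_A_different_B,
               brute(groups$A, groups$B))
  expect_equal(cs$group_sites$conserved_B_different_A,
               brute(groups$B, groups$A))
  expect_error(conservation_summary(aln, groups = list(A = names(aln),
                                                       B = character(0))),
               "empty group")
})
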