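hit_row <- function(start, end, score, chrom = "chr1") {
  data.frame(seq_id = rep(chrom, length(start)), start = start, end = end,
             strand = rep("+", length(start)), score = score,
             pvalue = rep(1e-8, length(start)), stringsAsFactors = FALSE)
}

test_that("target calling uses 1 bp overlap and the max score", {
  g <- three_exon_gene()
  rs <- derive_regions(g, chrom_length = 1e5, upstream_kb = 0.5)
  # no hits at all
  empty <- call_target(hit_row(integer(0), integer(0), numeric(0)), rs)
  expect_false(empty$is_target)
  expect_true(is.na(empty$affinity))
  # two contributing hits: affinity is the maximum
  h <- rbind(hit_row(1100, 1113, 8.2), hit_row(1600, 1613, 9.1))
  ct <- call_target(h, rs)
  expect_true(ct$is_target)
  expect_equal(ct$n_hits, 2)
  expect_equal(ct$affinity, 9.1)
  # a hit between regions (downstream flank) does not count
  ct2 <- call_target(hit_row(5000, 5013, 12), rs)
  expect_false(ct2$is_target)
  # 1 bp overlap at the upstream edge counts; touching does not
  up <- rs$upstream[1, ]
  expect_true(call_target(hit_row(up[1] - 12, up[1] + 1, 5), rs)$is_target)
  expect_false(call_target(hit_row(up[1] - 13, up[1], 5), rs)$is_target)
  # hits on another chromosome are ignored
  expect_false(call_target(hit_row(1100, 1113, 8, chrom = "chr2"),
                           rs)$is_target)
})

test_that("species summaries compute ratio and mean affinity", {
  calls <- data.frame(
    gene_id = paste0("g", 1:10),
    is_target = c(rep(TRUE, 3), rep(FALSE, 7)),
    n_hits = c(1, 2, 1, rep(0, 7)),
    affinity = c(9.0, 9.5, 10.0, rep(NA, 7))
  )
  s <- summarize_species(calls, "spX", 1)
  expect_equal(s$target_ratio, 0.3)
  expect_equal(s$mean_affinity, 9.5)
  expect_equal(s$hibernator, 1L)
  # zero targets: ratio defined, mean absent
  calls0 <- transform(calls, is_target = FALSE, affinity = NA_real_)
  s0 <- summarize_species(calls0, "spY", 0)
  expect_equal(s0$target_ratio, 0)
  expect_true(is.na(s0$mean_affinity))
  # saturation
  calls1 <- transform(calls, is_target = TRUE, affinity = 5)
  expect_equal(summarize_species(calls1, "spZ", 0)$target_ratio, 1)
})

test_that("removing hits never increases ratio or affinity", {
  g <- generate_genome(genome_recipe(n_genes = 10, seed = 42,
                                     plant_strength = 0.8))
  res <- scan_genome_targets(g)
  hits <- res$hits
  rsets <- lapply(g$genes, derive_regions, chrom_length = g$chrom_length)
  set.seed(1)
  keep <- sample(nrow(hits), floor(nrow(hits) / 2))
  calls_full <- call_targets(hits, rsets)
  calls_half <- call_targets(hits[keep, ], rsets)
  expect_lte(sum(calls_half$is_target), sum(calls_full$is_target))
  both <- !is.na(calls_half$affinity) & !is.na(calls_full$affinity)
  expect_true(all(calls_half$affinity[both] <= calls_full$affinity[both]))
})

test_that("threshold sweep is monotone and saturates at p = 1", {
  g <- generate_genome(genome_recipe(n_genes = 12, seed = 7))
  pfm_used <- g$recipe$pfm
  bg <- build_background(g$sequences)
  pw <- pfm_to_pwm(pfm_used, bg)
  rsets <- lapply(g$genes, derive_regions, chrom_length = g$chrom_length)
  sweep_res <- threshold_sweep(pw, g$sequences, rsets,
                               thresholds = c(5e-7, 5e-6, 1))
  expect_equal(sweep_res$pval_upper, c(5e-7, 5e-6, 1))
  expect_true(all(diff(sweep_res$target_ratio) >= 0))
  # at p = 1 every gene with a scorable window is a target
  expect_equal(sweep_res$target_ratio[3], 1)
})
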