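test_that("genome generation is deterministic and internally consistent", {
  rec <- genome_recipe(n_genes = 8, seed = 21)
  g1 <- generate_genome(rec)
  g2 <- generate_genome(rec)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$truth, g2$truth)
  expect_equal(length(g1$genes), 8)
  expect_equal(nchar(g1$sequences[["chr1"]]), g1$chrom_length)
  # every planted site lies inside its stated region of its gene
  for (k in seq_len(nrow(g1$truth$sites))) {
    site <- g1$truth$sites[k, ]
    rs <- derive_regions(g1$genes[[site$gene_id]], g1$chrom_length)
    iv <- rs[[site$region]]
    expect_true(any(site$start >= iv[, 1] & site$end <= iv[, 2]))
  }
  # target labels match the planted sites
  expect_equal(g1$truth$targets$is_target,
               g1$truth$targets$gene_id %in% g1$truth$sites$gene_id)
})

test_that("planting rate zero leaves an empty truth table", {
  g <- generate_genome(genome_recipe(
    n_genes = 5, seed = 2,
    plant_rate = c(upstream = 0, exon = 0, intron = 0)))
  expect_equal(nrow(g$truth$sites), 0)
  expect_false(any(g$truth$targets$is_target))
})

test_that("consensus-strength planted sites are recovered by rescanning", {
  g <- generate_genome(genome_recipe(n_genes = 20, seed = 17,
                                     plant_strength = 1,
                                     plant_rate = c(upstream = 1,
                                                    exon = 0, intron = 0)))
  res <- scan_genome_targets(g)
  truth_targets <- sum(g$truth$targets$is_target)
  called <- merge(res$calls, g$truth$targets, by = "gene_id")
  # every gene with a planted consensus site is called a target
  expect_true(all(called$is_target.x[called$is_target.y]))
  expect_gte(res$summary$n_targets, truth_targets)
})

test_that("capacity constraints are enforced", {
  expect_error(generate_genome(genome_recipe(intergenic = 500)),
               "capacity")
})

test_that("genome files round-trip through FASTA and GFF3", {
  g <- generate_genome(genome_recipe(n_genes = 4, seed = 5))
  dir <- withr::local_tempdir()
  write_genome(g, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "sp1.fa"))
  expect_equal(as.character(fa[["chr1"]]), g$sequences[["chr1"]])
  genes <- read_gene_models(file.path(dir, "sp1.gff3"))
  expect_setequal(names(genes), names(g$genes))
  gback <- genes[[g$genes[[2]]$gene_id]]
  expect_equal(gback$exons, g$genes[[2]]$exons, ignore_attr = TRUE)
  expect_equal(gback$strand, g$genes[[2]]$strand)
  expect_equal(gback$tss, g$genes[[2]]$tss)
  expect_true(file.exists(file.path(dir, "sp1_truth.json")))
})

test_that("cohort bookkeeping and uplift are applied", {
  coh <- generate_cohort(cohort_recipe(n_species = 12, n_hibernators = 3,
                                       seed = 2))
  expect_equal(nrow(coh$species), 12)
  expect_equal(sum(coh$species$hibernator), 3)
  expect_equal(length(coh$tree$tip.label), 12)
  expect_setequal(coh$tree$tip.label, coh$species$species)
  hib <- coh$truth$hibernator == 1
  expect_true(all(coh$truth$plant_rate_upstream[hib] >
                    max(coh$truth$plant_rate_upstream[!hib])))
  expect_true(all(coh$truth$plant_strength[hib] >
                    max(coh$truth$plant_strength[!hib])))
  # deterministic
  coh2 <- generate_cohort(cohort_recipe(n_species = 12, n_hibernators = 3,
                                        seed = 2))
  expect_identical(coh$truth, coh2$truth)
})

test_that("a small cohort pipeline separates the planted groups", {
  coh <- generate_cohort(cohort_recipe(
    n_species = 10, n_hibernators = 5, seed = 6,
    base = genome_recipe(n_genes = 10)))
  pipe <- run_cohort_pipeline(coh)
  expect_equal(nrow(pipe$summaries), 10)
  expect_equal(pipe$trait_affinity$species, pipe$summaries$species)
  s <- pipe$summaries
  expect_gt(mean(s$mean_affinity[s$hibernator == 1]),
            mean(s$mean_affinity[s$hibernator == 0]))
})
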