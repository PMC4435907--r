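# --- seeded generators for every input the pipeline consumes ---

#' Bundled synthetic nuclear-receptor-style motif
#'
#' A synthetic position frequency matrix shaped like a nuclear-receptor
#' direct repeat (AGGTCA-A-AGGTCA, 13 columns, ~15 bits): constructed
#' for examples and fixtures, not taken from any motif database.  A
#' plain-text copy ships as
#' `system.file("extdata", "synthetic_nr_motif_pfm.txt",
#' package = "hibtarget")` for [read_pfm] examples.
#'
#' @param n_obs nominal count total per column (default 100).
#' @return a [pfm].
#' @export
example_pfm <- function(n_obs = 100) {
  consensus <- strsplit("AGGTCAAAGGTCA", "")[[1]]
  dominant <- 0.85
  counts <- sapply(consensus, function(b) {
    p <- rep((1 - dominant) / 3, 4)
    p[match(b, DNA_BASES)] <- dominant
    round(p * n_obs)
  })
  pfm(counts)
}

#' Recipe for a synthetic genome with planted motif sites
#'
#' Defines a one-chromosome genome of identically structured genes on
#' an i.i.d. background, with motif instances planted into designated
#' gene regions at Poisson rates.  Planting strength interpolates
#' between sampling site bases from the PFM column frequencies
#' (strength 0) and writing the column consensus (strength 1).
#'
#' @param species species label.
#' @param n_genes number of genes (default 25).
#' @param background base composition (A,C,G,T; default 0.3/0.2/0.2/0.3).
#' @param exon_count,exon_length,intron_length gene structure (defaults
#'   3 exons of 200 bp, 400 bp introns).
#' @param utr_length length of the terminal UTR portions of the first
#'   and last exon (default 100 bp).
#' @param intergenic gap between consecutive genes and at the
#'   chromosome ends (default 12000, leaving the 10 kb upstream window
#'   clear of the neighboring gene).
#' @param plant_rate named vector of expected planted sites per gene
#'   for regions `upstream`, `exon`, `intron`.
#' @param plant_strength consensus weight in [0, 1].
#' @param pfm the motif to plant (default [example_pfm]).
#' @param upstream_kb upstream window the planting (and later calling)
#'   uses, in kb (default 10).
#' @param hibernator 0/1 flag carried through to summaries.
#' @param seed integer seed.
#' @return an object of class `genome_recipe`.
#' @export
genome_recipe <- function(species = "sp1", n_genes = 25,
                          background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                          exon_count = 3, exon_length = 200,
                          intron_length = 400, utr_length = 100,
                          intergenic = 12000,
                          plant_rate = c(upstream = 0.8, exon = 0,
                                         intron = 0.4),
                          plant_strength = 0.6,
                          pfm = example_pfm(),
                          upstream_kb = 10, hibernator = 0, seed = 1) {
  stopifnot(abs(sum(background) - 1) < 1e-9, all(background > 0),
            all(plant_rate >= 0), plant_strength >= 0, plant_strength <= 1,
            n_genes >= 1, exon_count >= 1, exon_length > 0,
            intergenic > 0)
  structure(list(
    species = species, n_genes = n_genes, background = background,
    exon_count = exon_count, exon_length = exon_length,
    intron_length = intron_length, utr_length = utr_length,
    intergenic = intergenic, plant_rate = plant_rate,
    plant_strength = plant_strength, pfm = pfm,
    upstream_kb = upstream_kb, hibernator = as.integer(hibernator),
    seed = as.integer(seed)
  ), class = "genome_recipe")
}

# draw one motif instance as a character string
.draw_site <- function(pfm, strength) {
  probs <- sweep(pfm$counts, 2, colSums(pfm$counts), "/")
  vapply(seq_len(pfm$width), function(j) {
    if (runif(1) < strength) {
      DNA_BASES[which.max(probs[, j])]
    } else {
      sample(DNA_BASES, 1, prob = probs[, j])
    }
  }, character(1))
}

.revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

#' Generate a synthetic genome with planted motif sites
#'
#' Draws an i.i.d. background chromosome, lays out non-overlapping
#' genes, plants motif instances in the designated regions at the
#' recipe's Poisson rates, and returns the sequences, gene models and a
#' truth table of planted coordinates and intended target labels.
#' Byte-identical for a fixed recipe (the seed lives in the recipe).
#'
#' @param recipe a [genome_recipe].
#' @return an object of class `synthetic_genome`: list with `species`,
#'   `hibernator`, `sequences` (named character, one chromosome),
#'   `genes` (named list of [gene_model]), `chrom_length`, `truth`
#'   (list with `sites` data.frame and `targets` data.frame), `recipe`.
#' @export
generate_genome <- function(recipe) {
  stopifnot(inherits(recipe, "genome_recipe"))
  r <- recipe
  gene_len <- r$exon_count * r$exon_length +
    (r$exon_count - 1) * r$intron_length
  pitch <- r$intergenic + gene_len
  chrom_length <- r$n_genes * pitch + r$intergenic
  up_size <- round(r$upstream_kb * 1000)
  if (r$intergenic < up_size + r$pfm$width) {
    stop("capacity error: intergenic gap (", r$intergenic,
         ") cannot hold the ", up_size, " bp upstream window plus a site")
  }
  w <- r$pfm$width
  .with_seed(r$seed, {
    seq_int <- sample.int(4, chrom_length, replace = TRUE,
                          prob = r$background)
    chars <- DNA_BASES[seq_int]

    genes <- vector("list", r$n_genes)
    sites <- list()
    for (gi in seq_len(r$n_genes)) {
      gstart <- r$intergenic + (gi - 1) * pitch
      strand <- sample(c("+", "-"), 1)
      ex_starts <- gstart +
        (seq_len(r$exon_count) - 1) * (r$exon_length + r$intron_length)
      exons <- cbind(ex_starts, ex_starts + r$exon_length)
      gid <- sprintf("%s_g%03d", r$species, gi)
      # terminal UTRs (strand-aware) and CDS
      ul <- min(r$utr_length, r$exon_length)
      if (strand == "+") {
        utr5 <- matrix(c(exons[1, 1], exons[1, 1] + ul), ncol = 2)
        utr3 <- matrix(c(exons[nrow(exons), 2] - ul,
                         exons[nrow(exons), 2]), ncol = 2)
      } else {
        utr5 <- matrix(c(exons[nrow(exons), 2] - ul,
                         exons[nrow(exons), 2]), ncol = 2)
        utr3 <- matrix(c(exons[1, 1], exons[1, 1] + ul), ncol = 2)
      }
      cds <- exons
      cds[1, 1] <- cds[1, 1] + ul
      cds[nrow(cds), 2] <- cds[nrow(cds), 2] - ul
      cds <- cds[cds[, 2] > cds[, 1], , drop = FALSE]
      gm <- gene_model(gid, "chr1", strand, exons,
                       cds = cds, utr5 = utr5, utr3 = utr3)
      genes[[gi]] <- gm

      regions <- derive_regions(gm, chrom_length,
                                upstream_kb = r$upstream_kb)
      for (kind in c("upstream", "exon", "intron")) {
        rate <- r$plant_rate[[kind]]
        if (is.null(rate) || rate <= 0) next
        ivs <- regions[[kind]]
        if (nrow(ivs) == 0) next
        n_sites <- rpois(1, rate)
        if (n_sites == 0) next
        widths <- ivs[, 2] - ivs[, 1]
        ok <- widths >= w
        if (!any(ok)) next
        ivs <- ivs[ok, , drop = FALSE]
        widths <- widths[ok]
        for (k in seq_len(n_sites)) {
          iv <- ivs[sample.int(nrow(ivs), 1, prob = widths - w + 1), ,
                    drop = FALSE]
          pos <- iv[1, 1] + sample.int(iv[1, 2] - iv[1, 1] - w + 1, 1) - 1
          site <- paste(.draw_site(r$pfm, r$plant_strength), collapse = "")
          s_strand <- sample(c("+", "-"), 1)
          written <- if (s_strand == "+") site else .revcomp_chr(site)
          chars[(pos + 1):(pos + w)] <- strsplit(written, "")[[1]]
          sites[[length(sites) + 1]] <- data.frame(
            gene_id = gid, region = kind, chrom = "chr1",
            start = pos, end = pos + w, strand = s_strand,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    names(genes) <- vapply(genes, function(g) g$gene_id, character(1))
    sites_df <- if (length(sites)) do.call(rbind, sites) else
      data.frame(gene_id = character(), region = character(),
                 chrom = character(), start = integer(), end = integer(),
                 strand = character(), stringsAsFactors = FALSE)
    targets <- data.frame(
      gene_id = names(genes),
      is_target = names(genes) %in% sites_df$gene_id,
      stringsAsFactors = FALSE
    )
    structure(list(
      species = r$species, hibernator = r$hibernator,
      sequences = c(chr1 = paste(chars, collapse = "")),
      genes = genes, chrom_length = chrom_length,
      truth = list(sites = sites_df, targets = targets),
      recipe = r
    ), class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome for", x$species, ":", length(x$genes), "genes on",
      x$chrom_length, "bp;", nrow(x$truth$sites), "planted site(s)\n")
  invisible(x)
}

#' Write a synthetic genome to disk
#'
#' Emits FASTA, GFF3 and a JSON truth table.
#'
#' @param genome a `synthetic_genome`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(fa, file.path(dir, paste0(genome$species,
                                                        ".fa")))
  write_gene_models_gff3(genome$genes,
                         file.path(dir, paste0(genome$species, ".gff3")))
  jsonlite::write_json(genome$truth,
                       file.path(dir, paste0(genome$species,
                                             "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the target-calling pipeline on one genome
#'
#' Convenience wrapper: background estimation, PWM construction, scan,
#' per-gene calling and the species summary, using the genome's own
#' planting motif by default.
#'
#' @param genome a `synthetic_genome` (or a list with `sequences`,
#'   `genes`, `chrom_length`, `species`, `hibernator`).
#' @param pfm motif to scan with (default the genome's planting PFM).
#' @param pval_upper scan threshold (default 5e-7).
#' @param pseudocount,decimals,bg_pseudo PWM construction parameters.
#' @param upstream_kb upstream window for calling (default 10).
#' @return list with `summary` (one-row species summary), `calls`,
#'   `hits`.
#' @export
scan_genome_targets <- function(genome, pfm = NULL, pval_upper = 5e-7,
                                pseudocount = 1, decimals = 1,
                                bg_pseudo = 0.01, upstream_kb = 10) {
  if (is.null(pfm)) pfm <- genome$recipe$pfm
  bg <- build_background(genome$sequences, bg_pseudo = bg_pseudo)
  pw <- pfm_to_pwm(pfm, bg, pseudocount = pseudocount, decimals = decimals)
  hits <- scan_pwm(pw, genome$sequences, pval_upper = pval_upper)
  region_sets <- lapply(genome$genes, derive_regions,
                        chrom_length = genome$chrom_length,
                        upstream_kb = upstream_kb)
  calls <- call_targets(hits, region_sets)
  list(
    summary = summarize_species(calls, genome$species, genome$hibernator),
    calls = calls, hits = hits
  )
}

#' Recipe for a multi-species cohort with a hibernator uplift
#'
#' Species genomes share a base recipe; hibernating species receive a
#' planting-rate multiplier and a planting-strength increment, which is
#' the synthetic stand-in for hibernators having more target genes and
#' higher binding affinity.  The tree is a seeded pure-birth tree
#' scaled to unit height unless one is supplied.
#'
#' @param n_species number of species (default 64).
#' @param n_hibernators number of hibernating species (default 16).
#' @param base a [genome_recipe] used for every species (its species
#'   name, hibernator flag and seed are overridden per species).
#' @param rate_uplift multiplier on `plant_rate` for hibernators
#'   (default 1.6).
#' @param strength_uplift additive increment on `plant_strength` for
#'   hibernators, capped at 1 (default 0.25).
#' @param tree optional `ape::phylo` with `n_species` tips.
#' @param seed integer seed.
#' @return an object of class `cohort_recipe`.
#' @export
cohort_recipe <- function(n_species = 64, n_hibernators = 16,
                          base = genome_recipe(),
                          rate_uplift = 1.6, strength_uplift = 0.25,
                          tree = NULL, seed = 1) {
  stopifnot(n_hibernators >= 1, n_hibernators < n_species,
            rate_uplift >= 0, strength_uplift >= 0)
  structure(list(
    n_species = n_species, n_hibernators = n_hibernators, base = base,
    rate_uplift = rate_uplift, strength_uplift = strength_uplift,
    tree = tree, seed = as.integer(seed)
  ), class = "cohort_recipe")
}

#' Generate a species cohort (tree, trait skeleton, genome recipes)
#'
#' Builds the cohort tree, assigns hibernator status to a random subset
#' of tips, and derives one seeded [genome_recipe] per species with the
#' hibernator uplift applied.  Genomes themselves are materialized per
#' species by [generate_genome] (see [run_cohort_pipeline]) so large
#' cohorts never need to be held in memory at once.
#'
#' @param recipe a [cohort_recipe].
#' @return an object of class `synthetic_cohort`: list with `tree`,
#'   `species` (data.frame species/hibernator), `genome_recipes`,
#'   `truth` (per-species planting rate and strength), `recipe`.
#' @export
generate_cohort <- function(recipe) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  r <- recipe
  sp <- sprintf("sp%02d", seq_len(r$n_species))
  tree <- r$tree
  .with_seed(derive_seed(r$seed, 0), {
    if (is.null(tree)) {
      tree <- ape::rphylo(r$n_species, birth = 1, death = 0)
      tree$tip.label <- sp
      h <- max(ape::node.depth.edgelength(tree))
      tree$edge.length <- tree$edge.length / h
    } else {
      if (length(tree$tip.label) != r$n_species) {
        stop("supplied tree must have n_species tips")
      }
      sp <- tree$tip.label
    }
    hib <- integer(r$n_species)
    hib[sample.int(r$n_species, r$n_hibernators)] <- 1L
    recipes <- vector("list", r$n_species)
    for (i in seq_len(r$n_species)) {
      g <- r$base
      g$species <- sp[i]
      g$hibernator <- hib[i]
      g$seed <- derive_seed(r$seed, i)
      if (hib[i] == 1L) {
        g$plant_rate <- g$plant_rate * r$rate_uplift
        g$plant_strength <- min(1, g$plant_strength + r$strength_uplift)
      }
      recipes[[i]] <- g
    }
    names(recipes) <- sp
    structure(list(
      tree = tree,
      species = data.frame(species = sp, hibernator = hib,
                           stringsAsFactors = FALSE),
      genome_recipes = recipes,
      truth = data.frame(
        species = sp, hibernator = hib,
        plant_rate_upstream = vapply(recipes, function(x)
          x$plant_rate[["upstream"]], numeric(1)),
        plant_strength = vapply(recipes, function(x)
          x$plant_strength, numeric(1)),
        stringsAsFactors = FALSE
      ),
      recipe = r
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$species), "species (",
      sum(x$species$hibernator), "hibernators )\n")
  invisible(x)
}

#' Run the full target-gene pipeline over a cohort
#'
#' Generates each species genome from its recipe, scans it, calls
#' targets, and assembles per-species summaries and the two trait
#' tables (target ratio and mean affinity) consumable by the
#' trait-correlation methods.
#'
#' @param cohort a `synthetic_cohort` (or [cohort_recipe], which is
#'   generated first).
#' @param pval_upper scan threshold (default 5e-7).
#' @param ... passed to [scan_genome_targets].
#' @return list with `summaries` (data.frame, one row per species),
#'   `trait_ratio` and `trait_affinity` (trait tables), `tree`.
#' @export
run_cohort_pipeline <- function(cohort, pval_upper = 5e-7, ...) {
  if (inherits(cohort, "cohort_recipe")) cohort <- generate_cohort(cohort)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- vector("list", length(cohort$genome_recipes))
  for (i in seq_along(cohort$genome_recipes)) {
    g <- generate_genome(cohort$genome_recipes[[i]])
    rows[[i]] <- scan_genome_targets(g, pval_upper = pval_upper, ...)$summary
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL
  list(
    summaries = summaries,
    trait_ratio = data.frame(species = summaries$species,
                             hibernator = summaries$hibernator,
                             value = summaries$target_ratio,
                             stringsAsFactors = FALSE),
    trait_affinity = data.frame(species = summaries$species,
                                hibernator = summaries$hibernator,
                                value = summaries$mean_affinity,
                                stringsAsFactors = FALSE),
    tree = cohort$tree
  )
}

#' Generate ChIP-peak fixtures with known feature classes
#'
#' Places peak midpoints uniformly inside the genome-wide region
#' partition of the requested class (after precedence), so
#' [annotate_peaks] recovers the intended class by construction.
#'
#' @param genes named list of [gene_model] objects.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param class_mix named probabilities over the seven peak classes
#'   (must sum to 1).
#' @param n_peaks number of peaks.
#' @param width peak width in bp (default 200).
#' @param distal_kb flank cutoff consistent with [annotate_peaks]
#'   (default 20).
#' @param seed integer seed.
#' @return list with `peaks` (data.frame chrom/start/end) and `truth`
#'   (intended class per peak).
#' @export
generate_chip_peaks <- function(genes, chrom_lengths, class_mix, n_peaks,
                                width = 200, distal_kb = 20, seed = 1) {
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class mix must sum to 1")
  if (!all(names(class_mix) %in% PEAK_CLASSES)) {
    stop("unknown peak class in mix: ",
         paste(setdiff(names(class_mix), PEAK_CLASSES), collapse = ", "))
  }
  part <- .peak_class_partition(genes, distal_kb)
  # available intervals per class across chromosomes (midpoint space)
  class_pool <- list()
  for (cl in names(class_mix)) {
    pool <- list()
    for (ch in names(part)) {
      if (cl == "Distal_Region") {
        taken <- part[[ch]][["taken"]]
        ir <- BiocGenerics::setdiff(
          IRanges::IRanges(1, chrom_lengths[[ch]]), taken)
      } else {
        ir <- part[[ch]][[cl]]
      }
      if (!is.null(ir) && length(ir) > 0) {
        pool[[ch]] <- data.frame(
          chrom = ch, start = BiocGenerics::start(ir) - 1,
          end = BiocGenerics::end(ir), stringsAsFactors = FALSE)
      }
    }
    if (class_mix[[cl]] > 0 && length(pool) == 0) {
      stop("requested class absent from annotation: ", cl)
    }
    class_pool[[cl]] <- if (length(pool)) do.call(rbind, pool) else NULL
  }
  .with_seed(seed, {
    cls <- sample(names(class_mix), n_peaks, replace = TRUE,
                  prob = class_mix)
    out <- vector("list", n_peaks)
    for (k in seq_len(n_peaks)) {
      pool <- class_pool[[cls[k]]]
      wts <- pool$end - pool$start
      for (try in 1:100) {
        row <- pool[sample.int(nrow(pool), 1, prob = wts), ]
        mid <- row$start + sample.int(row$end - row$start, 1) - 1
        start <- mid - floor(width / 2)
        end <- mid + ceiling(width / 2)
        if (start >= 0 && end <= chrom_lengths[[row$chrom]]) break
      }
      if (start < 0 || end > chrom_lengths[[row$chrom]]) {
        stop("could not place a ", cls[k], " peak inside the chromosome")
      }
      out[[k]] <- data.frame(chrom = row$chrom, start = start, end = end,
                             stringsAsFactors = FALSE)
    }
    peaks <- do.call(rbind, out)
    list(peaks = peaks,
         truth = data.frame(class = cls, stringsAsFactors = FALSE))
  })
}

#' Write peaks as BED3
#' @param peaks data.frame chrom/start/end.
#' @param path output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  write.table(peaks[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
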