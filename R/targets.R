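#' Derive labeled genomic regions for a gene
#'
#' Builds the region set used for target-gene calling: the upstream
#' promoter window (default 10 kb 5' of the TSS, strand-aware), the
#' exons, and the introns (gaps between consecutive exons).  Intervals
#' are clipped to chromosome bounds.
#'
#' @param gene a [gene_model].
#' @param chrom_length chromosome length in bases.
#' @param upstream_kb upstream window size in kb (default 10).
#' @return an object of class `region_set`: list with `gene_id`, `chrom`,
#'   `strand`, and interval matrices `upstream`, `exon`, `intron`
#'   (0-based half-open).
#' @export
derive_regions <- function(gene, chrom_length, upstream_kb = 10) {
  stopifnot(inherits(gene, "gene_model"))
  size <- round(upstream_kb * 1000)
  ex <- gene$exons
  if (any(ex[, 2] > chrom_length)) stop("gene extends beyond chromosome")
  if (gene$strand == "+") {
    up <- c(gene$tss - size, gene$tss)
  } else {
    up <- c(gene$tss + 1, gene$tss + 1 + size)
  }
  up[1] <- max(up[1], 0)
  up[2] <- min(up[2], chrom_length)
  upstream <- if (up[2] > up[1]) matrix(up, ncol = 2) else
    matrix(numeric(0), ncol = 2)
  n <- nrow(ex)
  intron <- if (n > 1) {
    cbind(ex[-n, 2], ex[-1, 1])
  } else {
    matrix(numeric(0), ncol = 2)
  }
  intron <- intron[intron[, 2] > intron[, 1], , drop = FALSE]
  structure(list(
    gene_id = gene$gene_id, chrom = gene$chrom, strand = gene$strand,
    upstream = .as_intervals(upstream),
    exon = .as_intervals(ex),
    intron = .as_intervals(intron)
  ), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("Regions for", x$gene_id, ":",
      nrow(x$upstream), "upstream,", nrow(x$exon), "exon,",
      nrow(x$intron), "intron interval(s)\n")
  invisible(x)
}

# >= 1 bp overlap between [s, e) hits and a set of [rs, re) intervals
.overlaps_any <- function(start, end, intervals) {
  if (nrow(intervals) == 0 || length(start) == 0) {
    return(logical(length(start)))
  }
  out <- logical(length(start))
  for (k in seq_len(nrow(intervals))) {
    out <- out | (start < intervals[k, 2] & intervals[k, 1] < end)
  }
  out
}

#' Call a gene as a transcription-factor target
#'
#' A gene is a target if at least one motif hit overlaps (by >= 1 bp)
#' its introns, exons, or upstream promoter window.  The gene's affinity
#' score is the maximum score among contributing hits ("only the highest
#' score estimated for a gene is adopted").
#'
#' @param hits hit data.frame from [scan_pwm] (same chromosome naming
#'   as the gene annotation).
#' @param regions a [region_set] from [derive_regions].
#' @return an object of class `gene_target_call`: list with `gene_id`,
#'   `is_target`, `n_hits`, `affinity` (NA when no hits contribute).
#' @export
call_target <- function(hits, regions) {
  stopifnot(inherits(regions, "region_set"))
  h <- hits[hits$seq_id == regions$chrom, , drop = FALSE]
  contributes <- .overlaps_any(h$start, h$end, regions$upstream) |
    .overlaps_any(h$start, h$end, regions$exon) |
    .overlaps_any(h$start, h$end, regions$intron)
  n <- sum(contributes)
  structure(list(
    gene_id = regions$gene_id,
    is_target = n >= 1,
    n_hits = n,
    affinity = if (n >= 1) max(h$score[contributes]) else NA_real_
  ), class = "gene_target_call")
}

#' Call targets for a set of genes
#'
#' @param hits hit data.frame from [scan_pwm].
#' @param region_sets list of [region_set] objects.
#' @return data.frame with one row per gene: `gene_id`, `is_target`,
#'   `n_hits`, `affinity`.
#' @export
call_targets <- function(hits, region_sets) {
  rows <- lapply(region_sets, function(rs) {
    cl <- call_target(hits, rs)
    data.frame(gene_id = cl$gene_id, is_target = cl$is_target,
               n_hits = cl$n_hits, affinity = cl$affinity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-species target-gene summary
#'
#' The target-gene ratio is the number of target genes divided by the
#' number of all genes; the mean affinity averages the per-gene best
#' scores over target genes only.
#'
#' @param calls data.frame from [call_targets].
#' @param species species label.
#' @param hibernator 0/1 hibernation flag.
#' @return one-row data.frame with `species`, `hibernator`, `n_genes`,
#'   `n_targets`, `target_ratio`, `mean_affinity`.
#' @export
summarize_species <- function(calls, species, hibernator) {
  if (nrow(calls) == 0) stop("no gene calls to summarize")
  n_targets <- sum(calls$is_target)
  data.frame(
    species = species,
    hibernator = as.integer(hibernator),
    n_genes = nrow(calls),
    n_targets = n_targets,
    target_ratio = n_targets / nrow(calls),
    mean_affinity = if (n_targets > 0) {
      mean(calls$affinity[calls$is_target])
    } else {
      NA_real_
    },
    stringsAsFactors = FALSE
  )
}

#' Target summaries across scan p-value thresholds
#'
#' Scans once at the loosest threshold and re-filters, so per-threshold
#' calls are mutually consistent; the target ratio is non-decreasing in
#' the threshold.
#'
#' @param pwm a [pwm].
#' @param sequences sequences to scan.
#' @param region_sets list of [region_set] objects.
#' @param thresholds vector of p-value thresholds.
#' @param species,hibernator labels passed to [summarize_species].
#' @return data.frame with one row per threshold (column `pval_upper`
#'   prepended to the [summarize_species] columns).
#' @export
threshold_sweep <- function(pwm, sequences, region_sets, thresholds,
                            species = "species", hibernator = 0L) {
  stopifnot(length(thresholds) >= 1, all(thresholds > 0), all(thresholds <= 1))
  dist <- score_distribution(pwm)
  hits <- scan_pwm(pwm, sequences, pval_upper = max(thresholds), dist = dist)
  rows <- lapply(thresholds, function(th) {
    calls <- call_targets(hits[hits$pvalue <= th, , drop = FALSE], region_sets)
    cbind(pval_upper = th,
          summarize_species(calls, species, hibernator))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

PEAK_CLASSES <- c("5'UTR", "Coding Exon", "3'UTR", "Intron",
                  "UpStream", "DownStream", "Distal_Region")

# genome-wide disjoint class partition honoring the precedence order:
# 5'UTR > Coding Exon > 3'UTR > Intron > UpStream > DownStream > Distal
.peak_class_partition <- function(genes, distal_kb = 20) {
  d <- round(distal_kb * 1000)
  per_chrom_ir <- function(get) {
    lst <- lapply(genes, get)
    chroms <- vapply(genes, function(g) g$chrom, character(1))
    out <- list()
    for (ch in unique(chroms)) {
      ivs <- do.call(rbind, lst[chroms == ch])
      if (is.null(ivs) || nrow(ivs) == 0) {
        out[[ch]] <- IRanges::IRanges()
      } else {
        out[[ch]] <- IRanges::reduce(
          IRanges::IRanges(start = ivs[, 1] + 1, end = ivs[, 2]))
      }
    }
    out
  }
  utr5 <- per_chrom_ir(function(g) g$utr5)
  cds <- per_chrom_ir(function(g) {
    if (is.null(g$cds)) g$exons else g$cds
  })
  utr3 <- per_chrom_ir(function(g) g$utr3)
  intron <- per_chrom_ir(function(g) {
    n <- nrow(g$exons)
    if (n < 2) return(NULL)
    iv <- cbind(g$exons[-n, 2], g$exons[-1, 1])
    iv[iv[, 2] > iv[, 1], , drop = FALSE]
  })
  upstream <- per_chrom_ir(function(g) {
    if (g$strand == "+") {
      matrix(c(max(gene_span(g)[1] - d, 0), gene_span(g)[1]), ncol = 2)
    } else {
      matrix(c(gene_span(g)[2], gene_span(g)[2] + d), ncol = 2)
    }
  })
  downstream <- per_chrom_ir(function(g) {
    if (g$strand == "+") {
      matrix(c(gene_span(g)[2], gene_span(g)[2] + d), ncol = 2)
    } else {
      matrix(c(max(gene_span(g)[1] - d, 0), gene_span(g)[1]), ncol = 2)
    }
  })
  chroms <- unique(vapply(genes, function(g) g$chrom, character(1)))
  layers <- list(`5'UTR` = utr5, `Coding Exon` = cds, `3'UTR` = utr3,
                 Intron = intron, UpStream = upstream,
                 DownStream = downstream)
  # subtract higher-precedence layers chromosome-wise
  part <- list()
  for (ch in chroms) {
    taken <- IRanges::IRanges()
    part[[ch]] <- list()
    for (cl in names(layers)) {
      ir <- layers[[cl]][[ch]]
      if (is.null(ir)) ir <- IRanges::IRanges()
      avail <- BiocGenerics::setdiff(ir, taken)
      part[[ch]][[cl]] <- avail
      taken <- IRanges::reduce(c(taken, avail))
    }
    part[[ch]][["taken"]] <- taken
  }
  part
}

#' Annotate ChIP peaks by genomic feature class
#'
#' Each peak is assigned, by its midpoint, to exactly one of 5'UTR,
#' Coding Exon, 3'UTR, Intron, UpStream, DownStream, or Distal_Region
#' (farther than `distal_kb` from any gene), with class precedence in
#' that order.  Up/DownStream are the strand-aware flanks of the gene
#' span out to `distal_kb`.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), or a GRanges.
#' @param genes named list of [gene_model] objects.
#' @param distal_kb distance cutoff in kb separating flanks from the
#'   distal class (default 20).
#' @return an object of class `peak_annotation_summary`: list with
#'   `class` (per-peak factor), `counts`, `ratios`, `n_peaks`.
#' @export
annotate_peaks <- function(peaks, genes, distal_kb = 20) {
  if (is(peaks, "GRanges")) {
    peaks <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(peaks)),
      start = BiocGenerics::start(peaks) - 1,
      end = BiocGenerics::end(peaks),
      stringsAsFactors = FALSE
    )
  }
  if (any(peaks$end <= peaks$start)) stop("malformed peak interval (end <= start)")
  part <- .peak_class_partition(genes, distal_kb)
  mid <- floor((peaks$start + peaks$end) / 2)
  cls <- rep("Distal_Region", nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    sel <- which(peaks$chrom == ch)
    if (is.null(part[[ch]])) next
    q <- IRanges::IRanges(start = mid[sel] + 1, width = 1)
    for (cl in setdiff(PEAK_CLASSES, "Distal_Region")) {
      ir <- part[[ch]][[cl]]
      if (is.null(ir) || length(ir) == 0) next
      hit <- IRanges::overlapsAny(q, ir)
      assignable <- hit & cls[sel] == "Distal_Region"
      cls[sel][assignable] <- cl
    }
  }
  cls <- factor(cls, levels = PEAK_CLASSES)
  counts <- table(cls)
  structure(list(
    class = cls,
    counts = as.integer(counts),
    ratios = as.numeric(counts) / length(cls),
    classes = PEAK_CLASSES,
    n_peaks = length(cls)
  ), class = "peak_annotation_summary")
}

#' @export
print.peak_annotation_summary <- function(x, ...) {
  cat("Peak annotation over", x$n_peaks, "peaks\n")
  print(data.frame(class = x$classes, count = x$counts,
                   ratio = round(x$ratios, 4)))
  invisible(x)
}

#' Read a BED3+ peak file
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start` (0-based), `end`.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Build a TSS-anchored regulatory window
#'
#' Three window kinds anchor on the TSS: `TSS_Up` ends at the TSS on its
#' 5' side, `TSS_Around` is centered on the TSS, and `TSS_Body` starts
#' at the TSS and extends into the gene.  All are strand-oriented (on
#' the - strand, "upstream" lies to the genomic right) and clipped to
#' chromosome bounds.
#'
#' @param gene a [gene_model].
#' @param kind one of "TSS_Around", "TSS_Up", "TSS_Body".
#' @param size_kb window size in kb (the study sweeps 2.5, 5, 7.5, 10).
#' @param chrom_length chromosome length for clipping (default Inf).
#' @return an object of class `regulatory_window`: list with `gene_id`,
#'   `kind`, `size_kb`, `chrom`, `strand`, `start`, `end` (0-based
#'   half-open).
#' @export
make_window <- function(gene, kind = c("TSS_Around", "TSS_Up", "TSS_Body"),
                        size_kb, chrom_length = Inf) {
  kind <- match.arg(kind)
  if (size_kb <= 0) stop("window size must be positive")
  size <- round(size_kb * 1000)
  tss <- gene$tss
  if (gene$strand == "+") {
    iv <- switch(kind,
      TSS_Up = c(tss - size, tss),
      TSS_Body = c(tss, tss + size),
      TSS_Around = c(tss - floor(size / 2), tss + ceiling(size / 2))
    )
  } else {
    # on the - strand the TSS base is position tss; 5' is to the right
    iv <- switch(kind,
      TSS_Up = c(tss + 1, tss + 1 + size),
      TSS_Body = c(tss + 1 - size, tss + 1),
      TSS_Around = c(tss + 1 - ceiling(size / 2), tss + 1 + floor(size / 2))
    )
  }
  iv[1] <- max(iv[1], 0)
  iv[2] <- min(iv[2], chrom_length)
  structure(list(
    gene_id = gene$gene_id, kind = kind, size_kb = size_kb,
    chrom = gene$chrom, strand = gene$strand,
    start = unname(iv[1]), end = unname(iv[2])
  ), class = "regulatory_window")
}

#' @export
print.regulatory_window <- function(x, ...) {
  cat(sprintf("%s %s %.1f kb: %s:[%d, %d) (%s)\n", x$gene_id, x$kind,
              x$size_kb, x$chrom, x$start, x$end, x$strand))
  invisible(x)
}
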