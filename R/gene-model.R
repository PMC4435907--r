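#' Construct a gene model
#'
#' A minimal strand-aware gene representation: sorted disjoint exons in
#' 0-based half-open coordinates, with the TSS at the leftmost exon
#' start on the + strand and at the rightmost exon end - 1 on the -
#' strand.  Optional CDS and UTR intervals support peak classification.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons 2-column matrix (start, end), 0-based half-open, sorted.
#' @param cds,utr5,utr3 optional 2-column interval matrices.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons,
                       cds = NULL, utr5 = NULL, utr3 = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- .as_intervals(exons)
  if (nrow(exons) == 0) stop("gene must have at least one exon")
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop("malformed exon (end <= start)")
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop("exons overlap")
  }
  tss <- unname(if (strand == "+") exons[1, 1] else
    exons[nrow(exons), 2] - 1)
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand, tss = tss,
    exons = exons,
    cds = if (is.null(cds)) NULL else .as_intervals(cds),
    utr5 = if (is.null(utr5)) NULL else .as_intervals(utr5),
    utr3 = if (is.null(utr3)) NULL else .as_intervals(utr3)
  ), class = "gene_model")
}

.as_intervals <- function(x) {
  m <- as.matrix(x)
  if (length(m) == 0) return(matrix(numeric(0), ncol = 2))
  if (ncol(m) != 2) stop("intervals must be a 2-column (start, end) matrix")
  storage.mode(m) <- "double"
  colnames(m) <- c("start", "end")
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene", x$gene_id, "on", x$chrom, x$strand,
      "| TSS", x$tss, "|", nrow(x$exons), "exon(s)\n")
  invisible(x)
}

#' Gene span (leftmost start, rightmost end)
#' @param gene a `gene_model`.
#' @return numeric length-2 (start, end), 0-based half-open.
#' @export
gene_span <- function(gene) {
  c(gene$exons[1, 1], gene$exons[nrow(gene$exons), 2])
}

#' Read gene models from a GFF3 or BED12 file
#'
#' Uses rtracklayer for parsing.  For GFF3, exon/CDS/UTR features are
#' grouped by transcript and the longest transcript of each gene is
#' taken as canonical.  For BED12, blocks become exons and the thick
#' interval the CDS.
#'
#' @param path annotation file (`.gff3`/`.gff` or `.bed`).
#' @param format override autodetection: "gff3" or "bed12".
#' @return a named list of `gene_model` objects.
#' @export
read_gene_models <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "BED")
    out <- lapply(seq_along(gr), function(i) {
      g <- gr[i]
      blocks <- S4Vectors::mcols(g)$blocks[[1]]
      if (is.null(blocks) || length(blocks) == 0) {
        ex <- cbind(BiocGenerics::start(g) - 1, BiocGenerics::end(g))
      } else {
        abs <- IRanges::shift(blocks, BiocGenerics::start(g) - 1)
        ex <- cbind(BiocGenerics::start(abs) - 1, BiocGenerics::end(abs))
      }
      thick <- S4Vectors::mcols(g)$thick
      cds <- NULL
      if (!is.null(thick) && IRanges::width(thick) > 1) {
        cds <- cbind(BiocGenerics::start(thick) - 1, BiocGenerics::end(thick))
      }
      gene_model(
        gene_id = S4Vectors::mcols(g)$name %||% paste0("gene", i),
        chrom = as.character(GenomicRanges::seqnames(g)),
        strand = as.character(BiocGenerics::strand(g)),
        exons = ex, cds = cds
      )
    })
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    out <- .genes_from_gff_granges(gr)
  }
  names(out) <- vapply(out, function(g) g$gene_id, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

.genes_from_gff_granges <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  is_tx <- type %in% c("mRNA", "transcript")
  tx_ids <- as.character(mc$ID[is_tx])
  tx_gene <- vapply(which(is_tx), function(i) {
    p <- unlist(mc$Parent[i])
    if (length(p) == 0) as.character(mc$ID[i]) else as.character(p[1])
  }, character(1))
  names(tx_gene) <- tx_ids
  feat <- which(type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"))
  parent_of <- vapply(feat, function(i) {
    p <- unlist(mc$Parent[i])
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  # transcripts and their per-type intervals
  genes <- list()
  for (tid in tx_ids) {
    rows <- feat[parent_of == tid]
    if (length(rows) == 0) next
    sub <- gr[rows]
    stype <- type[rows]
    iv <- function(tt) {
      sel <- stype == tt
      if (!any(sel)) return(NULL)
      cbind(BiocGenerics::start(sub)[sel] - 1, BiocGenerics::end(sub)[sel])
    }
    ex <- iv("exon")
    if (is.null(ex)) ex <- iv("CDS")
    gid <- tx_gene[[tid]]
    gm <- gene_model(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(sub))[1],
      strand = as.character(BiocGenerics::strand(sub))[1],
      exons = ex, cds = iv("CDS"),
      utr5 = iv("five_prime_UTR"), utr3 = iv("three_prime_UTR")
    )
    span <- sum(gm$exons[, 2] - gm$exons[, 1])
    # longest transcript per gene is canonical
    if (is.null(genes[[gid]]) || attr(genes[[gid]], "span") < span) {
      attr(gm, "span") <- span
      genes[[gid]] <- gm
    }
  }
  lapply(genes, function(g) { attr(g, "span") <- NULL; g })
}

#' Write gene models as GFF3
#'
#' @param genes named list of `gene_model` objects.
#' @param path output file.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    span <- gene_span(g)
    lines <- c(
      sprintf("%s\thibtarget\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, span[1] + 1, span[2], g$strand, g$gene_id),
      sprintf("%s\thibtarget\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom, span[1] + 1, span[2], g$strand, g$gene_id, g$gene_id)
    )
    emit <- function(tt, iv) {
      if (is.null(iv) || nrow(iv) == 0) return(character(0))
      phase <- if (tt == "CDS") "0" else "."
      sprintf("%s\thibtarget\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s.t1",
              g$chrom, tt, iv[, 1] + 1, iv[, 2], g$strand, phase, g$gene_id)
    }
    lines <- c(lines, emit("exon", g$exons), emit("CDS", g$cds),
               emit("five_prime_UTR", g$utr5), emit("three_prime_UTR", g$utr3))
    writeLines(lines, con)
  }
  invisible(path)
}
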