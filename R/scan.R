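#' Scan sequences for PWM matches with exact p-values
#'
#' Scores every window of motif width on the forward strand (and, when
#' `two_strand`, the reverse-complement of the same window) against the
#' PWM, converts scores to exact background p-values via the
#' dynamic-programming score distribution, and reports windows with
#' p-value at or below the threshold.  Windows containing ambiguous
#' bases (N) are skipped.
#'
#' @param pwm a [pwm] object.
#' @param sequences named character vector or `DNAStringSet`.
#' @param pval_upper inclusive upper p-value threshold (default 5e-7,
#'   the scan threshold used for target-gene calling).
#' @param two_strand scan both strands (default TRUE).
#' @param dist optional precomputed [score_distribution] for `pwm`.
#' @return a data.frame of hits with columns `seq_id`, `start` (0-based),
#'   `end` (half-open), `strand`, `score`, `pvalue`, sorted by
#'   (seq_id, start, strand).
#' @export
scan_pwm <- function(pwm, sequences, pval_upper = 5e-7, two_strand = TRUE,
                     dist = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (!(pval_upper > 0 && pval_upper <= 1)) {
    stop("pval_upper must be in (0, 1]")
  }
  seqs <- .as_dna_character(sequences)
  if (is.null(dist)) dist <- score_distribution(pwm)
  w <- pwm$width
  scale <- 10^pwm$decimals

  # integer score threshold: smallest lattice score whose tail p <= threshold
  qualifying <- which(dist$pval <= pval_upper)
  if (length(qualifying) == 0) {
    min_int <- Inf
  } else {
    min_int <- dist$int_offset + min(qualifying) - 1
  }

  iw_fwd <- pwm$int_weights
  iw_rev <- reverse_complement_pwm(pwm)$int_weights

  res <- vector("list", 2L * length(seqs))
  k <- 0L
  for (sid in names(seqs)) {
    code <- encode_dna(seqs[[sid]])
    L <- length(code)
    if (L < w) next
    strands <- if (two_strand) c("+", "-") else "+"
    for (strand in strands) {
      iw <- if (strand == "+") iw_fwd else iw_rev
      nw <- L - w + 1L
      s <- iw[code[seq_len(nw)], 1L]
      if (w > 1) {
        for (j in 2:w) {
          s <- s + iw[code[j:(nw + j - 1L)], j]
        }
      }
      hit <- which(!is.na(s) & s >= min_int)
      if (length(hit) == 0) next
      score_int <- s[hit]
      k <- k + 1L
      res[[k]] <- data.frame(
        seq_id = sid,
        start = hit - 1L,
        end = hit - 1L + w,
        strand = strand,
        score = score_int / scale,
        pvalue = dist$pval[score_int - dist$int_offset + 1L],
        stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0L) {
    out <- data.frame(
      seq_id = character(), start = integer(), end = integer(),
      strand = character(), score = numeric(), pvalue = numeric(),
      stringsAsFactors = FALSE
    )
    return(out)
  }
  out <- do.call(rbind, res[seq_len(k)])
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write motif hits as TSV
#'
#' @param hits hit data.frame from [scan_pwm].
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write motif hits as BED6
#'
#' Scores are scaled by 100 and rounded to integers per BED convention.
#'
#' @param hits hit data.frame from [scan_pwm].
#' @param path output file.
#' @param name feature name (motif id) for column 4.
#' @export
write_hits_bed <- function(hits, path, name = "motif") {
  bed <- data.frame(
    chrom = hits$seq_id,
    start = hits$start,
    end = hits$end,
    name = name,
    score = as.integer(round(hits$score * 100)),
    strand = hits$strand
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
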