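#' Read a position frequency matrix
#'
#' Reads a plain-text count matrix describing the base composition of a
#' transcription-factor binding motif.  The canonical layout has one row
#' per base (A, C, G, T) and one column per motif position; the
#' transposed layout (rows are positions) is accepted via `dialect`.
#'
#' @param path path to a whitespace-delimited numeric matrix.  Row labels
#'   (`A:`, `>A`, `A`) are tolerated and ignored; base order is assumed
#'   A, C, G, T.
#' @param dialect `"rows-are-bases"` (default) or `"rows-are-positions"`.
#' @return an object of class `pfm`: a list with `counts` (4 x width
#'   numeric matrix, rownames A,C,G,T) and `width`.
#' @export
read_pfm <- function(path, dialect = c("rows-are-bases", "rows-are-positions")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(l) {
    toks <- strsplit(l, "[\t ]+")[[1]]
    # drop a leading base label such as "A", "A:", ">A", "A|"
    if (length(toks) > 0 && grepl("^>?[ACGTacgt][:|]?$", toks[1])) {
      toks <- toks[-1]
    }
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) stop("non-numeric cell in PFM file: ", l)
    vals
  })
  if (length(unique(lengths(rows))) != 1) {
    stop("ragged PFM file: rows have differing numbers of columns")
  }
  m <- do.call(rbind, rows)
  if (dialect == "rows-are-positions") m <- t(m)
  if (nrow(m) != 4) {
    stop("PFM must have 4 rows (A,C,G,T) after applying the dialect; got ",
         nrow(m))
  }
  pfm(m)
}

#' Construct a position frequency matrix
#'
#' @param counts 4 x width numeric matrix of non-negative base counts;
#'   rows in A, C, G, T order.
#' @return an object of class `pfm`.
#' @export
pfm <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PFM counts must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 1) stop("PFM must have width >= 1")
  if (any(!is.finite(counts))) stop("non-numeric cell in PFM")
  if (any(counts < 0)) stop("negative count in PFM")
  if (any(colSums(counts) <= 0)) stop("PFM column with zero total count")
  dimnames(counts) <- list(DNA_BASES, NULL)
  structure(list(counts = counts, width = ncol(counts)), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix, width", x$width, "\n")
  print(round(x$counts, 3))
  invisible(x)
}

#' Estimate an order-0 background model from sequences
#'
#' Counts A/C/G/T over the sequence set (ambiguous bases excluded) and
#' smooths the empirical frequencies by mixing with the uniform
#' distribution at total mass `4 * bg_pseudo`, i.e.
#' `p_b = f_b * (1 - 4 * bg_pseudo) + bg_pseudo`, so every base retains
#' probability at least `bg_pseudo`.
#'
#' @param sequences character vector or `DNAStringSet`.
#' @param bg_pseudo pseudo-probability floor per base (default 0.01).
#' @return an object of class `bg_model`: list with `prob` (named A,C,G,T
#'   probabilities summing to 1) and `bg_pseudo`.
#' @export
build_background <- function(sequences, bg_pseudo = 0.01) {
  stopifnot(bg_pseudo >= 0, bg_pseudo < 0.25)
  seqs <- .as_dna_character(sequences)
  if (length(seqs) == 0) stop("empty sequence set")
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in seqs) {
    code <- encode_dna(s)
    tb <- tabulate(code, nbins = 4)
    counts <- counts + tb
  }
  total <- sum(counts)
  if (total == 0) stop("no non-ambiguous bases in sequence set")
  prob <- (counts / total) * (1 - 4 * bg_pseudo) + bg_pseudo
  prob <- prob / sum(prob)
  background_model(prob, bg_pseudo)
}

#' Construct a background model from explicit probabilities
#'
#' @param prob numeric length-4 probabilities in A,C,G,T order.
#' @param bg_pseudo the pseudo-probability mass used to build `prob`.
#' @return an object of class `bg_model`.
#' @export
background_model <- function(prob, bg_pseudo = 0) {
  prob <- setNames(as.numeric(prob), DNA_BASES)
  if (abs(sum(prob) - 1) > 1e-12) stop("background probabilities must sum to 1")
  if (bg_pseudo > 0 && any(prob < bg_pseudo - 1e-12)) {
    stop("background probability below the pseudo-probability floor")
  }
  if (any(prob < 0)) stop("negative background probability")
  structure(list(prob = prob, bg_pseudo = bg_pseudo), class = "bg_model")
}

#' Uniform background model
#' @return a `bg_model` with all probabilities 0.25.
#' @export
uniform_background <- function() background_model(rep(0.25, 4))

#' Convert a PFM to a rounded log-odds position weight matrix
#'
#' Column weights are base-2 log-odds of the pseudocount-regularised
#' motif frequency against the background:
#' `w(b, j) = round(log2(((n_bj + pseudo * p_b) / (N_j + pseudo)) / p_b),
#' decimals)`.  Rounding is applied here, before any scanning or p-value
#' computation, so that hit scores and the exact score distribution live
#' on the same `10^-decimals` lattice.
#'
#' @param pfm a [pfm] object.
#' @param bg a [background_model].
#' @param pseudocount total pseudocount per column, distributed by
#'   background probability (default 1).
#' @param decimals number of decimal places the weights are rounded to
#'   (default 1).
#' @return an object of class `pwm`: list with `weights` (4 x width),
#'   `int_weights` (weights scaled by `10^decimals`, integer),
#'   `pseudocount`, `decimals`, `background`, `width`.
#' @export
pfm_to_pwm <- function(pfm, bg, pseudocount = 1, decimals = 1) {
  stopifnot(inherits(pfm, "pfm"), inherits(bg, "bg_model"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (decimals < 0 || decimals != round(decimals)) {
    stop("decimals must be a non-negative integer")
  }
  counts <- pfm$counts
  coltot <- colSums(counts)
  p <- bg$prob
  freq <- sweep(counts + pseudocount * p, 2, coltot + pseudocount, "/")
  if (any(freq == 0)) {
    stop("zero motif frequency with zero pseudocount: log-odds undefined")
  }
  w <- log2(freq / p)
  w <- round(w, decimals)
  iw <- round(w * 10^decimals)
  storage.mode(iw) <- "integer"
  dimnames(w) <- list(DNA_BASES, NULL)
  structure(list(
    weights = w, int_weights = iw, pseudocount = pseudocount,
    decimals = decimals, background = bg, width = ncol(w)
  ), class = "pwm")
}

#' Construct a PWM directly from weights
#'
#' Mainly useful for tests and toy examples; weights are snapped to the
#' `10^-decimals` lattice.
#'
#' @param weights 4 x width matrix of log-odds weights (A,C,G,T rows).
#' @param bg a [background_model] (default uniform).
#' @param decimals lattice precision (default 1).
#' @return a `pwm` object.
#' @export
pwm <- function(weights, bg = uniform_background(), decimals = 1) {
  weights <- as.matrix(weights)
  if (nrow(weights) != 4) stop("PWM weights must have 4 rows")
  w <- round(weights, decimals)
  iw <- round(w * 10^decimals)
  storage.mode(iw) <- "integer"
  dimnames(w) <- list(DNA_BASES, NULL)
  structure(list(
    weights = w, int_weights = iw, pseudocount = NA_real_,
    decimals = decimals, background = bg, width = ncol(w)
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("Position weight matrix, width ", x$width,
      ", log2 odds rounded to ", x$decimals, " decimals\n", sep = "")
  print(x$weights)
  cat("max score:", max_score(x), "\n")
  invisible(x)
}

#' Maximum achievable PWM score
#' @param pwm a `pwm` object.
#' @return sum of per-column maxima.
#' @export
max_score <- function(pwm) sum(apply(pwm$weights, 2, max))

#' Reverse-complement a PWM
#'
#' Scanning the forward strand with the reverse-complemented PWM scores
#' the reverse strand at the same coordinates.
#'
#' @param pwm a `pwm` object.
#' @return a `pwm` object.
#' @export
reverse_complement_pwm <- function(pwm) {
  w <- pwm$weights[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  rownames(w) <- DNA_BASES
  out <- pwm
  out$weights <- w
  out$int_weights <- pwm$int_weights[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  rownames(out$int_weights) <- DNA_BASES
  out
}

#' Exact PWM score distribution under the background model
#'
#' Dynamic-programming convolution over motif columns on the integer
#' score lattice (`10^-decimals` granularity): the distribution of the
#' score of a single random background window, from which exact tail
#' p-values are read off.
#'
#' @param pwm a `pwm` object.
#' @return an object of class `score_distribution`: list with `score`
#'   (ascending lattice values), `prob`, `pval` (upper-tail, inclusive),
#'   `decimals`, `int_offset` (integer score of `score[1]`).
#' @export
score_distribution <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  iw <- pwm$int_weights
  if (any(!is.finite(iw))) stop("PWM weights must be finite")
  p <- unname(pwm$background$prob)
  W <- ncol(iw)
  lo <- sum(apply(iw, 2, min))
  hi <- sum(apply(iw, 2, max))
  n <- hi - lo + 1L
  # start before column 1: point mass at 0, tracked relative to running min
  cur <- 1
  cur_lo <- 0L
  for (j in seq_len(W)) {
    wj <- iw[, j]
    new_lo <- cur_lo + min(wj)
    new_hi <- cur_lo + length(cur) - 1L + max(wj)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- cur_lo + wj[b] - new_lo
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + p[b] * cur
    }
    cur <- new
    cur_lo <- new_lo
  }
  stopifnot(cur_lo == lo, length(cur) == n)
  pvals <- rev(cumsum(rev(cur)))
  pvals <- pmin(pvals, 1)
  structure(list(
    score = (lo:hi) / 10^pwm$decimals,
    prob = cur,
    pval = pvals,
    decimals = pwm$decimals,
    int_offset = lo
  ), class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  nz <- x$prob > 0
  cat("Exact PWM score distribution on the 10^-", x$decimals,
      " lattice\n", sep = "")
  cat(sum(nz), "achievable scores in [", min(x$score[nz]), ",",
      max(x$score[nz]), "]\n")
  invisible(x)
}

#' Exact p-value of a score
#'
#' Upper-tail probability (inclusive) of a random background window
#' scoring at least `score`.  Scores below the distribution minimum give
#' 1; scores above the maximum give 0.
#'
#' @param dist a [score_distribution].
#' @param score numeric score(s) on the PWM lattice.
#' @return numeric p-value(s).
#' @export
score_pvalue <- function(dist, score) {
  idx <- round(score * 10^dist$decimals) - dist$int_offset + 1
  n <- length(dist$pval)
  out <- numeric(length(idx))
  out[idx < 1] <- 1
  out[idx > n] <- 0
  ok <- idx >= 1 & idx <= n
  out[ok] <- dist$pval[idx[ok]]
  out
}

#' Smallest attainable p-value at or below a threshold
#'
#' Because scores live on a discrete lattice, the per-window hit
#' probability of a scan at `p <= pval_upper` equals the largest
#' attainable tail probability not exceeding the threshold, not the
#' threshold itself.  This helper exposes that effective rate.
#'
#' @param dist a [score_distribution].
#' @param pval_upper upper p-value threshold.
#' @return the attainable tail probability actually governing the scan.
#' @export
effective_pvalue <- function(dist, pval_upper) {
  ok <- dist$pval <= pval_upper & dist$prob >= 0
  if (!any(ok)) return(0)
  max(dist$pval[ok][dist$pval[ok] > 0], 0)
}
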