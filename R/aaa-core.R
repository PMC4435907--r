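#' @useDynLib hibtarget, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize optim rnorm runif rpois rbinom sd var
#'   pchisq pf qnorm pnorm quantile rexp setNames aov anova lm t.test
#' @importFrom utils write.table read.table head tail
#' @importFrom methods is
NULL

DNA_BASES <- c("A", "C", "G", "T")

# byte -> base index lookup (A/C/G/T -> 1:4, N and anything else -> NA),
# case-insensitive
.base_code_table <- local({
  tab <- rep(NA_integer_, 256)
  for (i in seq_along(DNA_BASES)) {
    tab[utf8ToInt(DNA_BASES[i])] <- i
    tab[utf8ToInt(tolower(DNA_BASES[i]))] <- i
  }
  tab
})

#' Encode a DNA string as base indices
#'
#' @param x a single character string over the A/C/G/T/N alphabet.
#' @return integer vector, 1..4 for A,C,G,T and NA for N.
#' @keywords internal
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  bad <- !(bytes %in% c(
    utf8ToInt("A"), utf8ToInt("C"), utf8ToInt("G"), utf8ToInt("T"),
    utf8ToInt("a"), utf8ToInt("c"), utf8ToInt("g"), utf8ToInt("t"),
    utf8ToInt("N"), utf8ToInt("n")
  ))
  if (any(bad)) {
    stop("sequence contains characters outside the A/C/G/T/N alphabet: ",
         paste(unique(rawToChar(as.raw(bytes[bad]), multiple = TRUE)),
               collapse = ", "))
  }
  .base_code_table[bytes]
}

# coerce character vector / DNAStringSet to a named character vector
.as_dna_character <- function(sequences) {
  if (is(sequences, "DNAStringSet") || is(sequences, "XStringSet")) {
    out <- as.character(sequences)
  } else if (is.character(sequences)) {
    out <- sequences
  } else {
    stop("sequences must be a character vector or a DNAStringSet")
  }
  if (length(out) > 0 && is.null(names(out))) {
    names(out) <- paste0("seq", seq_along(out))
  }
  out
}

#' Draw a reproducible sub-seed from a master seed
#'
#' Deterministically derives distinct 31-bit seeds for independent
#' simulation components so that one user-facing seed controls everything.
#'
#' @param seed master integer seed.
#' @param k component index.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647L)
}

# run expr under a local RNG seed without clobbering the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
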