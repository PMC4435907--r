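# --- codon machinery shared by the branch models and the simulator ---

# 64 codons in A,C,G,T nested order; 61 sense codons under the standard code
CODONS64 <- local({
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
})
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(CODONS64, STOP_CODONS)
N_SENSE <- length(SENSE_CODONS)  # 61

# amino acid per sense codon (standard genetic code)
CODON_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  unname(gc[SENSE_CODONS])
})

# pairwise structure of single-nucleotide changes between sense codons:
# $single  logical 61x61, exactly one differing position
# $ts      logical, that change is a transition (A<->G, C<->T)
# $nonsyn  logical, amino acid changes
.codon_pair_structure <- local({
  n <- N_SENSE
  splitmat <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  single <- matrix(FALSE, n, n)
  ts <- matrix(FALSE, n, n)
  nonsyn <- matrix(FALSE, n, n)
  is_ts <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "T") | (a == "T" & b == "C")
  }
  for (i in seq_len(n)) {
    diffs <- sweep(splitmat, 2, splitmat[i, ], "!=")
    ndiff <- rowSums(diffs)
    j1 <- which(ndiff == 1)
    single[i, j1] <- TRUE
    for (j in j1) {
      pos <- which(diffs[j, ])
      ts[i, j] <- is_ts(splitmat[i, pos], splitmat[j, pos])
      nonsyn[i, j] <- CODON_AA[i] != CODON_AA[j]
    }
  }
  list(single = single, ts = ts, nonsyn = nonsyn)
})

#' Translate an in-frame coding sequence
#'
#' Standard genetic code.  Fully gapped codons (`---`) translate to the
#' gap residue `-`; codons containing `N` translate to `X`; a trailing
#' stop codon is dropped; an internal stop codon is an error.
#'
#' @param cds a single DNA string whose length is divisible by 3.
#' @return a protein string.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("partial codon: length not divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc <- Biostrings::GENETIC_CODE
  aa <- vapply(codons, function(cd) {
    if (cd == "---") return("-")
    if (grepl("-", cd)) stop("partial codon gap in ", cd)
    if (grepl("N", cd)) return("X")
    r <- gc[[cd]]
    if (is.null(r)) stop("unrecognized codon ", cd)
    r
  }, character(1), USE.NAMES = FALSE)
  if (length(aa) > 0 && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1])
  }
  paste(aa, collapse = "")
}

#' Read an in-frame codon alignment from FASTA
#'
#' @param path FASTA file of aligned coding sequences.
#' @return named character vector of aligned sequences.
#' @export
read_codon_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  aln <- setNames(toupper(as.character(x)), names(x))
  validate_codon_alignment(aln)
  aln
}

#' Validate a codon alignment
#'
#' Checks equal row lengths, length divisible by 3, and absence of
#' internal stop codons in ungapped codons.
#'
#' @param aln named character vector of aligned CDS.
#' @return the alignment, invisibly.
#' @export
validate_codon_alignment <- function(aln) {
  if (length(unique(nchar(aln))) != 1) stop("alignment rows differ in length")
  if (nchar(aln[1]) %% 3 != 0) stop("alignment length not divisible by 3")
  for (nm in names(aln)) {
    s <- aln[[nm]]
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    ungapped <- !grepl("-", codons) & !grepl("N", codons)
    stops <- which(codons %in% STOP_CODONS & ungapped)
    stops <- stops[stops < length(codons)]
    if (length(stops) > 0) {
      stop("internal stop codon in ", nm, " at codon ", stops[1])
    }
  }
  invisible(aln)
}

# alignment -> integer codon matrix (ntaxa x ncodon), 1..61 sense index,
# 0 = missing (gap / ambiguous / terminal stop)
.codon_index_matrix <- function(aln) {
  validate_codon_alignment(aln)
  nc <- nchar(aln[[1]]) / 3
  idx <- matrix(0L, nrow = length(aln), ncol = nc,
                dimnames = list(names(aln), NULL))
  lookup <- setNames(seq_len(N_SENSE), SENSE_CODONS)
  for (i in seq_along(aln)) {
    codons <- substring(aln[[i]], seq(1, nchar(aln[[i]]), 3),
                        seq(3, nchar(aln[[i]]), 3))
    m <- lookup[codons]
    m[is.na(m)] <- 0L
    idx[i, ] <- m
  }
  idx
}

#' Amino-acid alignment conservation summary
#'
#' A column is identical iff all non-gap residues agree across all
#' taxa.  With a two-group partition, a column is reported as
#' "conserved in A, different in B" when it is identical within group A
#' but either variable within group B or fixed in B for a different
#' residue than A's.
#'
#' @param aa_alignment named character vector (or `AAStringSet`) of
#'   aligned protein sequences.
#' @param region length-2 integer (first, last column, 1-based,
#'   inclusive); default the whole alignment.
#' @param groups optional named list of taxon-name vectors partitioning
#'   the taxa.
#' @return an object of class `conservation_summary` with fields
#'   `region`, `n_columns`, `n_identical`, `n_variable`,
#'   `percent_identity`, and (when `groups` given) `group_sites`, a list
#'   of column indices named `conserved_<A>_different_<B>`.
#' @export
conservation_summary <- function(aa_alignment, region = NULL, groups = NULL) {
  if (is(aa_alignment, "AAStringSet") || is(aa_alignment, "XStringSet")) {
    aa_alignment <- setNames(as.character(aa_alignment), names(aa_alignment))
  }
  if (length(unique(nchar(aa_alignment))) != 1) {
    stop("alignment rows differ in length")
  }
  W <- nchar(aa_alignment[[1]])
  if (is.null(region)) region <- c(1L, W)
  if (region[1] < 1 || region[2] > W || region[1] > region[2]) {
    stop("region outside alignment")
  }
  chars <- do.call(rbind, strsplit(unname(aa_alignment), ""))
  rownames(chars) <- names(aa_alignment)
  cols <- region[1]:region[2]
  ident_within <- function(rows, j) {
    v <- chars[rows, j]
    v <- v[v != "-"]
    length(unique(v)) <= 1
  }
  residue_of <- function(rows, j) {
    v <- chars[rows, j]
    v <- v[v != "-"]
    if (length(v) == 0) NA_character_ else v[1]
  }
  all_rows <- rownames(chars)
  identical_col <- vapply(cols, function(j) ident_within(all_rows, j),
                          logical(1))
  n_ident <- sum(identical_col)
  out <- list(
    region = region,
    n_columns = length(cols),
    n_identical = n_ident,
    n_variable = length(cols) - n_ident,
    percent_identity = round(100 * n_ident / length(cols), 2)
  )
  if (!is.null(groups)) {
    if (any(lengths(groups) == 0)) stop("empty group")
    if (!setequal(unlist(groups), all_rows)) {
      stop("groups must partition the alignment taxa")
    }
    gs <- list()
    gn <- names(groups)
    for (a in gn) for (b in setdiff(gn, a)) {
      sel <- vapply(cols, function(j) {
        if (!ident_within(groups[[a]], j)) return(FALSE)
        ra <- residue_of(groups[[a]], j)
        if (!ident_within(groups[[b]], j)) return(TRUE)
        rb <- residue_of(groups[[b]], j)
        !is.na(ra) && !is.na(rb) && ra != rb
      }, logical(1))
      gs[[paste0("conserved_", a, "_different_", b)]] <- cols[sel]
    }
    out$group_sites <- gs
  }
  structure(out, class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf(
    "Columns %d-%d: %d identical, %d variable (%.2f%% identity)\n",
    x$region[1], x$region[2], x$n_identical, x$n_variable,
    x$percent_identity))
  if (!is.null(x$group_sites)) {
    for (nm in names(x$group_sites)) {
      cat(nm, ":", length(x$group_sites[[nm]]), "site(s)\n")
    }
  }
  invisible(x)
}
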