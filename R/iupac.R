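#' @useDynLib carpassay, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats ppois rbinom runif setNames
#' @importFrom utils read.table write.table head
NULL

# IUPAC nucleotide code expansions (degenerate primer semantics)
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Does an IUPAC code match a concrete base?
#'
#' Matching is asymmetric: `code` may be degenerate, `base` must be a concrete
#' nucleotide. A template `N` therefore never matches (it is not in any
#' expansion set by this definition of "concrete").
#'
#' @param code Single IUPAC character (primer side).
#' @param base Single concrete base, one of A/C/G/T (template side).
#' @return `TRUE` iff `base` is in the expansion of `code`.
#' @export
#' @examples
#' iupac_match("Y", "C")  # TRUE
#' iupac_match("Y", "A")  # FALSE
iupac_match <- function(code, base) {
  exp <- IUPAC_CODES[[toupper(code)]]
  if (is.null(exp)) stop("invalid IUPAC code: ", code)
  if (!base %in% c("A", "C", "G", "T")) {
    if (base %in% names(IUPAC_CODES)) return(FALSE)  # ambiguous template base fails
    stop("invalid template base: ", base)
  }
  base %in% exp
}

#' A degenerate PCR primer
#'
#' @param name Primer name.
#' @param sequence IUPAC string; whitespace is stripped (published primer
#'   strings sometimes carry line-break spaces).
#' @param orientation "forward" or "reverse".
#' @return Object of class `degenerate_primer`.
#' @export
degenerate_primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0)
    stop("primer '", name, "' contains non-IUPAC characters: ",
         paste(unique(bad), collapse = ", "))
  if (nchar(sequence) < 10)
    stop("primer '", name, "' is shorter than 10 nt")
  structure(list(name = name, sequence = sequence, orientation = orientation),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s) 5'-%s-3' [degeneracy %d]\n",
              x$name, x$orientation, x$sequence, degeneracy(x)))
  invisible(x)
}

#' Number of concrete sequences a degenerate primer expands to
#'
#' @param primer A [degenerate_primer()].
#' @return Product of per-position expansion-set sizes.
#' @export
degeneracy <- function(primer) {
  chars <- strsplit(primer$sequence, "")[[1]]
  prod(vapply(chars, function(ch) length(IUPAC_CODES[[ch]]), integer(1)))
}

#' Enumerate all concrete expansions of a degenerate primer
#'
#' @param primer A [degenerate_primer()].
#' @return Character vector of all ACGT sequences the primer can assume.
#' @export
expand_primer <- function(primer) {
  chars <- strsplit(primer$sequence, "")[[1]]
  sets <- lapply(chars, function(ch) IUPAC_CODES[[ch]])
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste0, collapse = "")
}

# reverse complement preserving IUPAC degeneracy (via Biostrings)
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# count IUPAC mismatches of a primer against a same-length concrete template
# chunk; vectorised over `chunks`. Template N counts as a mismatch.
primer_mismatches <- function(primer_seq, chunks) {
  pm <- strsplit(primer_seq, "")[[1]]
  allowed <- lapply(pm, function(ch) IUPAC_CODES[[ch]])
  n <- nchar(primer_seq)
  out <- integer(length(chunks))
  full <- nchar(chunks) == n
  if (any(full)) {
    m <- matrix(unlist(strsplit(chunks[full], "")), nrow = n)
    mism <- integer(sum(full))
    for (i in seq_len(n)) mism <- mism + !(m[i, ] %in% allowed[[i]])
    out[full] <- mism
  }
  out[!full] <- n  # too short to contain the primer: everything mismatches
  out
}

#' Default assay primers
#'
#' The degenerate cytochrome-b primer pair of the targeted invasive-carp
#' assay (forward degeneracy 48, reverse degeneracy 16), amplifying a 135 nt
#' diagnostic insert.
#'
#' @return List with elements `forward` and `reverse`.
#' @export
assay_primers <- function() {
  list(
    forward = degenerate_primer("carp_cytb_F", "TGATGAAAYTTYGGMTCYCTHCTAGG", "forward"),
    reverse = degenerate_primer("carp_cytb_R", "AARAAGAATGATGCYCCRTTRGC", "reverse")
  )
}
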