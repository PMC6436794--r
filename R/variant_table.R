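#' Parse a haplotype variant-key table
#'
#' Reads the TSV variant key describing mitochondrial haplotypes as
#' substitutions relative to a reference haplotype. The format is:
#' `#segment <name> <length>` header lines (one per gene segment), a column
#' header row (`label`, then `<segment>:<pos>` columns with 1-based
#' gene-relative positions), and one row per haplotype where `.` means
#' "same allele as the reference haplotype" (the first body row).
#'
#' @param path Path to a TSV file, or `NULL` when `text` is given.
#' @param text Character scalar with the TSV content (alternative to `path`).
#' @return Object of class `variant_table` with fields `segments` (named
#'   integer vector of segment lengths, in declaration order), `reference`
#'   (label of the reference haplotype), `sites` (data.frame with `segment`,
#'   `pos`), `calls` (character matrix haplotypes x sites, concrete alleles).
#' @export
parse_variant_table <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    lines <- readLines(path)
  } else {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  lines <- lines[nzchar(trimws(lines))]
  seg_lines <- grep("^#segment\t", lines, value = TRUE)
  if (length(seg_lines) == 0) stop("no '#segment' header lines found")
  segs <- do.call(rbind, strsplit(seg_lines, "\t"))
  segments <- setNames(as.integer(segs[, 3]), segs[, 2])
  if (anyDuplicated(names(segments))) stop("duplicate segment declarations")
  if (any(is.na(segments)) || any(segments < 1)) stop("invalid segment lengths")

  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "label") stop("first header column must be 'label'")
  site_ids <- header[-1]
  parts <- strsplit(site_ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("site columns must be '<segment>:<pos>'")
  sites <- data.frame(segment = vapply(parts, `[`, "", 1),
                      pos = as.integer(vapply(parts, `[`, "", 2)),
                      stringsAsFactors = FALSE)
  unknown <- setdiff(unique(sites$segment), names(segments))
  if (length(unknown) > 0) stop("undeclared segment(s): ", paste(unknown, collapse = ", "))
  for (sg in unique(sites$segment)) {
    p <- sites$pos[sites$segment == sg]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing within segment '", sg, "'")
    if (any(p > segments[[sg]]))
      stop("position exceeds declared length of segment '", sg, "'")
    if (any(p < 1)) stop("positions must be >= 1")
  }

  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  if (length(rows) == 0) stop("no haplotype rows")
  labels <- vapply(rows, `[`, "", 1)
  if (anyDuplicated(labels)) stop("duplicate haplotype labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  nsite <- nrow(sites)
  calls <- matrix("", nrow = length(labels), ncol = nsite,
                  dimnames = list(labels, site_ids))
  ref_label <- labels[1]
  ref_alleles <- toupper(rows[[1]][-1])
  if (length(ref_alleles) != nsite)
    stop("reference row '", ref_label, "' has ", length(ref_alleles),
         " entries; expected ", nsite)
  bad <- which(!ref_alleles %in% c("A", "C", "G", "T"))
  if (length(bad) > 0)
    stop("reference row '", ref_label, "': invalid allele '", ref_alleles[bad[1]],
         "' in column ", site_ids[bad[1]])
  calls[1, ] <- ref_alleles
  for (i in seq_along(rows)[-1]) {
    vals <- toupper(rows[[i]][-1])
    if (length(vals) != nsite)
      stop("row '", labels[i], "' has ", length(vals), " entries; expected ", nsite)
    bad <- which(!vals %in% c("A", "C", "G", "T", "."))
    if (length(bad) > 0)
      stop("row '", labels[i], "': invalid allele '", vals[bad[1]],
           "' in column ", site_ids[bad[1]])
    vals[vals == "."] <- ref_alleles[vals == "."]
    calls[i, ] <- vals
  }
  if (nrow(calls) > 1) {
    key <- apply(calls, 1L, paste0, collapse = "")
    if (anyDuplicated(key))
      stop("haplotype rows not pairwise distinct: ",
           paste(rownames(calls)[duplicated(key) | duplicated(key, fromLast = TRUE)],
                 collapse = ", "))
  }
  structure(list(segments = segments, reference = ref_label,
                 sites = sites, calls = calls),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d haplotypes x %d variant positions (%s); reference '%s'\n",
              nrow(x$calls), nrow(x$sites),
              paste(sprintf("%s: %d", names(x$segments),
                            vapply(names(x$segments),
                                   function(s) sum(x$sites$segment == s), 0L)),
                    collapse = ", "),
              x$reference))
  invisible(x)
}

#' Serialise a variant table back to its TSV form
#'
#' @param vt A `variant_table`.
#' @param path Optional output path; when `NULL` the TSV text is returned.
#' @return The TSV content, invisibly when written to `path`.
#' @export
format_variant_table <- function(vt, path = NULL) {
  hdr <- c(sprintf("#segment\t%s\t%d", names(vt$segments), vt$segments),
           paste(c("label", colnames(vt$calls)), collapse = "\t"))
  ref <- vt$calls[vt$reference, ]
  body <- vapply(rownames(vt$calls), function(lab) {
    v <- vt$calls[lab, ]
    if (lab != vt$reference) v[v == ref] <- "."
    paste(c(lab, v), collapse = "\t")
  }, "")
  out <- paste(c(hdr, body), collapse = "\n")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

#' The packaged silver carp variant key
#'
#' Concatenated cytochrome-b / COI haplotype key for the eight North American
#' silver carp haplotypes A-H (haplotype H is the highly divergent putative
#' largescale silver carp introgression).
#'
#' @return A `variant_table` with 8 haplotypes over 58 variant positions.
#' @export
silver_carp_variants <- function() {
  parse_variant_table(system.file("extdata", "silver_carp_haplotypes.tsv",
                                  package = "carpassay", mustWork = TRUE))
}
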