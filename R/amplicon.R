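#' Amplicon definition: primer pair plus expected insert
#'
#' @param forward,reverse [degenerate_primer()] objects. Defaults are the
#'   assay's cytochrome-b pair.
#' @param insert_window [diagnostic_window()] the insert occupies on the
#'   reference gene.
#' @param expected_insert_length Insert length in nt; must equal the window
#'   length (135 by default).
#' @return Object of class `amplicon_definition`.
#' @export
amplicon_definition <- function(forward = assay_primers()$forward,
                                reverse = assay_primers()$reverse,
                                insert_window = diagnostic_window(),
                                expected_insert_length = window_length(insert_window)) {
  if (expected_insert_length != window_length(insert_window))
    stop("expected_insert_length (", expected_insert_length,
         ") != window length (", window_length(insert_window), ")")
  structure(list(forward = forward, reverse = reverse,
                 insert_window = insert_window,
                 expected_insert_length = as.integer(expected_insert_length)),
            class = "amplicon_definition")
}

#' Find degenerate-primer binding sites on a sequence
#'
#' Slides the primer (plus strand) and its reverse complement (minus strand)
#' along a concrete template, counting IUPAC mismatches; template `N` fails
#' all matches.
#'
#' @param seq Template sequence (ACGTN string).
#' @param primer A [degenerate_primer()].
#' @param max_mismatch Maximum mismatches allowed (default 0).
#' @return data.frame with `start` (1-based), `strand` ("+"/"-"),
#'   `mismatches`, sorted by start. Zero rows when absent.
#' @export
find_primer_sites <- function(seq, primer, max_mismatch = 0L) {
  stopifnot(max_mismatch >= 0)
  seq <- toupper(seq)
  scan_one <- function(pat, strand) {
    k <- nchar(pat)
    n <- nchar(seq)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    chunks <- substring(seq, starts, starts + k - 1L)
    mm <- primer_mismatches(pat, chunks)
    hit <- which(mm <= max_mismatch)
    if (length(hit) == 0) return(NULL)
    data.frame(start = starts[hit], strand = strand, mismatches = mm[hit],
               stringsAsFactors = FALSE)
  }
  out <- rbind(scan_one(primer$sequence, "+"),
               scan_one(revcomp(primer$sequence), "-"))
  if (is.null(out))
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-silico PCR: extract the amplicon insert from a reference haplotype
#'
#' Locates the forward primer on the plus strand and the reverse primer on
#' the minus strand (i.e. its reverse complement downstream on the plus
#' strand) and returns the bases strictly between them.
#'
#' @param reference A [haplotype()] carrying the target segment.
#' @param amp An [amplicon_definition()].
#' @param max_mismatch Mismatches tolerated at each primer site (default 0:
#'   panel references are expected to carry exact sites).
#' @return List with `sequence`, `segment`, `start`, `end` (1-based inclusive
#'   insert coordinates on the reference).
#' @export
extract_insert <- function(reference, amp, max_mismatch = 0L) {
  seg <- amp$insert_window$segment
  seq <- reference$segments[[seg]]
  if (is.null(seq))
    stop("reference '", reference$label, "' lacks segment '", seg, "'")
  fw_all <- find_primer_sites(seq, amp$forward, max_mismatch)
  rv_all <- find_primer_sites(seq, amp$reverse, max_mismatch)
  pick1 <- function(hits, primer) {
    if (nrow(hits) == 0)
      stop("extraction error: no site for primer '", primer$name, "'")
    if (nrow(hits) > 1)
      stop("extraction error: multiple sites for primer '", primer$name, "'")
    hits
  }
  if (any(fw_all$strand == "+")) {
    # plus orientation: forward primer 5' of the insert, reverse primer's
    # reverse complement 3' of it
    fw <- pick1(fw_all[fw_all$strand == "+", , drop = FALSE], amp$forward)
    rv <- pick1(rv_all[rv_all$strand == "-" & rv_all$start > fw$start, ,
                       drop = FALSE], amp$reverse)
    ins_start <- fw$start + nchar(amp$forward$sequence)
    ins_end <- rv$start - 1L
  } else {
    # minus orientation (reverse-complemented reference): roles mirror
    fw <- pick1(fw_all[fw_all$strand == "-", , drop = FALSE], amp$forward)
    rv <- pick1(rv_all[rv_all$strand == "+" & rv_all$start < fw$start, ,
                       drop = FALSE], amp$reverse)
    ins_start <- rv$start + nchar(amp$reverse$sequence)
    ins_end <- fw$start - 1L
  }
  if (ins_end < ins_start) stop("extraction error: primers overlap or abut")
  list(sequence = substr(seq, ins_start, ins_end),
       segment = seg, start = ins_start, end = ins_end)
}

#' Extract all panel inserts
#'
#' Runs [extract_insert()] over every haplotype of every species and attaches
#' the diagnostic-window class of each haplotype.
#'
#' @param panel A [reference_panel()].
#' @param amp An [amplicon_definition()].
#' @param max_mismatch Passed to [extract_insert()].
#' @return data.frame: `species`, `label`, `class`, `insert`, `start`, `end`.
#' @export
panel_inserts <- function(panel, amp = amplicon_definition(), max_mismatch = 0L) {
  cls <- class_of_label(panel, amp$insert_window)
  rows <- lapply(panel_haplotypes(panel), function(h) {
    ins <- extract_insert(h, amp, max_mismatch)
    data.frame(species = h$species, label = h$label,
               class = cls[[h$species]][[h$label]],
               insert = ins$sequence, start = ins$start, end = ins$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
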