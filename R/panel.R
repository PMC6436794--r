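#' Diagnostic assay window
#'
#' The between-primer insert of the targeted assay, in 1-based inclusive
#' gene-relative coordinates. The default is the 135 nt cytochrome-b insert
#' at positions 115-249, whose variable sites (117-228) discriminate the
#' invasive carps and the silver carp haplotype classes. With this placement
#' the reverse primer occupies 250-272 and its single degenerate R position
#' falls exactly on the polymorphic site 258 (A in most haplotypes, G in the
#' divergent introgressed haplotype), so every haplotype carries an exact
#' primer site - the reading under which the assay is internally consistent.
#'
#' @param segment Segment (gene) name.
#' @param start,end 1-based inclusive bounds.
#' @return Object of class `diagnostic_window`.
#' @export
diagnostic_window <- function(segment = "cytb", start = 115L, end = 249L) {
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 1 && start <= end)) stop("need 1 <= start <= end")
  structure(list(segment = segment, start = start, end = end),
            class = "diagnostic_window")
}

window_length <- function(window) window$end - window$start + 1L

#' A single reconstructed or user-provided haplotype
#'
#' @param label Haplotype label (e.g. "A").
#' @param species Species name.
#' @param segments Named character vector/list of uppercase segment sequences.
#' @param provenance "reconstructed" or "provided".
#' @return Object of class `haplotype`.
#' @export
haplotype <- function(label, species, segments,
                      provenance = c("reconstructed", "provided")) {
  provenance <- match.arg(provenance)
  segments <- vapply(segments, toupper, "")
  bad <- grepl("[^ACGTN]", segments)
  if (any(bad)) stop("haplotype ", label, ": segment(s) ",
                     paste(names(segments)[bad], collapse = ", "),
                     " contain non-ACGTN characters")
  structure(list(label = label, species = species,
                 segments = segments, provenance = provenance),
            class = "haplotype")
}

#' Rebuild full haplotype sequences from a variant key and a backbone
#'
#' Inverts the variant table onto backbone segment sequences: each haplotype
#' equals the backbone except at its substitution positions. The backbone must
#' carry the reference haplotype's allele at every variant position.
#'
#' @param vt A [parse_variant_table()] result.
#' @param backbone Named character vector/list of segment sequences whose
#'   lengths match the table's segment declarations.
#' @param species Species name attached to the haplotypes.
#' @return List of [haplotype()] objects, in the table's row order.
#' @export
reconstruct_haplotypes <- function(vt, backbone, species = "silver carp") {
  backbone <- vapply(backbone, toupper, "")
  missing <- setdiff(names(vt$segments), names(backbone))
  if (length(missing) > 0)
    stop("backbone lacks segment(s): ", paste(missing, collapse = ", "))
  for (sg in names(vt$segments)) {
    if (nchar(backbone[[sg]]) != vt$segments[[sg]])
      stop("backbone segment '", sg, "' has length ", nchar(backbone[[sg]]),
           "; declared ", vt$segments[[sg]])
  }
  ref <- vt$calls[vt$reference, ]
  bb_at <- vapply(seq_len(nrow(vt$sites)), function(i) {
    substr(backbone[[vt$sites$segment[i]]], vt$sites$pos[i], vt$sites$pos[i])
  }, "")
  conflict <- which(bb_at != ref)
  if (length(conflict) > 0)
    stop("backbone disagrees with reference alleles at: ",
         paste(colnames(vt$calls)[conflict], collapse = ", "))
  lapply(rownames(vt$calls), function(lab) {
    segs <- backbone[names(vt$segments)]
    for (i in seq_len(nrow(vt$sites))) {
      sg <- vt$sites$segment[i]
      substr(segs[[sg]], vt$sites$pos[i], vt$sites$pos[i]) <- vt$calls[lab, i]
    }
    haplotype(lab, species, segs, "reconstructed")
  })
}

#' Re-derive a variant key from reconstructed haplotypes
#'
#' Inverse of [reconstruct_haplotypes()]: compares every haplotype of one
#' species to a reference haplotype and records all differing positions.
#' Useful to verify the parse -> reconstruct round trip.
#'
#' @param haps List of [haplotype()] objects sharing segment lengths.
#' @param reference Label of the reference haplotype (defaults to the first).
#' @return A `variant_table`.
#' @export
derive_variant_table <- function(haps, reference = haps[[1]]$label) {
  labels <- vapply(haps, function(h) h$label, "")
  ref_h <- haps[[match(reference, labels)]]
  seg_names <- names(ref_h$segments)
  segments <- setNames(vapply(ref_h$segments, nchar, 0L), seg_names)
  # union of differing positions across all haplotypes
  site_list <- list()
  for (sg in seg_names) {
    refc <- strsplit(ref_h$segments[[sg]], "")[[1]]
    diffpos <- sort(unique(unlist(lapply(haps, function(h) {
      which(strsplit(h$segments[[sg]], "")[[1]] != refc)
    }))))
    if (length(diffpos) > 0)
      site_list[[sg]] <- data.frame(segment = sg, pos = diffpos,
                                    stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_list)
  rownames(sites) <- NULL
  site_ids <- sprintf("%s:%d", sites$segment, sites$pos)
  calls <- matrix("", nrow = length(haps), ncol = nrow(sites),
                  dimnames = list(labels, site_ids))
  for (j in seq_len(nrow(sites)))
    calls[, j] <- vapply(haps, function(h)
      substr(h$segments[[sites$segment[j]]], sites$pos[j], sites$pos[j]), "")
  # put the reference row first, as the TSV format requires
  ord <- c(match(reference, labels), setdiff(seq_along(labels), match(reference, labels)))
  structure(list(segments = segments, reference = reference,
                 sites = sites, calls = calls[ord, , drop = FALSE]),
            class = "variant_table")
}

#' A reference panel of haplotypes grouped by species
#'
#' @param ... Named arguments: `species = list of haplotypes`, or a single
#'   list of haplotypes whose `species` fields are used.
#' @param metadata Free-form provenance description.
#' @return Object of class `reference_panel`.
#' @export
reference_panel <- function(..., metadata = character()) {
  args <- list(...)
  entries <- list()
  add <- function(h) {
    sp <- h$species
    labs <- vapply(entries[[sp]], function(x) x$label, character(1))
    if (h$label %in% labs)
      stop("duplicate haplotype label '", h$label, "' for species '", sp, "'")
    entries[[sp]] <<- c(entries[[sp]], list(h))
  }
  for (a in args) {
    if (inherits(a, "haplotype")) add(a)
    else for (h in a) add(h)
  }
  for (sp in names(entries)) {
    lens <- unique(lapply(entries[[sp]], function(h) vapply(h$segments, nchar, 0L)))
    if (length(lens) > 1)
      stop("haplotypes of species '", sp, "' have differing segment lengths")
    # deterministic ordering everywhere: labels sorted lexicographically
    ord <- order(vapply(entries[[sp]], function(h) h$label, ""))
    entries[[sp]] <- entries[[sp]][ord]
  }
  if (length(entries) > 0) entries <- entries[order(names(entries))]
  structure(list(entries = entries, metadata = metadata),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel>\n")
  for (sp in names(x$entries))
    cat(sprintf("  %s: %s\n", sp,
                paste(vapply(x$entries[[sp]], function(h) h$label, ""), collapse = " ")))
  invisible(x)
}

panel_haplotypes <- function(panel) {
  unlist(lapply(names(panel$entries), function(sp) panel$entries[[sp]]),
         recursive = FALSE)
}

window_slice <- function(hap, window) {
  seq <- hap$segments[[window$segment]]
  if (is.null(seq)) stop("haplotype ", hap$label, " lacks segment '", window$segment, "'")
  substr(seq, window$start, min(window$end, nchar(seq)))
}

#' Hamming distance between two haplotypes
#'
#' Counts differing positions over all segments, or restricted to a
#' [diagnostic_window()]. Sequences must have equal segment lengths.
#'
#' @param h1,h2 [haplotype()] objects.
#' @param window Optional `diagnostic_window`.
#' @return Non-negative integer.
#' @export
hamming_distance <- function(h1, h2, window = NULL) {
  if (!is.null(window)) {
    a <- window_slice(h1, window); b <- window_slice(h2, window)
    if (nchar(a) != nchar(b)) stop("window slices differ in length")
    return(hamming_cpp(a, b))
  }
  segs <- union(names(h1$segments), names(h2$segments))
  total <- 0L
  for (sg in segs) {
    a <- h1$segments[[sg]]; b <- h2$segments[[sg]]
    if (is.null(a) || is.null(b)) stop("segment '", sg, "' missing from one haplotype")
    if (nchar(a) != nchar(b))
      stop("segment '", sg, "' lengths differ: ", nchar(a), " vs ", nchar(b))
    total <- total + hamming_cpp(a, b)
  }
  total
}

#' Pairwise Hamming distance matrix over a panel
#'
#' @param panel A [reference_panel()].
#' @param window Optional `diagnostic_window` restricting the comparison.
#' @return Symmetric integer matrix labelled `species|label`.
#' @export
distance_matrix <- function(panel, window = NULL) {
  haps <- panel_haplotypes(panel)
  if (length(haps) == 0) stop("empty panel")
  labs <- vapply(haps, function(h) paste0(h$species, "|", h$label), "")
  n <- length(haps)
  m <- matrix(0L, n, n, dimnames = list(labs, labs))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- hamming_distance(haps[[i]], haps[[j]], window)
      m[i, j] <- d; m[j, i] <- d
    }
  }
  m
}

#' Collapse haplotypes into diagnostic-window equivalence classes
#'
#' Two haplotypes of a species fall in the same class iff their windowed
#' Hamming distance is zero, i.e. the assay cannot tell them apart. Class
#' names join member labels with "/" in alphabetical order (e.g. "A/C").
#'
#' @param panel A [reference_panel()].
#' @param window A `diagnostic_window` (default: the assay insert).
#' @return Named list: species -> character vector of class names.
#' @export
collapse_classes <- function(panel, window = diagnostic_window()) {
  out <- list()
  for (sp in names(panel$entries)) {
    haps <- panel$entries[[sp]]
    keys <- vapply(haps, function(h) window_slice(h, window), "")
    labs <- vapply(haps, function(h) h$label, "")
    cls <- vapply(split(labs, keys), function(v)
      paste(sort(v), collapse = "/"), "")
    out[[sp]] <- sort(unname(cls))
  }
  out
}

#' Map each haplotype label to its diagnostic-window class name
#'
#' @inheritParams collapse_classes
#' @return Named list: species -> named character vector label -> class.
#' @export
class_of_label <- function(panel, window = diagnostic_window()) {
  out <- list()
  for (sp in names(panel$entries)) {
    haps <- panel$entries[[sp]]
    keys <- vapply(haps, function(h) window_slice(h, window), "")
    labs <- vapply(haps, function(h) h$label, "")
    cls <- vapply(split(labs, keys), function(v) paste(sort(v), collapse = "/"), "")
    out[[sp]] <- setNames(cls[match(keys, names(cls))], labs)
  }
  out
}

#' Write a panel to FASTA (+ JSON manifest)
#'
#' Record ids are `species|label|segment`.
#'
#' @param panel A [reference_panel()].
#' @param fasta Output FASTA path.
#' @param manifest Optional JSON manifest path.
#' @export
write_panel_fasta <- function(panel, fasta, manifest = NULL) {
  haps <- panel_haplotypes(panel)
  seqs <- unlist(lapply(haps, function(h) {
    setNames(as.character(h$segments),
             sprintf("%s|%s|%s", h$species, h$label, names(h$segments)))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  if (!is.null(manifest)) {
    info <- lapply(haps, function(h)
      list(species = h$species, label = h$label,
           segments = as.list(vapply(h$segments, nchar, 0L)),
           provenance = h$provenance))
    jsonlite::write_json(info, manifest, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(fasta)
}

#' Read a panel from FASTA written by [write_panel_fasta()]
#'
#' @param fasta FASTA path with `species|label|segment` record ids.
#' @return A [reference_panel()].
#' @export
read_panel_fasta <- function(fasta) {
  ss <- Biostrings::readDNAStringSet(fasta)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop("panel FASTA ids must be 'species|label|segment'")
  key <- vapply(parts, function(p) paste(p[1], p[2], sep = "|"), "")
  haps <- lapply(split(seq_along(ss), key), function(idx) {
    p <- parts[[idx[1]]]
    segs <- setNames(as.character(ss[idx]), vapply(parts[idx], `[`, "", 3))
    haplotype(p[2], p[1], segs, "provided")
  })
  reference_panel(unname(haps))
}
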