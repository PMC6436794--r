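#' Calibrate the erroneous-ASV cutoff from positive controls
#'
#' Any positive-control ASV whose sequence is not exactly one of the expected
#' control sequences is erroneous (PCR/sequencing error or undetected
#' mis-assignment). The largest single erroneous-ASV fraction observed across
#' all positive controls of the run becomes the run's detection cutoff.
#'
#' @param tab An [asv_table()] covering the run.
#' @param pc_samples Character vector of positive-control sample ids.
#' @param expected_sequences Character vector of the control taxa's insert
#'   sequences.
#' @return Object of class `run_calibration`: `cutoff_fraction`, `evidence`
#'   (data.frame sample_id, total, max_erroneous_count, max_erroneous_fraction).
#' @export
calibrate <- function(tab, pc_samples, expected_sequences) {
  stopifnot(length(pc_samples) >= 1, length(expected_sequences) >= 1)
  missing <- setdiff(pc_samples, colnames(tab$counts))
  if (length(missing) > 0)
    stop("positive control(s) absent from table: ", paste(missing, collapse = ", "))
  evidence <- do.call(rbind, lapply(pc_samples, function(s) {
    cnt <- tab$counts[, s]
    total <- sum(cnt)
    if (total == 0) stop("positive control '", s, "' has no reads")
    err <- cnt[!(tab$seq %in% expected_sequences)]
    mx <- if (length(err) > 0) max(err) else 0L
    data.frame(sample_id = s, total = total, max_erroneous_count = mx,
               max_erroneous_fraction = mx / total, stringsAsFactors = FALSE)
  }))
  structure(list(cutoff_fraction = max(evidence$max_erroneous_fraction),
                 evidence = evidence),
            class = "run_calibration")
}

#' @export
print.run_calibration <- function(x, ...) {
  cat(sprintf("<run_calibration> cutoff = %.4f%% over %d positive control(s)\n",
              100 * x$cutoff_fraction, nrow(x$evidence)))
  invisible(x)
}

#' Check a no-template control
#'
#' A run's NTC passes when its verified-read count (reads surviving
#' spacer/primer/length checks, from the filter ledger) does not exceed
#' `max_reads`. Raw reads that were all rejected at verification (hops,
#' dimers) do not fail an NTC.
#'
#' @param ledger Filter ledger data.frame from [run_reads()].
#' @param ntc_sample NTC sample id.
#' @param max_reads Allowance (default 0).
#' @return "pass" or "fail".
#' @export
check_ntc <- function(ledger, ntc_sample, max_reads = run_config()$ntc_max_reads) {
  row <- ledger[ledger$sample_id == ntc_sample, ]
  if (nrow(row) != 1) stop("NTC '", ntc_sample, "' not found in ledger")
  if (row$verified > max_reads) "fail" else "pass"
}

#' Apply the calibrated cutoff to one sample
#'
#' An ASV is retained iff its fraction of the sample's reads is greater than
#' or equal to the cutoff; below-cutoff ASVs are returned too, for divergence
#' flagging rather than silent deletion.
#'
#' @param tab An [asv_table()].
#' @param sample Sample id.
#' @param cal A [calibrate()] result (or a bare cutoff fraction).
#' @param total Denominator for fractions; defaults to the sample's column
#'   sum. Pass the sample's merged-read total to express fractions of all
#'   merged reads.
#' @return List of data.frames `retained` and `below` (asv_id, sequence,
#'   reads, fraction).
#' @export
apply_cutoff <- function(tab, sample, cal, total = NULL) {
  cutoff <- if (inherits(cal, "run_calibration")) cal$cutoff_fraction else cal
  cnt <- tab$counts[, sample]
  if (is.null(total)) total <- sum(cnt)
  if (total <= 0) stop("sample '", sample, "' has no reads")
  present <- cnt > 0
  df <- data.frame(asv_id = rownames(tab$counts)[present],
                   sequence = unname(tab$seq[present]),
                   reads = unname(cnt[present]),
                   fraction = unname(cnt[present]) / total,
                   stringsAsFactors = FALSE)
  list(retained = df[df$fraction >= cutoff, , drop = FALSE],
       below = df[df$fraction < cutoff, , drop = FALSE])
}

#' Assign an ASV to species and haplotype class by Hamming best match
#'
#' The ASV is compared to every panel insert; the minimum distance defines
#' the best match. Distance 0 is a known haplotype (class = its
#' diagnostic-window class). A distance in (0, novel_max] with a unique best
#' species is a novel within-species haplotype. Ties between species are
#' reported as ambiguous, never resolved. Anything farther (or of a
#' different length) is unassigned.
#'
#' @param seq ASV sequence.
#' @param inserts Insert table from [panel_inserts()] (columns species,
#'   label, class, insert).
#' @param novel_max Maximum distance for a novel call.
#' @return data.frame row: `species`, `haplotype_class`, `label`, `distance`,
#'   `status`.
#' @export
assign_asv <- function(seq, inserts, novel_max = run_config()$novel_max) {
  d <- dist_to_set_cpp(seq, inserts$insert)
  usable <- d >= 0
  una <- data.frame(species = NA_character_, haplotype_class = NA_character_,
                    label = NA_character_, distance = NA_integer_,
                    status = "unassigned", stringsAsFactors = FALSE)
  if (!any(usable)) return(una)
  dmin <- min(d[usable])
  best <- which(usable & d == dmin)
  best_species <- sort(unique(inserts$species[best]))
  if (dmin == 0) {
    if (length(best_species) > 1)
      return(data.frame(species = paste(best_species, collapse = ";"),
                        haplotype_class = NA_character_, label = NA_character_,
                        distance = 0L, status = "ambiguous", stringsAsFactors = FALSE))
    hit <- best[1]  # identical inserts share one class by construction
    return(data.frame(species = inserts$species[hit],
                      haplotype_class = inserts$class[hit],
                      label = paste(sort(inserts$label[best]), collapse = "/"),
                      distance = 0L, status = "known", stringsAsFactors = FALSE))
  }
  if (dmin <= novel_max) {
    if (length(best_species) > 1)
      return(data.frame(species = paste(best_species, collapse = ";"),
                        haplotype_class = NA_character_, label = NA_character_,
                        distance = dmin, status = "ambiguous", stringsAsFactors = FALSE))
    hit <- best[1]
    return(data.frame(species = best_species,
                      haplotype_class = "novel",
                      label = paste(sort(inserts$label[best]), collapse = "/"),
                      distance = dmin, status = "novel", stringsAsFactors = FALSE))
  }
  una$distance <- dmin
  una
}

#' Flag or discard below-cutoff ASVs
#'
#' A below-cutoff ASV is kept as a flagged putative detection
#' (`below_cutoff_flagged`, requiring re-sequencing confirmation) only when
#' it (i) assigns to a panel species (known or novel) and (ii) is farther
#' than `divergence_floor_frac * insert length` nt (strictly more than 10
#' percent of the sequence length by default, i.e. > 13.5 nt for 135 nt)
#' from every retained ASV in the sample - too divergent to be an error off
#' anything retained. Otherwise it is `below_cutoff_removed`.
#'
#' @param below,retained data.frames from [apply_cutoff()].
#' @param inserts Panel insert table.
#' @param cfg A [run_config()].
#' @return `below` with added `species`, `haplotype_class`, `distance`,
#'   `status`, `flag` columns.
#' @export
flag_below_cutoff <- function(below, retained, inserts, cfg = run_config()) {
  if (nrow(below) == 0) {
    below$species <- character(0); below$haplotype_class <- character(0)
    below$distance <- integer(0); below$status <- character(0)
    below$flag <- character(0)
    return(below)
  }
  res <- do.call(rbind, lapply(below$sequence, assign_asv, inserts = inserts,
                               novel_max = cfg$novel_max))
  below <- cbind(below, res[, c("species", "haplotype_class", "distance", "status")])
  floor_nt <- cfg$divergence_floor_frac * nchar(inserts$insert[1])
  divergent <- vapply(below$sequence, function(s) {
    if (nrow(retained) == 0) return(TRUE)
    d <- dist_to_set_cpp(s, retained$sequence)
    all(d < 0 | d > floor_nt)
  }, logical(1))
  below$flag <- ifelse(below$status %in% c("known", "novel") & divergent,
                       "below_cutoff_flagged", "below_cutoff_removed")
  below
}

#' Summarise one sample's assignments into a detection report
#'
#' One row per retained or flagged ASV, with read fractions over the sample's
#' merged-read total. Positive (known/novel) detections are tagged
#' `requires_confirmation`, mirroring confirmation by re-sequencing with
#' non-shared spacers.
#'
#' @param sample Sample id.
#' @param retained Retained set from [apply_cutoff()].
#' @param below Flagged set from [flag_below_cutoff()].
#' @param inserts Panel insert table.
#' @param cfg A [run_config()].
#' @return data.frame: `sample_id`, `species`, `haplotype_class`, `asv_id`,
#'   `reads`, `fraction`, `status`, `flag`.
#' @export
summarize_sample <- function(sample, retained, below, inserts,
                             cfg = run_config()) {
  rows <- NULL
  if (nrow(retained) > 0) {
    res <- do.call(rbind, lapply(retained$sequence, assign_asv,
                                 inserts = inserts, novel_max = cfg$novel_max))
    rows <- data.frame(sample_id = sample, species = res$species,
                       haplotype_class = res$haplotype_class,
                       asv_id = retained$asv_id, reads = retained$reads,
                       fraction = retained$fraction, status = res$status,
                       flag = ifelse(res$status %in% c("known", "novel"),
                                     "requires_confirmation", "none"),
                       stringsAsFactors = FALSE)
  }
  flagged <- below[below$flag == "below_cutoff_flagged", , drop = FALSE]
  if (nrow(flagged) > 0) {
    rows <- rbind(rows, data.frame(
      sample_id = sample, species = flagged$species,
      haplotype_class = flagged$haplotype_class, asv_id = flagged$asv_id,
      reads = flagged$reads, fraction = flagged$fraction,
      status = flagged$status, flag = "below_cutoff_flagged",
      stringsAsFactors = FALSE))
  }
  if (is.null(rows))
    rows <- data.frame(sample_id = character(), species = character(),
                       haplotype_class = character(), asv_id = character(),
                       reads = integer(), fraction = numeric(),
                       status = character(), flag = character(),
                       stringsAsFactors = FALSE)
  rows[order(-rows$reads, rows$asv_id), , drop = FALSE]
}

#' End-to-end detection over a processed run
#'
#' Calibrates on the run's positive controls, checks NTCs, applies the cutoff
#' per field sample, assigns retained ASVs, flags divergent below-cutoff
#' ASVs, and assembles the run-level detection report. Fractions use each
#' sample's merged-read total from the ledger.
#'
#' @param run Result of [run_reads()].
#' @param manifest Manifest data.frame (roles drive calibration/NTC logic).
#' @param inserts Panel insert table from [panel_inserts()].
#' @param expected_control_sequences Insert sequences of the positive-control
#'   taxa.
#' @param cfg A [run_config()].
#' @return List: `calibration`, `ntc_status` (named vector),
#'   `detections` (data.frame), `below` (all below-cutoff rows).
#' @export
detect_run <- function(run, manifest, inserts, expected_control_sequences,
                       cfg = run_config()) {
  tab <- run$table; ledger <- run$ledger
  pc <- manifest$sample_id[manifest$role == "positive_control"]
  ntc <- manifest$sample_id[manifest$role == "ntc"]
  field <- manifest$sample_id[manifest$role == "sample"]
  cal <- calibrate(tab, pc, expected_control_sequences)
  ntc_status <- setNames(vapply(ntc, function(s)
    check_ntc(ledger, s, cfg$ntc_max_reads), ""), ntc)
  detections <- NULL; below_all <- NULL
  for (s in field) {
    total <- ledger$merged[ledger$sample_id == s]
    if (total == 0) next
    cut <- apply_cutoff(tab, s, cal, total = total)
    below <- flag_below_cutoff(cut$below, cut$retained, inserts, cfg)
    detections <- rbind(detections,
                        summarize_sample(s, cut$retained, below, inserts, cfg))
    if (nrow(below) > 0)
      below_all <- rbind(below_all, cbind(sample_id = s, below))
  }
  if (is.null(detections))
    detections <- summarize_sample("none",
                                   data.frame(asv_id = character(), sequence = character(),
                                              reads = integer(), fraction = numeric()),
                                   flag_below_cutoff(
                                     data.frame(asv_id = character(), sequence = character(),
                                                reads = integer(), fraction = numeric()),
                                     data.frame(sequence = character()), inserts, cfg),
                                   inserts, cfg)[0, ]
  list(calibration = cal, ntc_status = ntc_status,
       detections = detections, below = below_all)
}
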