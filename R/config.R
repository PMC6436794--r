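#' Pipeline run configuration
#'
#' All tunable parameters of the read pipeline and detection stage, with the
#' package defaults. Serialises losslessly to/from YAML.
#'
#' @param primer_mismatch IUPAC mismatches tolerated when locating a template
#'   primer on a read (spacers are always compared exactly).
#' @param min_mate_template Pre-merge floor: each mate's trimmed template must
#'   be at least this many nt. `NA` (the default) derives it as
#'   `ceiling((expected_insert_length + min_overlap) / 2)` - the smallest mate
#'   length at which a pair can still span the full insert with the required
#'   overlap (78 nt for the 135 nt assay). Primer dimers fall far below it.
#' @param merged_length_tol Post-merge tolerance on
#'   `|merged length - expected_insert_length|` (0 = exact).
#' @param min_overlap Minimum ungapped mate overlap in nt.
#' @param max_overlap_mismatch Maximum mismatch fraction inside the overlap.
#' @param error_rate Assumed per-base substitution error rate for denoising.
#' @param alpha Poisson-tail significance: a minor variant is kept as real
#'   only when the probability of seeing at least its count from errors off
#'   its best parent is <= alpha.
#' @param chimera_fold Minimum abundance fold of both parents over a putative
#'   chimera.
#' @param novel_max Maximum Hamming distance from the best panel haplotype
#'   for a "novel" (within-species) haplotype call.
#' @param divergence_floor_frac Below-cutoff ASVs are flagged as putative
#'   detections only when farther than `ceil(frac * insert length)` nt from
#'   every retained ASV of the sample (the >10 percent-of-length rule).
#' @param ntc_max_reads Maximum verified reads a no-template control may show
#'   and still pass.
#' @param seed Seed threaded through any stochastic step.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(primer_mismatch = 2L,
                       min_mate_template = NA_integer_,
                       merged_length_tol = 0L,
                       min_overlap = 20L,
                       max_overlap_mismatch = 0.1,
                       error_rate = 0.001,
                       alpha = 1e-4,
                       chimera_fold = 2,
                       novel_max = 2L,
                       divergence_floor_frac = 0.10,
                       ntc_max_reads = 0L,
                       seed = 1L) {
  stopifnot(primer_mismatch >= 0,
            is.na(min_mate_template) || min_mate_template >= 1,
            merged_length_tol >= 0,
            min_overlap >= 1, max_overlap_mismatch >= 0, max_overlap_mismatch < 1,
            error_rate > 0, error_rate < 0.1, alpha > 0, alpha < 1,
            chimera_fold >= 1, novel_max >= 0,
            divergence_floor_frac > 0, divergence_floor_frac < 1,
            ntc_max_reads >= 0)
  structure(list(primer_mismatch = as.integer(primer_mismatch),
                 min_mate_template = as.integer(min_mate_template),
                 merged_length_tol = as.integer(merged_length_tol),
                 min_overlap = as.integer(min_overlap),
                 max_overlap_mismatch = max_overlap_mismatch,
                 error_rate = error_rate, alpha = alpha,
                 chimera_fold = chimera_fold,
                 novel_max = as.integer(novel_max),
                 divergence_floor_frac = divergence_floor_frac,
                 ntc_max_reads = as.integer(ntc_max_reads),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [run_config()] object (reader); `path` invisibly (writer).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_config
#' @param cfg A `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
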