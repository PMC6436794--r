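#' Construct an ASV table
#'
#' @param seq Named character vector of ASV sequences (names = ASV ids).
#' @param counts Integer matrix, ASVs x samples, rownames = ASV ids.
#' @param ledger Optional per-sample filter ledger data.frame.
#' @return Object of class `asv_table`.
#' @export
asv_table <- function(seq, counts, ledger = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == length(seq),
            all(rownames(counts) == names(seq)))
  if (anyDuplicated(seq)) stop("ASV sequences must be unique")
  if (any(counts < 0)) stop("negative counts")
  structure(list(seq = seq, counts = counts, ledger = ledger),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d ASVs x %d samples, %d reads\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

# canonical ASV ordering: descending total count, ties by sequence
order_asvs <- function(seq, counts) {
  tot <- rowSums(counts)
  order(-tot, seq)
}

relabel_asvs <- function(seq, counts, ledger = NULL) {
  ord <- order_asvs(seq, counts)
  seq <- seq[ord]; counts <- counts[ord, , drop = FALSE]
  ids <- sprintf("asv_%03d", seq_along(seq))
  names(seq) <- ids; rownames(counts) <- ids
  asv_table(seq, counts, ledger)
}

#' Verify spacer + primer structure of read pairs and trim to the template
#'
#' Each mate must begin with its library's spacer (compared exactly: a
#' mismatch marks a likely index hop) followed by the template primer
#' (forward primer on read 1, reverse primer on read 2), matched under IUPAC
#' rules with up to `cfg$primer_mismatch` mismatches. Both are removed; the
#' remaining template must reach the per-mate floor `cfg$min_mate_template`
#' (by default the smallest length at which the pair can still span the full
#' insert with the required overlap; short primer-dimer templates fail it)
#' and be free of N.
#'
#' Vectorised over read pairs.
#'
#' @param r1,q1,r2,q2 Character vectors: mate sequences and phred+33 quality
#'   strings.
#' @param spacer_f,spacer_r The library's spacer pair.
#' @param amp An [amplicon_definition()].
#' @param cfg A [run_config()].
#' @return data.frame with `status` ("accepted", "spacer_mismatch",
#'   "missing_primer", "bad_length", "ambiguous_base") and trimmed
#'   `t1`, `tq1`, `t2`, `tq2` (empty strings when rejected).
#' @export
verify_and_trim <- function(r1, q1, r2, q2, spacer_f, spacer_r, amp,
                            cfg = run_config()) {
  n <- length(r1)
  stopifnot(length(q1) == n, length(r2) == n, length(q2) == n)
  status <- rep("accepted", n)
  sf <- nchar(spacer_f); sr <- nchar(spacer_r)
  fw <- amp$forward$sequence; rv <- amp$reverse$sequence
  lf <- nchar(fw); lr <- nchar(rv)

  ok_spacer <- substr(r1, 1L, sf) == spacer_f & substr(r2, 1L, sr) == spacer_r
  status[!ok_spacer] <- "spacer_mismatch"

  idx <- which(ok_spacer)
  mm1 <- primer_mismatches(fw, substr(r1[idx], sf + 1L, sf + lf))
  mm2 <- primer_mismatches(rv, substr(r2[idx], sr + 1L, sr + lr))
  no_primer <- mm1 > cfg$primer_mismatch | mm2 > cfg$primer_mismatch
  status[idx[no_primer]] <- "missing_primer"

  keep <- idx[!no_primer]
  maxlen <- amp$expected_insert_length
  t1 <- substr(r1[keep], sf + lf + 1L, sf + lf + maxlen)
  tq1 <- substr(q1[keep], sf + lf + 1L, sf + lf + maxlen)
  t2 <- substr(r2[keep], sr + lr + 1L, sr + lr + maxlen)
  tq2 <- substr(q2[keep], sr + lr + 1L, sr + lr + maxlen)

  floor_len <- cfg$min_mate_template
  if (is.na(floor_len))
    floor_len <- ceiling((maxlen + cfg$min_overlap) / 2)
  short <- pmin(nchar(t1), nchar(t2)) < floor_len
  status[keep[short]] <- "bad_length"
  hasN <- !short & (grepl("N", t1, fixed = TRUE) | grepl("N", t2, fixed = TRUE))
  status[keep[hasN]] <- "ambiguous_base"

  out <- data.frame(status = status, t1 = "", tq1 = "", t2 = "", tq2 = "",
                    stringsAsFactors = FALSE)
  acc <- !short & !hasN
  out$t1[keep[acc]] <- t1[acc]; out$tq1[keep[acc]] <- tq1[acc]
  out$t2[keep[acc]] <- t2[acc]; out$tq2[keep[acc]] <- tq2[acc]
  out
}

#' Merge trimmed mate templates by best ungapped overlap
#'
#' Read 2 is reverse complemented, then the mate pair is merged at the
#' overlap (>= `cfg$min_overlap` nt) with the lowest mismatch fraction
#' (<= `cfg$max_overlap_mismatch`; ties resolved to the larger overlap).
#' Overlap disagreements take the higher-quality base; agreements keep the
#' higher quality. Merged sequences whose length deviates from the expected
#' insert length by more than `cfg$merged_length_tol` are rejected.
#'
#' Vectorised over pairs.
#'
#' @param t1,tq1,t2,tq2 Trimmed templates/qualities from [verify_and_trim()].
#' @param amp An [amplicon_definition()].
#' @param cfg A [run_config()].
#' @return data.frame with `status` ("merged", "no_overlap",
#'   "excess_mismatch", "bad_merge_length"), `merged`, `quality`, `overlap`,
#'   `mismatches`.
#' @export
merge_pairs <- function(t1, tq1, t2, tq2, amp, cfg = run_config()) {
  t2rc <- revcomp(t2)
  q2rc <- vapply(strsplit(tq2, ""), function(v) paste(rev(v), collapse = ""), "")
  res <- merge_pairs_cpp(t1, tq1, t2rc, q2rc,
                         cfg$min_overlap, cfg$max_overlap_mismatch)
  status <- c("merged", "no_overlap", "excess_mismatch")[res$status + 1L]
  off <- status == "merged" &
    abs(nchar(res$merged) - amp$expected_insert_length) > cfg$merged_length_tol
  status[off] <- "bad_merge_length"
  data.frame(status = status, merged = res$merged, quality = res$quality,
             overlap = res$overlap, mismatches = res$mismatches,
             stringsAsFactors = FALSE)
}

#' Dereplicate merged inserts into an ASV table
#'
#' Groups identical sequences (100 percent identity) and counts them per
#' sample; read totals are preserved exactly.
#'
#' @param merged_by_sample Named list: sample_id -> character vector of merged
#'   insert sequences.
#' @param ledger Optional filter ledger to attach.
#' @return An [asv_table()].
#' @export
dereplicate <- function(merged_by_sample, ledger = NULL) {
  samples <- names(merged_by_sample)
  uniq <- sort(unique(unlist(merged_by_sample, use.names = FALSE)))
  counts <- matrix(0L, nrow = length(uniq), ncol = length(samples),
                   dimnames = list(NULL, samples))
  for (s in samples) {
    tb <- table(factor(merged_by_sample[[s]], levels = uniq))
    counts[, s] <- as.integer(tb)
  }
  names(uniq) <- seq_along(uniq)  # placeholder ids, replaced by relabel
  rownames(counts) <- names(uniq)
  relabel_asvs(uniq, counts, ledger)
}

# expected error-derived count of a specific minor sequence at Hamming
# distance d from a parent of abundance N, for per-base substitution rate e
# over length L: each parent read independently mutates into exactly that
# sequence with probability (e/3)^d (1-e)^(L-d).
error_lambda <- function(N, d, L, e) N * (e / 3)^d * (1 - e)^(L - d)

#' Poisson-model denoising of an ASV table
#'
#' For every ASV (descending pooled abundance) the most plausible parent
#' among more-abundant retained ASVs is found; if the upper-tail Poisson
#' probability of drawing at least the minor's read count from sequencing
#' error off that parent - conditioned on the variant being observed at all,
#' p = P(X >= k | X >= 1) - exceeds `alpha`, the minor is absorbed into the
#' parent (its counts are added, not discarded). The conditioning means a
#' singleton can never be declared a real variant, however distant its best
#' parent. Passes repeat until a fixed point, so the operation is idempotent
#' on its own output.
#'
#' @param tab An [asv_table()].
#' @param error_rate Per-base substitution error rate.
#' @param alpha Significance level retained variants must beat.
#' @return A denoised [asv_table()]; absorbed ids are recorded in
#'   `attr(, "absorbed")`.
#' @export
denoise <- function(tab, error_rate = run_config()$error_rate,
                    alpha = run_config()$alpha) {
  stopifnot(error_rate > 0, error_rate < 0.1, alpha > 0, alpha < 1)
  seq <- tab$seq; counts <- tab$counts
  absorbed_into <- character(0)
  repeat {
    changed <- FALSE
    tot <- rowSums(counts)
    for (i in order(-tot, seq)) {
      if (tot[i] == 0) next
      L <- nchar(seq[i])
      parents <- which(tot > tot[i])
      if (length(parents) == 0) next
      d <- dist_to_set_cpp(seq[i], unname(seq[parents]))
      usable <- d > 0
      if (!any(usable)) next
      lam <- error_lambda(tot[parents[usable]], d[usable], L, error_rate)
      best <- which.max(lam)
      # abundance p-value, conditioned on observing the variant at all;
      # singletons are never significant, and a vanishing denominator
      # (lambda ~ 0 with k >= 2) means an arbitrarily significant variant
      den <- ppois(0, lam[best], lower.tail = FALSE)
      p_tail <- if (tot[i] <= 1) 1
      else if (den == 0) 0
      else ppois(tot[i] - 1, lam[best], lower.tail = FALSE) / den
      if (p_tail > alpha) {
        j <- parents[usable][best]
        counts[j, ] <- counts[j, ] + counts[i, ]
        counts[i, ] <- 0L
        tot[j] <- tot[j] + tot[i]; tot[i] <- 0
        absorbed_into[names(seq)[i]] <- names(seq)[j]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep <- rowSums(counts) > 0
  out <- relabel_asvs(seq[keep], counts[keep, , drop = FALSE], tab$ledger)
  attr(out, "absorbed") <- absorbed_into
  out
}

#' Remove chimeric (bimera) ASVs
#'
#' An ASV is chimeric when it can be split at one breakpoint into a perfect
#' left segment of one parent and a perfect right segment of another, both
#' parents at least `fold` times more abundant (pooled counts) and neither
#' identical to the ASV. Detected via longest-common-prefix/suffix lengths:
#' a bimera of parents (i, j) exists iff lcp_i + lcs_j >= length.
#'
#' @param tab An [asv_table()].
#' @param fold Minimum parent/chimera abundance ratio.
#' @return Filtered [asv_table()]; removed ids in `attr(, "chimeras")`.
#' @export
remove_chimeras <- function(tab, fold = run_config()$chimera_fold) {
  seq <- tab$seq; counts <- tab$counts
  tot <- rowSums(counts)
  is_chimera <- logical(length(seq))
  for (i in order(tot, seq)) {
    L <- nchar(seq[i])
    cand <- which(tot >= fold * tot[i] & seq_along(tot) != i)
    if (length(cand) < 2) next
    pl <- lcp_lcs_cpp(seq[i], unname(seq[cand]))
    ok <- pl$lcp >= 0  # equal length only
    lcp <- pl$lcp; lcs <- pl$lcs
    lcp[!ok] <- -1L; lcs[!ok] <- -1L
    # need i != j with 1 <= lcp_i < L, 1 <= lcs_j < L, lcp_i + lcs_j >= L
    li <- which(lcp >= 1 & lcp < L)
    lj <- which(lcs >= 1 & lcs < L)
    if (length(li) == 0 || length(lj) == 0) next
    found <- FALSE
    for (a in li[order(-lcp[li])][seq_len(min(2, length(li)))]) {
      for (b in lj[order(-lcs[lj])][seq_len(min(2, length(lj)))]) {
        if (a != b && lcp[a] + lcs[b] >= L) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) is_chimera[i] <- TRUE
  }
  keep <- !is_chimera
  out <- relabel_asvs(seq[keep], counts[keep, , drop = FALSE], tab$ledger)
  attr(out, "chimeras") <- unname(seq[is_chimera])
  out
}

#' Run the full read pipeline over a sequencing-run manifest
#'
#' For every library: read the FASTQ pair, verify spacer/primer/length, trim,
#' merge; then dereplicate across samples, denoise and remove chimeras.
#' A per-sample ledger records every filtering step, so
#' raw = verified + rejections and verified = merged + merge rejections.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param amp An [amplicon_definition()].
#' @param cfg A [run_config()].
#' @return List: `table` (final [asv_table()] with ledger),
#'   `derep` (pre-denoise table), `ledger` (data.frame).
#' @export
run_reads <- function(manifest, amp = amplicon_definition(), cfg = run_config()) {
  merged_by_sample <- list()
  ledger <- NULL
  for (k in seq_len(nrow(manifest))) {
    s <- manifest[k, ]
    p1 <- read_fastq(s$fastq_r1); p2 <- read_fastq(s$fastq_r2)
    if (nrow(p1) != nrow(p2))
      stop("sample ", s$sample_id, ": R1/R2 read counts differ")
    v <- verify_and_trim(p1$seq, p1$qual, p2$seq, p2$qual,
                         s$spacer_f, s$spacer_r, amp, cfg)
    acc <- v$status == "accepted"
    m <- merge_pairs(v$t1[acc], v$tq1[acc], v$t2[acc], v$tq2[acc], amp, cfg)
    merged_by_sample[[s$sample_id]] <- m$merged[m$status == "merged"]
    row <- data.frame(
      sample_id = s$sample_id, role = s$role, raw = nrow(p1),
      spacer_mismatch = sum(v$status == "spacer_mismatch"),
      missing_primer = sum(v$status == "missing_primer"),
      bad_length = sum(v$status == "bad_length"),
      ambiguous_base = sum(v$status == "ambiguous_base"),
      verified = sum(acc),
      no_overlap = sum(m$status == "no_overlap"),
      excess_mismatch = sum(m$status == "excess_mismatch"),
      bad_merge_length = sum(m$status == "bad_merge_length"),
      merged = sum(m$status == "merged"),
      stringsAsFactors = FALSE)
    ledger <- rbind(ledger, row)
  }
  derep <- dereplicate(merged_by_sample, ledger)
  den <- denoise(derep, cfg$error_rate, cfg$alpha)
  final <- remove_chimeras(den, cfg$chimera_fold)
  attr(final, "absorbed") <- attr(den, "absorbed")
  list(table = final, derep = derep, ledger = ledger)
}
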