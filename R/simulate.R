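#' Build a seeded synthetic reference backbone
#'
#' Fills every declared segment with seeded pseudorandom bases, installs
#' concrete expansions of the two primers flanking the insert window on the
#' target segment, then installs the variant table's reference alleles at
#' their positions (reference alleles take precedence; a reference allele
#' inside a primer site must fall within that primer position's IUPAC
#' expansion, otherwise the placement is rejected).
#'
#' @param vt A [parse_variant_table()] result.
#' @param amp An [amplicon_definition()].
#' @param seed Integer seed (mandatory; same seed, same backbone).
#' @return Named character vector of segment sequences.
#' @export
make_backbone <- function(vt, amp = amplicon_definition(), seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  win <- amp$insert_window
  lf <- nchar(amp$forward$sequence); lr <- nchar(amp$reverse$sequence)
  fw_start <- win$start - lf; rv_start <- win$end + 1L
  if (fw_start < 1)
    stop("segment '", win$segment, "' too short 5' of the insert for the forward primer")
  if (rv_start + lr - 1L > vt$segments[[win$segment]])
    stop("segment '", win$segment, "' too short 3' of the insert for the reverse primer")
  backbone <- vapply(names(vt$segments), function(sg) {
    paste(sample(c("A", "C", "G", "T"), vt$segments[[sg]], replace = TRUE),
          collapse = "")
  }, "")
  # concrete primer sites (one random expansion each)
  fw_exp <- sample_expansion(amp$forward$sequence)
  rv_site <- sample_expansion(revcomp(amp$reverse$sequence))
  sg <- win$segment
  substr(backbone[[sg]], fw_start, fw_start + lf - 1L) <- fw_exp
  substr(backbone[[sg]], rv_start, rv_start + lr - 1L) <- rv_site
  # reference alleles, overriding primer bases only within their degeneracy
  site_chars <- c(strsplit(amp$forward$sequence, "")[[1]],
                  rep(NA_character_, window_length(win)),
                  strsplit(revcomp(amp$reverse$sequence), "")[[1]])
  ref <- vt$calls[vt$reference, ]
  for (i in seq_len(nrow(vt$sites))) {
    s <- vt$sites$segment[i]; p <- vt$sites$pos[i]
    if (s == sg && p >= fw_start && p <= rv_start + lr - 1L) {
      code <- site_chars[p - fw_start + 1L]
      if (!is.na(code) && !iupac_match(code, ref[i]))
        stop("site conflict: reference allele ", ref[i], " at ", s, ":", p,
             " outside primer degeneracy '", code, "'")
    }
    substr(backbone[[s]], p, p) <- ref[i]
  }
  # the random fill must not create stray primer sites (extraction demands
  # unique sites); astronomically unlikely, but verified
  fw_hits <- find_primer_sites(backbone[[sg]], amp$forward, 0L)
  rv_hits <- find_primer_sites(backbone[[sg]], amp$reverse, 0L)
  if (sum(fw_hits$strand == "+") != 1 || sum(rv_hits$strand == "-") != 1)
    stop("random backbone produced ambiguous primer sites; use another seed")
  backbone
}

# one concrete expansion of an IUPAC string, drawn uniformly
sample_expansion <- function(iupac_seq) {
  chars <- strsplit(iupac_seq, "")[[1]]
  paste(vapply(chars, function(ch) {
    exp <- IUPAC_CODES[[ch]]
    if (length(exp) == 1) exp else sample(exp, 1)
  }, ""), collapse = "")
}

#' Synthetic bighead carp insert ("L")
#'
#' A synthetic stand-in for the bighead carp cytochrome-b haplotype L insert:
#' the silver carp haplotype A insert with transitions at 14 fixed positions,
#' all chosen outside the silver carp variant sites of the window. By
#' construction its windowed distance is 14 nt to silver haplotype A and
#' 15 nt to haplotype B, reproducing the assay-region divergences reported
#' for the real haplotype; it is not the GenBank sequence.
#'
#' @param silver_a_insert The silver haplotype A insert sequence (135 nt).
#' @param window The insert's [diagnostic_window()] (for coordinate mapping).
#' @return Single-row insert table (species, label, class, insert).
#' @export
synthetic_bighead_insert <- function(silver_a_insert,
                                     window = diagnostic_window()) {
  gene_pos <- c(120L, 125L, 130L, 135L, 150L, 155L, 160L, 165L,
                175L, 190L, 205L, 235L, 240L, 245L)
  off <- gene_pos - window$start + 1L
  stopifnot(all(off >= 1), all(off <= nchar(silver_a_insert)))
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  s <- silver_a_insert
  for (o in off) substr(s, o, o) <- transition[[substr(s, o, o)]]
  data.frame(species = "bighead carp", label = "L", class = "L", insert = s,
             stringsAsFactors = FALSE)
}

#' Generate mock positive-control inserts
#'
#' Random insert-length sequences at least `min_dist` nt from every panel
#' insert and from each other, standing in for the Sanger-verified marine
#' fish mixture used as a sequencing positive control.
#'
#' @param n Number of mock taxa (default 10).
#' @param panel_insert_seqs Character vector of panel insert sequences.
#' @param len Insert length.
#' @param min_dist Minimum Hamming distance to panel inserts and each other.
#' @param seed Integer seed.
#' @return Named character vector (mock01, mock02, ...).
#' @export
mock_control_inserts <- function(n = 10L, panel_insert_seqs, len = 135L,
                                 min_dist = 30L, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    refs <- c(panel_insert_seqs, out)
    d <- dist_to_set_cpp(cand, refs)
    if (all(d < 0 | d >= min_dist)) out <- c(out, cand)
  }
  setNames(out, sprintf("mock%02d", seq_len(n)))
}

#' Specify a simulated sequencing run
#'
#' @param samples List of per-library specs: each a list with `sample_id`,
#'   `role` ("sample", "positive_control", "ntc"), `reads`, and `composition`
#'   (named fractions over template keys; NTCs take no composition - they
#'   emit only primer-dimer artifacts and receive index hops).
#' @param templates Named character vector mapping template keys (e.g.
#'   `"silver carp|A"`, `"mock01"`) to insert sequences.
#' @param error_rate Per-base substitution error rate.
#' @param hop_rate Probability a read is emitted into a different library
#'   while keeping its origin spacers (index hop).
#' @param dimer_rate Probability a read is a short primer-dimer artifact.
#' @param chimera_rate Probability a template is a two-parent chimera.
#' @param read_len Read length per mate.
#' @param spacer_len Library spacer length.
#' @param seed Integer seed (mandatory).
#' @return Object of class `run_sim_spec`.
#' @export
run_sim_spec <- function(samples, templates, error_rate = 0.001,
                         hop_rate = 0, dimer_rate = 0, chimera_rate = 0,
                         read_len = 150L, spacer_len = 7L, seed) {
  stopifnot(!missing(seed))
  rates <- c(error_rate, hop_rate, dimer_rate, chimera_rate)
  stopifnot(all(rates >= 0), all(rates < 1))
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_id in simulation spec")
  for (s in samples) {
    if (!s$role %in% c("sample", "positive_control", "ntc"))
      stop("unknown role: ", s$role)
    if (s$role != "ntc") {
      comp <- s$composition
      if (abs(sum(comp) - 1) > 1e-9)
        stop("composition of '", s$sample_id, "' does not sum to 1")
      missing <- setdiff(names(comp), names(templates))
      if (length(missing) > 0)
        stop("unknown template key(s): ", paste(missing, collapse = ", "))
    }
  }
  structure(list(samples = samples, templates = templates,
                 error_rate = error_rate, hop_rate = hop_rate,
                 dimer_rate = dimer_rate, chimera_rate = chimera_rate,
                 read_len = as.integer(read_len),
                 spacer_len = as.integer(spacer_len),
                 seed = as.integer(seed)),
            class = "run_sim_spec")
}

# distinct fixed-length spacers, one (forward, reverse) pair per library
make_spacers <- function(n, len) {
  draw <- function(k) vapply(seq_len(k), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
  f <- character(0); r <- character(0)
  while (length(f) < n) { c_ <- draw(1); if (!c_ %in% f) f <- c(f, c_) }
  while (length(r) < n) { c_ <- draw(1); if (!c_ %in% c(f, r)) r <- c(r, c_) }
  list(f = f, r = r)
}

inject_errors <- function(seqs, quals, rate) {
  if (rate <= 0) return(list(seq = seqs, qual = quals, hit = logical(length(seqs))))
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  hit <- nerr > 0
  bases <- c("A", "C", "G", "T")
  for (i in which(hit)) {
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1)
      substr(quals[i], p, p) <- "0"  # Q15 at injected errors
    }
  }
  list(seq = seqs, qual = quals, hit = hit)
}

#' Simulate a full sequencing run with truth table
#'
#' Emits per-library gzip FASTQ pairs whose reads carry
#' spacer + concrete primer expansion + template (read 2 reverse
#' complemented), per-base substitution errors at Q15 (correct bases Q35),
#' index-hopped reads that land in another library while keeping their
#' origin spacers, short primer-dimer artifacts, and two-parent chimeric
#' templates spliced at a uniform breakpoint. NTC libraries emit only dimers
#' (and receive hops). Output is deterministic for a given spec seed.
#'
#' @param spec A [run_sim_spec()].
#' @param out_dir Output directory (created if needed).
#' @return List: `manifest` (path), `truth` (data.frame and path),
#'   `spacers`, `fastq` paths.
#' @export
simulate_run <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  samples <- spec$samples
  n_lib <- length(samples)
  ids <- vapply(samples, `[[`, "", "sample_id")
  sp <- make_spacers(n_lib, spec$spacer_len)
  fwd_exps <- expand_primer(assay_primers()$forward)
  rev_exps <- expand_primer(assay_primers()$reverse)
  all_r1 <- vector("list", n_lib); all_r2 <- vector("list", n_lib)
  truth <- NULL
  # per-origin emission
  for (k in seq_len(n_lib)) {
    s <- samples[[k]]
    nread <- s$reads
    if (nread == 0) next
    if (s$role == "ntc") {
      template_key <- rep("dimer", nread)
      cls <- rep("dimer", nread)
    } else {
      is_dimer <- runif(nread) < spec$dimer_rate
      # chimeras need two distinct parent templates
      can_chim <- length(s$composition) >= 2
      is_chim <- can_chim & !is_dimer & runif(nread) < spec$chimera_rate
      keys <- sample(names(s$composition), nread, replace = TRUE,
                     prob = s$composition)
      template_key <- keys
      template_key[is_dimer] <- "dimer"
      template_key[is_chim] <- "chimera"
      cls <- ifelse(is_dimer, "dimer", ifelse(is_chim, "chimera", "clean"))
    }
    templ <- character(nread)
    clean <- !(template_key %in% c("dimer", "chimera"))
    templ[clean] <- unname(spec$templates[template_key[clean]])
    # dimers: spacer+primers with a short random filler instead of the insert
    for (i in which(template_key == "dimer"))
      templ[i] <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                        collapse = "")
    # chimeras: splice two (weighted) parent templates at a uniform breakpoint
    for (i in which(template_key == "chimera")) {
      pr <- sample(names(s$composition), 2, replace = FALSE,
                   prob = s$composition + 1e-12)
      a <- spec$templates[[pr[1]]]; b <- spec$templates[[pr[2]]]
      bp <- sample.int(nchar(a) - 1L, 1)
      templ[i] <- paste0(substr(a, 1, bp), substr(b, bp + 1L, nchar(b)))
      template_key[i] <- paste0("chimera:", pr[1], "+", pr[2])
    }
    fw <- sample(fwd_exps, nread, replace = TRUE)
    rv <- sample(rev_exps, nread, replace = TRUE)
    r1 <- substr(paste0(sp$f[k], fw, templ), 1L, spec$read_len)
    r2 <- substr(paste0(sp$r[k], rv, revcomp(templ)), 1L, spec$read_len)
    q1 <- strrep("D", nchar(r1)); q2 <- strrep("D", nchar(r2))  # Q35
    e1 <- inject_errors(r1, q1, spec$error_rate)
    e2 <- inject_errors(r2, q2, spec$error_rate)
    r1 <- e1$seq; q1 <- e1$qual; r2 <- e2$seq; q2 <- e2$qual
    cls[cls == "clean" & (e1$hit | e2$hit)] <- "error"
    # index hops: the read keeps its origin spacers but lands elsewhere
    hopped <- n_lib > 1 & runif(nread) < spec$hop_rate
    dest <- rep(k, nread)
    if (any(hopped)) {
      others <- setdiff(seq_len(n_lib), k)
      dest[hopped] <- others[sample.int(length(others), sum(hopped),
                                        replace = TRUE)]
    }
    cls[hopped] <- "hop"
    read_id <- sprintf("%s_%06d", ids[k], seq_len(nread))
    truth <- rbind(truth, data.frame(
      read_id = read_id, origin = ids[k], library = ids[dest],
      template = template_key, class = cls, stringsAsFactors = FALSE))
    for (d in unique(dest)) {
      ix <- which(dest == d)
      all_r1[[d]] <- c(all_r1[[d]],
                       paste0("@", read_id[ix], "\n", r1[ix], "\n+\n", q1[ix]))
      all_r2[[d]] <- c(all_r2[[d]],
                       paste0("@", read_id[ix], "\n", r2[ix], "\n+\n", q2[ix]))
    }
  }
  # write per-library FASTQ pairs and the manifest
  man <- data.frame(sample_id = ids,
                    role = vapply(samples, `[[`, "", "role"),
                    fastq_r1 = sprintf("%s_R1.fastq.gz", ids),
                    fastq_r2 = sprintf("%s_R2.fastq.gz", ids),
                    spacer_f = sp$f, spacer_r = sp$r, stringsAsFactors = FALSE)
  for (k in seq_len(n_lib)) {
    for (mate in 1:2) {
      path <- file.path(out_dir, man[[paste0("fastq_r", mate)]][k])
      con <- gzfile(path, "wb")
      recs <- if (mate == 1) all_r1[[k]] else all_r2[[k]]
      if (length(recs) > 0) writeChar(paste0(paste(recs, collapse = "\n"), "\n"),
                                      con, eos = NULL)
      close(con)
    }
  }
  man_path <- file.path(out_dir, "manifest.tsv")
  write_tsv(man, man_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  if (is.null(truth))
    truth <- data.frame(read_id = character(), origin = character(),
                        library = character(), template = character(),
                        class = character(), stringsAsFactors = FALSE)
  write_tsv(truth, truth_path)
  list(manifest = man_path, truth = truth, truth_path = truth_path,
       spacers = sp,
       fastq = file.path(out_dir, c(man$fastq_r1, man$fastq_r2)))
}
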