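# shared fixtures: the packaged silver carp key reconstructed on a fixed
# synthetic backbone, plus the synthetic bighead insert and mock controls

fx <- local({
  vt <- silver_carp_variants()
  amp <- amplicon_definition()
  backbone <- make_backbone(vt, amp, seed = 11)
  panel <- reference_panel(reconstruct_haplotypes(vt, backbone))
  silver <- panel_inserts(panel, amp)
  bighead <- synthetic_bighead_insert(silver$insert[silver$label == "A"])
  inserts <- rbind(silver[, c("species", "label", "class", "insert")], bighead)
  mocks <- mock_control_inserts(10, inserts$insert, seed = 12)
  list(vt = vt, amp = amp, backbone = backbone, panel = panel,
       silver = silver, bighead = bighead, inserts = inserts, mocks = mocks,
       templates = c(setNames(inserts$insert,
                              paste0(inserts$species, "|", inserts$label)),
                     mocks))
})

# position-by-position comparison oracle, independent of the compiled kernel
oracle_hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  sum(va != vb)
}

# full-length oracle distance between two haplotype objects
oracle_hap_dist <- function(h1, h2, window = NULL) {
  if (!is.null(window)) {
    return(oracle_hamming(substr(h1$segments[[window$segment]], window$start, window$end),
                          substr(h2$segments[[window$segment]], window$start, window$end)))
  }
  sum(vapply(names(h1$segments), function(sg)
    oracle_hamming(h1$segments[[sg]], h2$segments[[sg]]), 0))
}

# build a small asv_table from a named count vector (one sample) or matrix
make_tab <- function(seqs, counts, sample = "s1") {
  if (is.null(dim(counts)))
    counts <- matrix(as.integer(counts), ncol = 1, dimnames = list(NULL, sample))
  ids <- sprintf("asv_%03d", seq_along(seqs))
  rownames(counts) <- ids
  asv_table(setNames(seqs, ids), counts)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# one-substitution neighbour of a sequence at position p
mutate1 <- function(s, p, base = NULL) {
  old <- substr(s, p, p)
  if (is.null(base)) base <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(s, p, p) <- base
  s
}
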