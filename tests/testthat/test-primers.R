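test_that("IUPAC matching follows the code expansions and is asymmetric", {
  expect_true(iupac_match("Y", "C"))
  expect_true(iupac_match("Y", "T"))
  expect_false(iupac_match("Y", "A"))
  expect_true(iupac_match("N", "G"))
  expect_true(iupac_match("A", "A"))
  expect_false(iupac_match("A", "G"))
  # template-side ambiguity never matches; invalid characters error
  expect_false(iupac_match("N", "N"))
  expect_false(iupac_match("A", "R"))
  expect_error(iupac_match("Z", "A"), "invalid IUPAC")
  expect_error(iupac_match("A", "Z"), "invalid template")
})

test_that("degeneracy equals the size of the exhaustive expansion set", {
  pr <- assay_primers()
  expect_equal(degeneracy(pr$forward), 48L)
  expect_equal(degeneracy(pr$reverse), 16L)
  for (p in pr) {
    ex <- expand_primer(p)
    expect_equal(length(ex), degeneracy(p))
    expect_equal(anyDuplicated(ex), 0L)
    # every expansion matches the degenerate pattern position by position
    chars <- strsplit(p$sequence, "")[[1]]
    for (e in ex[c(1, length(ex))]) {
      eb <- strsplit(e, "")[[1]]
      expect_true(all(mapply(iupac_match, chars, eb)))
    }
  }
  expect_equal(degeneracy(degenerate_primer("x", "ACGTACGTACGT")), 1L)
})

test_that("primer strings are validated and whitespace-stripped", {
  p <- degenerate_primer("r", "AARAAGAATGATGC YCCRTTRGC", "reverse")
  expect_equal(p$sequence, "AARAAGAATGATGCYCCRTTRGC")
  expect_error(degenerate_primer("bad", "ACGTACGTXX"), "non-IUPAC")
  expect_error(degenerate_primer("short", "ACGTA"), "shorter than 10")
})

test_that("find_primer_sites matches a brute-force sliding-window oracle", {
  oracle_sites <- function(seq, primer, max_mm) {
    hits <- NULL
    for (pat in list(c(primer$sequence, "+"),
                     c(carpassay:::revcomp(primer$sequence), "-"))) {
      pm <- strsplit(pat[1], "")[[1]]
      k <- length(pm)
      for (s in seq_len(nchar(seq) - k + 1)) {
        tb <- strsplit(substr(seq, s, s + k - 1), "")[[1]]
        mm <- sum(!mapply(function(code, b)
          b %in% c("A", "C", "G", "T") && iupac_match(code, b), pm, tb))
        if (mm <= max_mm)
          hits <- rbind(hits, data.frame(start = s, strand = pat[2],
                                         mismatches = mm))
      }
    }
    if (is.null(hits)) return(hits)
    hits <- hits[order(hits$start), ]
    rownames(hits) <- NULL
    hits
  }
  pr <- assay_primers()$forward
  set.seed(3)
  exp1 <- expand_primer(pr)[5]
  host <- paste0(random_seq(40), exp1, random_seq(40))
  got <- find_primer_sites(host, pr, 0)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 41L)
  expect_equal(got$mismatches, 0L)
  expect_equal(got, oracle_sites(host, pr, 0), ignore_attr = TRUE)
  # one mismatch appears only when tolerated
  host1 <- mutate1(host, 45)
  expect_equal(nrow(find_primer_sites(host1, pr, 0)), 0L)
  got1 <- find_primer_sites(host1, pr, 1)
  expect_equal(got1, oracle_sites(host1, pr, 1), ignore_attr = TRUE)
  expect_equal(got1$mismatches, 1L)
  # reverse complement strand is reported as "-"
  hostrc <- carpassay:::revcomp(host)
  gotrc <- find_primer_sites(hostrc, pr, 0)
  expect_equal(gotrc$strand, "-")
  expect_equal(gotrc, oracle_sites(hostrc, pr, 0), ignore_attr = TRUE)
  # template N fails all matches
  expect_equal(nrow(find_primer_sites(mutate1(host, 50, "N"), pr, 0)), 0L)
})

test_that("in-silico PCR extracts the 135 nt insert at the assay coordinates", {
  for (h in carpassay:::panel_haplotypes(fx$panel)) {
    ins <- extract_insert(h, fx$amp)
    expect_equal(nchar(ins$sequence), 135L)
    expect_equal(ins$start, 115L)
    expect_equal(ins$end, 249L)
  }
})

test_that("insert distances equal windowed haplotype distances", {
  win <- fx$amp$insert_window
  dm <- distance_matrix(fx$panel, win)
  ins <- fx$silver
  for (i in seq_len(nrow(ins))) for (j in seq_len(nrow(ins))) {
    expect_equal(oracle_hamming(ins$insert[i], ins$insert[j]),
                 dm[paste0("silver carp|", ins$label[i]),
                    paste0("silver carp|", ins$label[j])])
  }
})

test_that("extraction errors when a primer site is missing or duplicated", {
  h <- fx$panel$entries[["silver carp"]][[1]]
  broken <- h
  # destroy the forward site (3 mismatches beats the tolerance)
  for (p in c(90, 95, 100))
    substr(broken$segments[["cytb"]], p, p) <-
      setdiff(c("A", "C", "G", "T"),
              substr(broken$segments[["cytb"]], p, p))[1]
  expect_error(extract_insert(broken, fx$amp), "no site.*carp_cytb_F")
  dup <- h
  site <- substr(h$segments[["cytb"]], 89, 114)
  dup$segments[["cytb"]] <- paste0(dup$segments[["cytb"]], site)
  dup2 <- haplotype("dup", "x", dup$segments)
  expect_error(extract_insert(dup2, amplicon_definition(
    insert_window = diagnostic_window("cytb", 115, 249))), "multiple sites")
})

test_that("extraction on the reverse-complemented reference mirrors the insert", {
  h <- fx$panel$entries[["silver carp"]][[2]]
  fwd <- extract_insert(h, fx$amp)
  rc <- haplotype(h$label, h$species,
                  list(cytb = carpassay:::revcomp(h$segments[["cytb"]])))
  back <- extract_insert(rc, fx$amp)
  L <- nchar(h$segments[["cytb"]])
  expect_equal(back$sequence, carpassay:::revcomp(fwd$sequence))
  expect_equal(back$start, L - fwd$end + 1L)
  expect_equal(back$end, L - fwd$start + 1L)
})
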