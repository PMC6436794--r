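cfg <- run_config()

test_that("the cutoff is the worst single erroneous control ASV fraction", {
  exp1 <- fx$mocks[["mock01"]]; exp2 <- fx$mocks[["mock02"]]
  err1 <- mutate1(exp1, 10); err2 <- mutate1(exp2, 20)
  counts <- cbind(pc1 = c(6000L, 3981L, 19L, 0L),
                  pc2 = c(500L, 470L, 0L, 30L))
  tab <- make_tab(c(exp1, exp2, err1, err2), counts)
  cal <- calibrate(tab, "pc1", c(exp1, exp2))
  expect_equal(cal$cutoff_fraction, 19 / 10000)
  # pooled across the run's controls, the max rule applies
  cal2 <- calibrate(tab, c("pc1", "pc2"), c(exp1, exp2))
  expect_equal(cal2$cutoff_fraction, max(19 / 10000, 30 / 1000))
  # clean control: cutoff 0
  clean <- make_tab(c(exp1, exp2), c(700L, 300L), sample = "pc3")
  expect_equal(calibrate(clean, "pc3", c(exp1, exp2))$cutoff_fraction, 0)
  empty <- make_tab(exp1, 0L, sample = "pc4")
  expect_error(calibrate(empty, "pc4", exp1), "no reads")
  expect_error(calibrate(tab, "nope", exp1), "absent")
})

test_that("raising an erroneous control count never lowers the cutoff", {
  exp1 <- fx$mocks[["mock01"]]
  err <- mutate1(exp1, 5)
  for (n in c(0L, 5L, 19L, 100L)) {
    tab <- make_tab(c(exp1, err), c(10000L, n), sample = "pc")
    cutoffs <- calibrate(tab, "pc", exp1)$cutoff_fraction
    if (n == 0) expect_equal(cutoffs, 0)
    else expect_equal(cutoffs, n / (10000 + n))
  }
})

test_that("no-template controls pass only when verification-clean", {
  ledger <- data.frame(sample_id = c("ntc1", "ntc2", "ntc3"),
                       verified = c(0L, 50L, 0L), raw = c(0L, 60L, 40L))
  expect_equal(check_ntc(ledger, "ntc1"), "pass")
  expect_equal(check_ntc(ledger, "ntc2"), "fail")
  # raw reads present but all rejected at verification still pass
  expect_equal(check_ntc(ledger, "ntc3"), "pass")
  expect_equal(check_ntc(ledger, "ntc2", max_reads = 50L), "pass")
  expect_error(check_ntc(ledger, "missing"), "not found")
})

test_that("the cutoff splits a sample at the observed boundary, inclusively", {
  seqs <- c(fx$silver$insert[1], fx$silver$insert[2], fx$bighead$insert)
  counts <- c(2720L, 2020L, 70L)
  tab <- make_tab(seqs, counts, sample = "shop")
  cut <- apply_cutoff(tab, "shop", 0.0019, total = 100000)
  expect_equal(cut$retained$fraction, c(0.0272, 0.0202))
  expect_equal(cut$below$fraction, 0.0007)
  # cutoff 0 retains everything; an exact boundary fraction is retained
  expect_equal(nrow(apply_cutoff(tab, "shop", 0)$below), 0L)
  cut_b <- apply_cutoff(tab, "shop", 70 / 100000, total = 100000)
  expect_true("asv_003" %in% cut_b$retained$asv_id)
})

test_that("ASVs assign to species and haplotype class by Hamming best match", {
  ins <- fx$inserts
  b <- ins$insert[ins$label == "B"]
  # exact haplotype B
  got <- assign_asv(b, ins)
  expect_equal(got$status, "known")
  expect_equal(got$species, "silver carp")
  expect_equal(got$haplotype_class, "B")
  expect_equal(got$distance, 0L)
  # exact A assigns to the merged A/C class (window-identical haplotypes)
  got_a <- assign_asv(ins$insert[ins$label == "A"], ins)
  expect_equal(got_a$haplotype_class, "A/C")
  expect_equal(got_a$label, "A/C")
  # one substitution off B, far from everything else: a novel silver haplotype
  nov <- assign_asv(mutate1(b, 100), ins)
  expect_equal(nov$status, "novel")
  expect_equal(nov$species, "silver carp")
  expect_equal(nov$haplotype_class, "novel")
  expect_equal(nov$distance, 1L)
  # exact synthetic bighead L
  bh <- assign_asv(fx$bighead$insert, ins)
  expect_equal(bh$status, "known")
  expect_equal(bh$species, "bighead carp")
  expect_equal(bh$haplotype_class, "L")
  # too far from anything: unassigned
  expect_equal(assign_asv(fx$mocks[[1]], ins)$status, "unassigned")
  expect_equal(assign_asv(substr(b, 1, 100), ins)$status, "unassigned")
})

test_that("species ties surface as ambiguous and panel order is irrelevant", {
  b <- fx$inserts$insert[fx$inserts$label == "B"]
  z <- mutate1(b, 130)
  ins <- rbind(fx$inserts,
               data.frame(species = "other carp", label = "Z", class = "Z",
                          insert = z, stringsAsFactors = FALSE))
  # a third allele at the same site: one substitution from both B and Z
  third <- setdiff(c("A", "C", "G", "T"),
                   c(substr(b, 130, 130), substr(z, 130, 130)))[1]
  q <- mutate1(b, 130, third)
  got <- assign_asv(q, ins)
  expect_equal(got$status, "ambiguous")
  expect_equal(got$species, "other carp;silver carp")
  set.seed(5)
  for (rep in 1:5) {
    perm <- ins[sample(nrow(ins)), ]
    expect_equal(assign_asv(q, perm), got)
    expect_equal(assign_asv(fx$bighead$insert, perm),
                 assign_asv(fx$bighead$insert, ins))
  }
})

test_that("below-cutoff divergent panel hits are flagged, near misses removed", {
  ins <- fx$inserts
  a <- ins$insert[ins$label == "A"]; b <- ins$insert[ins$label == "B"]
  retained <- data.frame(asv_id = c("asv_001", "asv_002"),
                         sequence = c(a, b), reads = c(2720L, 2020L),
                         fraction = c(0.0272, 0.0202), stringsAsFactors = FALSE)
  below <- data.frame(asv_id = c("asv_003", "asv_004", "asv_005"),
                      sequence = c(fx$bighead$insert, mutate1(a, 40),
                                   random_seq(135)),
                      reads = c(70L, 30L, 20L),
                      fraction = c(7e-4, 3e-4, 2e-4), stringsAsFactors = FALSE)
  fl <- flag_below_cutoff(below, retained, ins, cfg)
  # bighead L: 14 and 15 nt from the retained silver ASVs - over 10% of 135
  expect_equal(fl$flag[1], "below_cutoff_flagged")
  expect_equal(fl$species[1], "bighead carp")
  # a 1-off shadow of a retained ASV is treated as error
  expect_equal(fl$flag[2], "below_cutoff_removed")
  # divergent but matching no panel species: removed
  expect_equal(fl$flag[3], "below_cutoff_removed")
})

test_that("sample summaries aggregate fractions that re-tally exactly", {
  ins <- fx$inserts
  a <- ins$insert[ins$label == "A"]; b <- ins$insert[ins$label == "B"]
  retained <- data.frame(asv_id = c("asv_001", "asv_002"),
                         sequence = c(a, b), reads = c(2720L, 2020L),
                         fraction = c(2720, 2020) / 100000,
                         stringsAsFactors = FALSE)
  below <- flag_below_cutoff(
    data.frame(asv_id = character(), sequence = character(),
               reads = integer(), fraction = numeric()),
    retained, ins, cfg)
  rep_ <- summarize_sample("shop", retained, below, ins, cfg)
  expect_equal(nrow(rep_), 2L)
  expect_equal(rep_$haplotype_class, c("A/C", "B"))
  expect_equal(rep_$fraction, rep_$reads / 100000)
  expect_true(all(rep_$flag == "requires_confirmation"))
  expect_lte(sum(rep_$fraction), 1)
  empty <- summarize_sample("shop",
                            retained[0, ], below, ins, cfg)
  expect_equal(nrow(empty), 0L)
})

test_that("detections shrink monotonically as the cutoff rises", {
  # A and C share one insert, so pick window-distinct haplotypes
  seqs <- c(fx$silver$insert[c(1, 2, 4)], fx$bighead$insert)
  tab <- make_tab(seqs, c(5000L, 3000L, 150L, 40L), sample = "s")
  n_prev <- Inf
  for (cut in c(0, 0.001, 0.02, 0.4, 0.7)) {
    n <- nrow(apply_cutoff(tab, "s", cut)$retained)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("detect_run ties calibration, NTC checks and assignment together", {
  mocks <- fx$mocks
  spec <- run_sim_spec(
    samples = list(
      list(sample_id = "shop1", role = "sample", reads = 2000,
           composition = c("silver carp|A" = 0.6, "silver carp|B" = 0.4)),
      list(sample_id = "pc1", role = "positive_control", reads = 2000,
           composition = setNames(rep(0.1, 10), names(mocks))),
      list(sample_id = "ntc1", role = "ntc", reads = 20)),
    templates = fx$templates, error_rate = 0.001, hop_rate = 0.01,
    dimer_rate = 0.02, chimera_rate = 0.01, seed = 101)
  sim <- simulate_run(spec, tempfile("det"))
  man <- read_manifest(sim$manifest)
  run <- run_reads(man, fx$amp, cfg)
  det <- detect_run(run, man, fx$inserts, unname(mocks), cfg)
  expect_equal(unname(det$ntc_status["ntc1"]), "pass")
  expect_s3_class(det$calibration, "run_calibration")
  d <- det$detections
  expect_equal(unique(d$sample_id), "shop1")
  expect_setequal(d$haplotype_class, c("A/C", "B"))
  # reported fractions re-tally against the ledger's merged totals
  merged <- run$ledger$merged[run$ledger$sample_id == "shop1"]
  expect_equal(d$fraction, d$reads / merged)
  expect_equal(d$reads,
               unname(run$table$counts[d$asv_id, "shop1"]))
})
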