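test_that("backbones are deterministic and carry the assay architecture", {
  b1 <- make_backbone(fx$vt, fx$amp, seed = 11)
  b2 <- make_backbone(fx$vt, fx$amp, seed = 11)
  expect_identical(b1, b2)
  b3 <- make_backbone(fx$vt, fx$amp, seed = 12)
  expect_false(identical(b1, b3))
  expect_equal(unname(nchar(b1)), unname(fx$vt$segments))
  # reference alleles sit at their positions
  for (i in seq_len(nrow(fx$vt$sites)))
    expect_equal(substr(b1[[fx$vt$sites$segment[i]]],
                        fx$vt$sites$pos[i], fx$vt$sites$pos[i]),
                 unname(fx$vt$calls["A", i]))
  # and the primers extract a 135 nt insert from it
  ins <- extract_insert(haplotype("bb", "x", as.list(b1)), fx$amp)
  expect_equal(nchar(ins$sequence), 135L)
})

test_that("a fixed seed reproduces the simulated run byte for byte", {
  spec <- run_sim_spec(
    samples = list(
      list(sample_id = "s1", role = "sample", reads = 300,
           composition = c("silver carp|A" = 0.5, "silver carp|B" = 0.5)),
      list(sample_id = "ntc1", role = "ntc", reads = 10)),
    templates = fx$templates, error_rate = 0.005, hop_rate = 0.02,
    dimer_rate = 0.02, chimera_rate = 0.01, seed = 404)
  d1 <- tempfile("sim_a"); d2 <- tempfile("sim_b")
  sim1 <- simulate_run(spec, d1)
  sim2 <- simulate_run(spec, d2)
  for (f in c("s1_R1.fastq.gz", "s1_R2.fastq.gz", "ntc1_R1.fastq.gz")) {
    expect_identical(readLines(gzfile(file.path(d1, f))),
                     readLines(gzfile(file.path(d2, f))))
  }
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(read_tsv(file.path(d1, "manifest.tsv"))[, c("sample_id", "spacer_f", "spacer_r")],
                   read_tsv(file.path(d2, "manifest.tsv"))[, c("sample_id", "spacer_f", "spacer_r")])
})

test_that("truth-table artifact rates track their binomial expectations", {
  n_rep <- 20; reads <- 400
  hop <- 0.03; dimer <- 0.04; chim <- 0.03
  counts <- c(hop = 0, dimer = 0, chimera = 0)
  for (r in seq_len(n_rep)) {
    spec <- run_sim_spec(
      samples = list(
        list(sample_id = "s1", role = "sample", reads = reads,
             composition = c("silver carp|A" = 0.5, "silver carp|B" = 0.5)),
        list(sample_id = "s2", role = "sample", reads = reads,
             composition = c("silver carp|D" = 0.5, "silver carp|H" = 0.5))),
      templates = fx$templates, error_rate = 0.001, hop_rate = hop,
      dimer_rate = dimer, chimera_rate = chim, seed = 6000 + r)
    tr <- simulate_run(spec, tempfile("rates"))$truth
    counts <- counts + c(sum(tr$class == "hop"), sum(tr$class == "dimer"),
                         sum(tr$class == "chimera"))
  }
  N <- n_rep * 2 * reads
  # marginal emission law: hop overrides; dimer precedes chimera
  p <- c(hop = hop,
         dimer = dimer * (1 - hop),
         chimera = (1 - dimer) * chim * (1 - hop))
  for (k in names(p)) {
    mu <- N * p[[k]]; sd3 <- 3 * sqrt(N * p[[k]] * (1 - p[[k]]))
    expect_gt(counts[[k]], mu - sd3)
    expect_lt(counts[[k]], mu + sd3)
  }
})

test_that("truth rows account for every emitted read and NTCs emit artifacts only", {
  spec <- run_sim_spec(
    samples = list(
      list(sample_id = "s1", role = "sample", reads = 500,
           composition = c("silver carp|A" = 1)),
      list(sample_id = "ntc1", role = "ntc", reads = 30)),
    templates = fx$templates, error_rate = 0.001, hop_rate = 0.05,
    dimer_rate = 0.02, seed = 505)
  dir <- tempfile("acct")
  sim <- simulate_run(spec, dir)
  expect_equal(nrow(sim$truth), 530L)
  man <- read_manifest(sim$manifest)
  n_fastq <- vapply(man$fastq_r1, function(f) nrow(read_fastq(f)), 0)
  expect_equal(unname(n_fastq),
               as.integer(table(factor(sim$truth$library, levels = man$sample_id))))
  ntc_rows <- sim$truth[sim$truth$origin == "ntc1", ]
  expect_true(all(ntc_rows$class %in% c("dimer", "hop")))
  # hopped rows land in a different library but keep their origin label
  hops <- sim$truth[sim$truth$class == "hop", ]
  expect_true(all(hops$library != hops$origin))
})

test_that("mock control inserts stay far from the panel and each other", {
  mocks <- fx$mocks
  expect_equal(length(mocks), 10L)
  expect_true(all(nchar(mocks) == 135L))
  for (m in mocks) {
    expect_true(all(vapply(fx$inserts$insert, oracle_hamming, 0, m) >= 30))
    others <- setdiff(mocks, m)
    expect_true(all(vapply(others, oracle_hamming, 0, m) >= 30))
  }
  expect_identical(mock_control_inserts(10, fx$inserts$insert, seed = 12), mocks)
})

test_that("simulation specs are validated", {
  expect_error(run_sim_spec(
    samples = list(list(sample_id = "s", role = "sample", reads = 10,
                        composition = c("silver carp|A" = 0.4))),
    templates = fx$templates, seed = 1), "sum to 1")
  expect_error(run_sim_spec(
    samples = list(list(sample_id = "s", role = "sample", reads = 10,
                        composition = c(nope = 1))),
    templates = fx$templates, seed = 1), "unknown template")
  expect_error(run_sim_spec(
    samples = list(list(sample_id = "s", role = "wrong", reads = 10,
                        composition = c("silver carp|A" = 1))),
    templates = fx$templates, seed = 1), "unknown role")
  expect_error(run_sim_spec(
    samples = list(list(sample_id = "s", role = "sample", reads = 10,
                        composition = c("silver carp|A" = 1))),
    templates = fx$templates, hop_rate = 1, seed = 1), "rates")
})
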