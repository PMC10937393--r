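test_that("simulation is bitwise reproducible for a fixed seed", {
  tpl <- toy_template()
  model <- expansion_model(tpl, N = 12, M = 30, read_length = 200L)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.fastq.gz"); f2 <- file.path(dir, "b.fastq.gz")
  s1 <- simulate_sample(model, 300, seed = 42, fastq = f1)
  s2 <- simulate_sample(model, 300, seed = 42, fastq = f2)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_identical(readLines(gzfile(f1)), readLines(gzfile(f2)))
  s3 <- simulate_sample(model, 300, seed = 43)
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))
})

test_that("a noise-free two-allele model yields mass only at N and M", {
  tpl <- toy_template()
  model <- expansion_model(tpl, N = 12, M = 30, epsilon = 0, stutter_s = 0,
                           p_unexpanded = 1, allele_balance = 0.5,
                           read_length = 200L)
  sim <- simulate_sample(model, 2000, seed = 8)
  sz <- size_sample(sim$reads$sequence, build_ladder(tpl))
  h <- sz$histogram
  expect_equal(sum(h$count[!h$i %in% c(12, 30)]), 0)
  expect_equal(sum(h$count), 2000)
  # allele balance within binomial sampling error (4 sd)
  expect_lt(abs(h$count[h$i == 30] - 1000), 4 * sqrt(2000 * 0.25))
  # with stutter disabled the pipeline histogram equals the truth histogram
  truth_counts <- table(factor(sim$truth$obs_len, levels = h$i))
  expect_equal(h$count, as.numeric(truth_counts))
})

test_that("no simulated molecule exceeds the ladder ceiling", {
  tpl <- toy_template(i_max = 40)
  model <- expansion_model(tpl, N = 12, M = 35, gain_mean = 30,
                           gain_shape = 2, p_unexpanded = 0.2,
                           read_length = 200L)
  sim <- simulate_sample(model, 1000, seed = 13)
  expect_true(all(sim$truth$obs_len <= 40))
  expect_true(all(sim$truth$true_len <= 40))
})

test_that("MSN-like preset hits its design targets on the truth table", {
  tpl <- htt_exon1_template()
  preset <- cell_type_preset("msn")
  model <- do.call(expansion_model,
                   c(list(template = tpl, N = 18, M = 44), preset))
  sim <- simulate_sample(model, 20000, seed = 17)
  mut <- sim$truth[sim$truth$allele == "mutant", ]
  # about half of mutant molecules gain more than 20 repeat units
  expect_equal(mean(mut$true_len - 44 > 20), 0.5, tolerance = 0.05)
  # truth MSLG close to the analytic (1 - p_unexpanded) * mean gain
  expect_equal(truth_mslg(sim$truth, 44),
               (1 - preset$p_unexpanded) * preset$gain_mean,
               tolerance = 0.1 * (1 - preset$p_unexpanded) * preset$gain_mean)
})

test_that("glia-like preset is stable (truth MSLG under 1 RU)", {
  tpl <- htt_exon1_template()
  model <- do.call(expansion_model,
                   c(list(template = tpl, N = 18, M = 44),
                     cell_type_preset("glia")))
  sim <- simulate_sample(model, 5000, seed = 19)
  expect_lt(truth_mslg(sim$truth, 44), 1)
})

test_that("make_cohort emits one sample per donor x cell type with roles", {
  cfg <- cohort_config(donors = 3L,
                       cell_types = c(dMSN = "msn", iMSN = "msn",
                                      CHAT_IN = "chat", glia = "glia"),
                       n_reads = 50L)
  dir <- withr::local_tempdir()
  ch <- make_cohort(cfg, seed = 5, out_dir = dir)
  expect_equal(nrow(ch$manifest), 12L)
  expect_true(all(file.exists(ch$manifest$fastq_path)))
  expect_equal(sum(ch$manifest$role == "allele_reference"), 3L)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  # same seed reproduces, different seed does not
  ch2 <- make_cohort(cfg, seed = 5)
  ch3 <- make_cohort(cfg, seed = 6)
  expect_identical(ch2$truth_summary, ch$truth_summary)
  expect_false(identical(ch2$truth_summary$truth_mslg,
                         ch3$truth_summary$truth_mslg))
  # duplicate sample ids rejected
  cfg_bad <- cfg
  cfg_bad$donors <- cfg$donors[c(1, 1), ]
  expect_error(make_cohort(cfg_bad, seed = 1), "duplicate",
               class = "strgain_config_error")
})

test_that("cohort truth MSLG separates expanding from stable presets", {
  cfg <- cohort_config(donors = 2L,
                       cell_types = c(MSN = "msn", glia = "glia"),
                       n_reads = 2000L)
  ch <- make_cohort(cfg, seed = 9)
  ts <- ch$truth_summary
  expect_true(all(ts$truth_mslg[ts$cell_type == "glia"] < 1))
  expect_true(all(ts$truth_mslg[ts$cell_type == "MSN"] > 5))
})
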