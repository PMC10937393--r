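make_bimodal_hist <- function(N, M, n_reads = 2000, shoulder = 0.1,
                              balance = 0.5) {
  nN <- round(n_reads * (1 - balance))
  nM <- n_reads - nN
  counts <- c(
    stats::setNames(c(shoulder * nN / 2, nN, shoulder * nN / 2,
                      shoulder^2 * nN), as.character(N + c(-2, 0, 1, 2))),
    stats::setNames(c(shoulder * nM / 2, nM, shoulder * nM / 2),
                    as.character(M + c(-1, 0, 1))))
  repeat_histogram(counts, i_min = 1, i_max = 113)
}

test_that("progenitor lengths come from the two histogram modes", {
  h <- make_bimodal_hist(17, 44)
  call <- call_progenitor_lengths(h)
  expect_equal(call$N, 17)
  expect_equal(call$M, 44)
})

test_that("equal-height modes are ordered with N the smaller", {
  h <- repeat_histogram(c(`20` = 500, `40` = 500), i_min = 1, i_max = 113)
  call <- call_progenitor_lengths(h)
  expect_equal(call$N, 20)
  expect_equal(call$M, 40)
})

test_that("single-mode and underpowered histograms are explicit errors", {
  single <- repeat_histogram(c(`30` = 1000, `31` = 40), i_min = 1, i_max = 113)
  expect_error(call_progenitor_lengths(single), "single-mode",
               class = "strgain_allele_error")
  thin <- repeat_histogram(c(`17` = 50, `44` = 50), i_min = 1, i_max = 113)
  expect_error(call_progenitor_lengths(thin), "insufficient",
               class = "strgain_allele_error")
  # a secondary peak below the prominence floor does not qualify
  weak <- repeat_histogram(c(`17` = 1000, `44` = 20), i_min = 1, i_max = 113)
  expect_error(call_progenitor_lengths(weak), "single-mode",
               class = "strgain_allele_error")
})

test_that("mode calling is exact across seeds with stutter shoulders", {
  for (s in 1:25) {
    withr::local_seed(3000 + s)
    N <- sample(10:25, 1)
    M <- N + sample(10:60, 1)
    h <- make_bimodal_hist(N, M, shoulder = runif(1, 0.05, 0.2),
                           balance = runif(1, 0.35, 0.65))
    call <- call_progenitor_lengths(h)
    expect_equal(c(call$N, call$M), c(N, M))
  }
})

test_that("structure detection is self-consistent on canonical reads", {
  tpl <- toy_template()
  lad <- build_ladder(tpl)
  model <- expansion_model(tpl, N = 12, M = 30, epsilon = 0.003,
                           stutter_s = 0.03, p_unexpanded = 0.9,
                           read_length = 200L)
  sim <- simulate_sample(model, 500, seed = 21)
  st <- detect_structure(sim$reads$sequence, tpl)
  expect_false(st$atypical)
  expect_false(st$conflicting)
  expect_true(st$interruption_present)
  expect_equal(st$cassette_codon_counts[["caa_cag"]], 2L)
  expect_equal(st$cassette_codon_counts[["ccg_tract"]], 3L)
  # deterministic
  expect_identical(unclass(detect_structure(sim$reads$sequence, tpl)),
                   unclass(st))
})

test_that("a deleted interruption cassette is detected as atypical", {
  canon <- toy_template()
  atyp <- toy_template(interruption = FALSE)
  model <- expansion_model(atyp, N = 12, M = 30, epsilon = 0.003,
                           stutter_s = 0, p_unexpanded = 0.9,
                           read_length = 200L)
  sim <- simulate_sample(model, 500, seed = 22)
  st <- detect_structure(sim$reads$sequence, canon)
  expect_true(st$atypical)
  expect_false(st$interruption_present)
})

test_that("two structural alleles are reported with frequencies, not chosen", {
  canon <- toy_template(ccg_n = 3)
  short <- toy_template(ccg_n = 1)
  mk <- function(tpl, seed) {
    simulate_sample(expansion_model(tpl, N = 12, M = 30, epsilon = 0,
                                    stutter_s = 0, p_unexpanded = 0.9,
                                    read_length = 200L),
                    400, seed = seed)$reads$sequence
  }
  mixed <- c(mk(canon, 31), mk(short, 32))
  st <- detect_structure(mixed, canon)
  expect_true(st$conflicting)
  expect_equal(nrow(st$alternatives), 2L)
  expect_equal(sort(st$alternatives$frequency), c(0.5, 0.5), tolerance = 0.02)
})

test_that("atypical reads are resized correctly on a structure-matched ladder", {
  canon <- toy_template(ccg_n = 3)
  atyp <- toy_template(interruption = FALSE, ccg_n = 1)
  model <- expansion_model(atyp, N = 12, M = 30, epsilon = 0,
                           stutter_s = 0, p_unexpanded = 1,
                           read_length = 200L)
  sim <- simulate_sample(model, 500, seed = 23)
  lad <- build_ladder(canon)
  before <- size_sample(sim$reads$sequence, lad, sample_id = "atyp")
  correct_before <- sum(before$histogram$count[before$histogram$i %in% c(12, 30)])
  st <- detect_structure(sim$reads$sequence, canon)
  expect_true(st$atypical)
  after <- resize_if_atypical(before, sim$reads$sequence, canon, st)
  expect_lte(after$qc$n_unassigned, before$qc$n_unassigned)
  h <- after$histogram
  expect_equal(sum(h$count[h$i %in% c(12, 30)]), 500)
  expect_gt(sum(h$count[h$i %in% c(12, 30)]), correct_before)
  # canonical structure: resize is a no-op returning the input
  canon_sim <- simulate_sample(
    expansion_model(canon, N = 12, M = 30, epsilon = 0, stutter_s = 0,
                    p_unexpanded = 1, read_length = 200L), 300, seed = 24)
  canon_sz <- size_sample(canon_sim$reads$sequence, build_ladder(canon))
  canon_st <- detect_structure(canon_sim$reads$sequence, canon)
  expect_identical(
    resize_if_atypical(canon_sz, canon_sim$reads$sequence, canon, canon_st),
    canon_sz)
})
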