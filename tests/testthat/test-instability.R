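# independent brute-force oracles written directly from the formulas
oracle_rose_normal <- function(h, N) {
  s <- 0
  for (j in (N + 1):(N + 3)) s <- s + sum(h$count[h$i == j])
  s / h$count[h$i == N]
}
oracle_rose_mutant <- function(h, M, i_max = 113) {
  s <- 0
  for (j in seq(M + 1, i_max)) s <- s + sum(h$count[h$i == j])
  s / h$count[h$i == M]
}
oracle_mslg <- function(h, M, i_max = 113) {
  num <- 0; den <- 0
  for (j in seq(M, i_max)) {
    num <- num + sum(h$count[h$i == j] * j)
    den <- den + sum(h$count[h$i == j])
  }
  num / den - M
}

test_that("RoSE and MSLG reproduce the printed-formula arithmetic exactly", {
  N <- 18; M <- 44
  h <- repeat_histogram(
    stats::setNames(c(1000, 30, 20, 10, 500, 500),
                    c(N, N + 1, N + 2, N + 3, M, M + 10)),
    i_min = 1, i_max = 113)
  expect_equal(rose_normal(h, N), 0.06)
  expect_equal(mslg(h, M), 5)
  expect_equal(rose_mutant(h, M), 1)
  # support: bins beyond N+3 and below M never contribute
  h2 <- repeat_histogram(
    stats::setNames(c(1000, 30, 20, 10, 999, 500, 500),
                    c(N, N + 1, N + 2, N + 3, N + 4, M, M + 10)),
    i_min = 1, i_max = 113)
  expect_equal(rose_normal(h2, N), 0.06)
  expect_equal(mslg(h2, M), 5)
  # degenerate supports
  h3 <- repeat_histogram(stats::setNames(c(100, 200), c(N, M)),
                         i_min = 1, i_max = 113)
  expect_equal(rose_normal(h3, N), 0)
  expect_equal(rose_mutant(h3, M), 0)
  expect_equal(mslg(h3, M), 0)
})

test_that("statistics match brute-force oracles on random histograms", {
  withr::local_seed(515)
  for (rep in 1:25) {
    N <- sample(10:25, 1)
    M <- N + sample(8:60, 1)
    h <- random_hist()
    h$count[h$i == N] <- h$count[h$i == N] + 100
    h$count[h$i == M] <- h$count[h$i == M] + 100
    expect_equal(rose_normal(h, N), oracle_rose_normal(h, N),
                 tolerance = 1e-12)
    expect_equal(rose_mutant(h, M), oracle_rose_mutant(h, M),
                 tolerance = 1e-12)
    expect_equal(mslg(h, M), oracle_mslg(h, M), tolerance = 1e-12)
  }
})

test_that("undefined statistics raise errors instead of guessing", {
  h <- repeat_histogram(c(`44` = 100), i_min = 1, i_max = 113)
  expect_error(rose_normal(h, 17), class = "strgain_undefined_statistic")
  expect_error(rose_mutant(h, 50), class = "strgain_undefined_statistic")
  expect_error(mslg(h, 50), class = "strgain_undefined_statistic")
  empty <- repeat_histogram(c(`44` = 0), i_min = 1, i_max = 113)
  expect_error(normalize_histogram(empty),
               class = "strgain_undefined_statistic")
})

test_that("all statistics are invariant under uniform count rescaling", {
  withr::local_seed(99)
  h <- random_hist()
  N <- 12; M <- 50
  h$count[h$i == N] <- 500
  h$count[h$i == M] <- 400
  for (c in c(0.25, 3, 1000)) {
    hs <- h; hs$count <- hs$count * c
    expect_equal(rose_normal(hs, N), rose_normal(h, N))
    expect_equal(rose_mutant(hs, M), rose_mutant(h, M))
    expect_equal(mslg(hs, M), mslg(h, M))
  }
})

test_that("moving mutant-range mass upward strictly increases MSLG", {
  withr::local_seed(7)
  M <- 40
  h <- repeat_histogram(stats::setNames(c(200, 100, 50), c(40, 55, 70)),
                        i_min = 1, i_max = 113)
  base <- mslg(h, M)
  for (rep in 1:10) {
    from <- sample(c(40, 55), 1)
    to <- from + sample(5:30, 1)
    h2 <- h
    h2$count[h2$i == from] <- h2$count[h2$i == from] - 10
    h2$count[h2$i == to] <- h2$count[h2$i == to] + 10
    expect_gt(mslg(h2, M), base)
  }
})

test_that("normalization scales to 1000 without changing MSLG", {
  h <- repeat_histogram(c(`44` = 2000, `54` = 2000), i_min = 1, i_max = 113)
  nh <- normalize_histogram(h)
  expect_equal(nh$count[nh$i == 44], 500)
  expect_equal(nh$count[nh$i == 54], 500)
  expect_equal(sum(nh$count), 1000, tolerance = 1e-9)
  single <- normalize_histogram(
    repeat_histogram(c(`40` = 37), i_min = 1, i_max = 113))
  expect_equal(single$count[single$i == 40], 1000)
  withr::local_seed(31)
  for (rep in 1:10) {
    h <- random_hist()
    M <- sample(h$i[h$count > 0], 1)
    expect_equal(mslg(normalize_histogram(h), M), mslg(h, M),
                 tolerance = 1e-12)
  }
})

test_that("gain distribution is a proper distribution over g >= 0", {
  M <- 44
  h <- repeat_histogram(stats::setNames(c(50, 50), c(M, M + 20)),
                        i_min = 1, i_max = 113)
  gd <- gain_distribution(h, M)
  expect_equal(gd$fraction[gd$gain == 0], 0.5)
  expect_equal(gd$fraction[gd$gain == 20], 0.5)
  all_at_m <- gain_distribution(
    repeat_histogram(c(`44` = 10), i_min = 1, i_max = 113), 44)
  expect_equal(all_at_m$fraction[all_at_m$gain == 0], 1)
  withr::local_seed(8)
  for (rep in 1:10) {
    h <- random_hist()
    M <- sample(h$i[h$count > 0], 1)
    gd <- gain_distribution(h, M)
    expect_equal(sum(gd$fraction), 1, tolerance = 1e-12)
    expect_true(all(gd$gain >= 0))
  }
})

test_that("instability_stats assembles the per-sample row with QC fields", {
  h <- repeat_histogram(
    stats::setNames(c(1000, 60, 7, 500, 250), c(17, 18, 30, 44, 64)),
    i_min = 1, i_max = 113, locus_id = "HTT_ex1", sample_id = "s1")
  call <- structure(list(N = 17, M = 44), class = "allele_call")
  st <- instability_stats(h, call)
  expect_equal(st$rose_normal, 0.06)
  expect_equal(st$rose_mutant, 250 / 500)
  expect_equal(st$mslg, (500 * 44 + 250 * 64) / 750 - 44)
  expect_equal(st$n_intermediate_reads, 7)
  expect_equal(st$n_mutant_reads, 750)
  expect_equal(st$n_normal_reads, 1060)
  # intermediate bins affect no statistic
  h2 <- h; h2$count[h2$i == 30] <- 400
  st2 <- instability_stats(h2, call)
  expect_equal(st2[c("rose_normal", "rose_mutant", "mslg")],
               st[c("rose_normal", "rose_mutant", "mslg")])
  expect_error(instability_stats(h, structure(list(N = 44, M = 17),
                                              class = "allele_call")),
               class = "strgain_allele_error")
})
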