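test_that("an error-free spanning read is assigned its true index at cost 0", {
  lad <- build_ladder(htt_exon1_template())
  a <- assign_read(substr(lad$sequence[lad$i == 44], 1, 400), lad)
  expect_equal(a$assigned_i, 44L)
  expect_equal(a$best_score, 0L)
  expect_equal(a$reason, "ok")
  expect_gte(a$margin, 1L)
})

test_that("reads truncated inside the tract tie between ladder members", {
  lad <- build_ladder(toy_template())
  tpl <- attr(lad, "template")
  # ends mid-tract: fits members 20, 21, ... equally well
  rd <- substr(perfect_read(lad, 30), 1, nchar(tpl$upstream_flank) + 3 * 20)
  a <- assign_read(rd, lad)
  expect_equal(a$reason, "tie")
  expect_true(is.na(a$assigned_i))
  costs <- oracle_ladder_costs(rd, lad)
  expect_gte(sum(costs == min(costs)), 2L)  # genuinely equidistant
})

test_that("flank substitutions do not break assignment and match the oracle argmin", {
  withr::local_seed(402)
  lad <- build_ladder(toy_template())
  for (rep in 1:10) {
    i <- sample(5:35, 1)
    rd <- perfect_read(lad, i)
    pos <- sample(c(2:20, nchar(rd) - 0:18), 2)  # flank positions
    for (p in pos)

      rd <- substitute_at(rd, p, sample(setdiff(c("A", "C", "G", "T"),
                                                substr(rd, p, p)), 1))
    a <- assign_read(rd, lad)
    costs <- oracle_ladder_costs(rd, lad)
    expect_equal(a$assigned_i, i)
    expect_equal(a$assigned_i, lad$i[which.min(costs)])
    expect_equal(a$best_score, min(costs))
  }
})

test_that("classifier equals exhaustive minimal-edit-distance classification", {
  withr::local_seed(707)
  lad <- build_ladder(toy_template())
  bases <- c("A", "C", "G", "T")
  for (rep in 1:120) {
    i <- sample(1:40, 1)
    rd <- perfect_read(lad, i)
    if (runif(1) < 0.3) rd <- substr(rd, 1, sample(30:nchar(rd), 1))
    n_err <- sample(0:5, 1)
    if (n_err > 0) {
      chars <- strsplit(rd, "")[[1]]
      for (p in sample(length(chars), n_err)) {
        op <- sample(3, 1)
        if (op == 1) chars[p] <- sample(setdiff(bases, chars[p]), 1)
        else if (op == 2) chars[p] <- ""
        else chars[p] <- paste0(chars[p], sample(c(bases, "N"), 1))
      }
      rd <- paste(chars, collapse = "")
    }
    if (runif(1) < 0.25) {
      rd <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(rd)))
    }
    got <- assign_read(rd, lad)
    exp <- oracle_classify(rd, lad)
    expect_equal(got$reason, exp$reason)
    expect_equal(got$best_score, exp$best)
    if (exp$reason == "ok") expect_equal(got$assigned_i, exp$i)
  }
})

test_that("N bases count as mismatches, other characters reject the read", {
  lad <- build_ladder(toy_template())
  rd <- substitute_at(perfect_read(lad, 12), 3, "N")
  a <- assign_read(rd, lad)
  expect_equal(a$assigned_i, 12L)
  expect_equal(a$best_score, 1L)
  bad <- assign_read(sub("A", "R", perfect_read(lad, 12)), lad)
  expect_equal(bad$reason, "invalid_chars")
  expect_equal(assign_read("", lad)$reason, "empty_read")
})

test_that("reads stopping within 12 nt of the tract end are too short", {
  lad <- build_ladder(toy_template())
  tpl <- attr(lad, "template")
  end <- nchar(tpl$upstream_flank) + 3 * 10
  rd <- substr(perfect_read(lad, 10), 1, end + 11)
  a <- assign_read(rd, lad)
  expect_equal(a$reason, "too_short")
  rd2 <- substr(perfect_read(lad, 10), 1, end + 12)
  expect_equal(assign_read(rd2, lad)$reason, "ok")
})

test_that("size_sample counts exactly, conserves reads and ignores order", {
  withr::local_seed(11)
  lad <- build_ladder(toy_template())
  reads <- c(rep(perfect_read(lad, 17), 500), rep(perfect_read(lad, 34), 500))
  sz <- size_sample(reads, lad, sample_id = "mix")
  h <- sz$histogram
  expect_equal(h$count[h$i == 17], 500)
  expect_equal(h$count[h$i == 34], 500)
  expect_equal(sum(h$count), 1000)
  expect_equal(sz$qc$n_unassigned, 0L)
  expect_equal(sz$qc$n_assigned + sz$qc$n_unassigned, sz$qc$n_reads)
  shuffled <- size_sample(sample(reads), lad, sample_id = "mix")
  expect_equal(shuffled$histogram$count, h$count)
})

test_that("sizing under substitution error recovers the simulated mixture", {
  tpl <- toy_template()
  lad <- build_ladder(tpl)
  model <- expansion_model(tpl, N = 12, M = 30, epsilon = 0.005,
                           stutter_s = 0, p_unexpanded = 1,
                           read_length = 200L)
  sim <- simulate_sample(model, 2000, seed = 5)
  sz <- size_sample(sim$reads$sequence, lad, sample_id = "eps")
  ok <- sz$assignments$reason == "ok"
  expect_gte(mean(sz$assignments$assigned_i[ok] == sim$truth$obs_len[ok]),
             0.99)
})

test_that("raising the substitution rate never improves assignment accuracy", {
  tpl <- toy_template()
  lad <- build_ladder(tpl)
  eps_grid <- c(0, 0.01, 0.03, 0.06)
  acc <- sapply(1:3, function(s) {
    sapply(eps_grid, function(eps) {
      model <- expansion_model(tpl, N = 12, M = 30, epsilon = eps,
                               stutter_s = 0, p_unexpanded = 0.5,
                               read_length = 200L)
      sim <- simulate_sample(model, 400, seed = 100 + s)
      sz <- size_sample(sim$reads$sequence, lad)
      ok <- sz$assignments$reason == "ok"
      sum(ok & sz$assignments$assigned_i == sim$truth$obs_len) / nrow(sim$truth)
    })
  })
  trend <- rowMeans(acc)
  expect_true(all(diff(trend) <= 0.005))   # non-increasing up to noise
  expect_lt(trend[length(trend)], trend[1])
})

test_that("FASTQ input is parsed, gzip-transparent, and failures are located", {
  lad <- build_ladder(toy_template())
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "reads.fastq.gz")
  reads <- tibble::tibble(
    read_id = c("r1", "r2"),
    sequence = c(perfect_read(lad, 9), perfect_read(lad, 22)))
  strgain:::write_fastq(reads, fq)
  sz <- size_sample(fq, lad, sample_id = "fq")
  expect_equal(sz$assignments$read_id, c("r1", "r2"))
  expect_equal(sort(sz$assignments$assigned_i), c(9L, 22L))

  empty <- file.path(dir, "empty.fastq")
  file.create(empty)
  expect_warning(sze <- size_sample(empty, lad, sample_id = "e"),
                 "empty histogram")
  expect_equal(sum(sze$histogram$count), 0)

  bad <- file.path(dir, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2", "ACGT", "oops", "IIII"), bad)
  expect_error(size_sample(bad, lad), "record 2",
               class = "strgain_io_error")
})
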