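#' Ratio of somatic expansions of the normal allele
#'
#' `RoSE_normal = (R_{N+1} + R_{N+2} + R_{N+3}) / R_N`: reads one to three
#' repeat units longer than the normal allele relative to reads at the
#' normal allele length. Bins beyond `N + 3` never contribute (longer reads
#' are attributed to the mutant allele's range).
#'
#' @param hist A `repeat_histogram` (or [size_sample()] result).
#' @param N Normal-allele repeat count.
#' @return Dimensionless ratio.
#' @export
rose_normal <- function(hist, N) {
  hist <- as_repeat_histogram(hist)
  rn <- hist_count(hist, N)
  if (rn == 0) {
    stop_strgain(sprintf("RoSE undefined: R_N = 0 at N = %d", N),
                 "strgain_undefined_statistic")
  }
  sum(hist_count(hist, N + 1:3)) / rn
}

#' Ratio of somatic expansions of the mutant allele
#'
#' `RoSE_mutant = sum_{i=M+1}^{i_max} R_i / R_M`: all reads longer than the
#' progenitor allele relative to reads at the progenitor length. The upper
#' bound is the ladder ceiling (113 by default).
#'
#' @param hist A `repeat_histogram`.
#' @param M Progenitor (unexpanded mutant) repeat count.
#' @return Dimensionless ratio.
#' @export
rose_mutant <- function(hist, M) {
  hist <- as_repeat_histogram(hist)
  rm_ <- hist_count(hist, M)
  if (rm_ == 0) {
    stop_strgain(sprintf("RoSE undefined: R_M = 0 at M = %d", M),
                 "strgain_undefined_statistic")
  }
  sum(hist$count[hist$i > M]) / rm_
}

#' Mean somatic length gain (RU)
#'
#' The average uninterrupted repeat length over reads at or above the
#' progenitor length, minus the progenitor length:
#' `MSLG = sum_{i=M}^{i_max} (R_i * i) / sum_{i=M}^{i_max} R_i - M`.
#' Contractions of the mutant allele (i < M) are outside the formula's
#' support and are not measured. The statistic is invariant under uniform
#' rescaling of the counts.
#'
#' @param hist A `repeat_histogram`.
#' @param M Progenitor repeat count.
#' @return Mean gain in repeat units, >= 0.
#' @export
mslg <- function(hist, M) {
  hist <- as_repeat_histogram(hist)
  sel <- hist$i >= M
  tot <- sum(hist$count[sel])
  if (tot == 0) {
    stop_strgain(
      sprintf("MSLG undefined: no reads at or above M = %d", M),
      "strgain_undefined_statistic")
  }
  sum(hist$count[sel] * hist$i[sel]) / tot - M
}

#' Scale a histogram to a fixed total read count
#'
#' Rescales every bin by `scale / sum(R_i)` (real values, no rounding), the
#' normalization used for displaying length distributions side by side.
#' All instability statistics are scale-invariant, so this is display-only.
#'
#' @param hist A `repeat_histogram`.
#' @param scale Target total (default 1000 reads).
#' @return A `repeat_histogram` with real-valued counts summing to `scale`.
#' @export
normalize_histogram <- function(hist, scale = 1000) {
  hist <- as_repeat_histogram(hist)
  tot <- sum(hist$count)
  if (tot == 0) {
    stop_strgain("cannot normalize an empty histogram",
                 "strgain_undefined_statistic")
  }
  hist$count <- hist$count * (scale / tot)
  hist
}

#' Distribution of somatic length gains over the mutant-allele range
#'
#' For reads at or above the progenitor length, the fraction carrying each
#' gain `g = i - M` (so `g = 0` is the unexpanded progenitor tract).
#'
#' @param hist A `repeat_histogram`.
#' @param M Progenitor repeat count.
#' @return A tibble with columns `gain` and `fraction` (summing to 1).
#' @export
gain_distribution <- function(hist, M) {
  hist <- as_repeat_histogram(hist)
  sel <- hist$i >= M
  tot <- sum(hist$count[sel])
  if (tot == 0) {
    stop_strgain(
      sprintf("gain distribution undefined: no reads at or above M = %d", M),
      "strgain_undefined_statistic")
  }
  tibble::tibble(gain = hist$i[sel] - M,
                 fraction = hist$count[sel] / tot)
}

#' Per-sample instability statistics
#'
#' Combines the three instability statistics with read accounting into one
#' row per sample: RoSE of both alleles, MSLG, mutant-/normal-range read
#' counts, and the count of intermediate reads with `N + 3 < i < M`, which
#' fall in neither formula's support and are reported for QC only.
#'
#' @param hist A `repeat_histogram` (or [size_sample()] result).
#' @param allele_call An `allele_call` (or a list with `N` and `M`).
#' @return A one-row tibble: `sample_id`, `locus_id`, `N`, `M`,
#'   `rose_normal`, `rose_mutant`, `mslg`, `n_mutant_reads`,
#'   `n_normal_reads`, `n_intermediate_reads`, `n_assigned`.
#' @export
instability_stats <- function(hist, allele_call) {
  hist <- as_repeat_histogram(hist)
  N <- allele_call$N
  M <- allele_call$M
  if (is.null(N) || is.null(M) || N >= M) {
    stop_strgain("allele call must satisfy N < M", "strgain_allele_error")
  }
  tibble::tibble(
    sample_id = attr(hist, "sample_id") %||% NA_character_,
    locus_id = attr(hist, "locus_id") %||% NA_character_,
    N = N, M = M,
    rose_normal = rose_normal(hist, N),
    rose_mutant = rose_mutant(hist, M),
    mslg = mslg(hist, M),
    n_mutant_reads = sum(hist$count[hist$i >= M]),
    n_normal_reads = sum(hist_count(hist, N + 0:3)),
    n_intermediate_reads = sum(hist$count[hist$i > N + 3 & hist$i < M]),
    n_assigned = sum(hist$count))
}
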