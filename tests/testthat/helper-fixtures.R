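# Shared fixtures: a compact locus so alignments stay small, and an
# independent semi-global edit-distance oracle built on Biostrings
# pairwiseAlignment (match 0 / mismatch -1 / gap -1 in "global-local" mode
# scores exactly minus the infix edit distance).

toy_template <- function(i_max = 40L, ccg_n = 3L, interruption = TRUE) {
  cassettes <- list()
  if (interruption) {
    cassettes <- c(cassettes,
                   list(locus_cassette("caa_cag", seq = "CAACAG",
                                       interruption = TRUE)))
  }
  cassettes <- c(cassettes,
                 list(locus_cassette("ccg_tract", unit = "CCG", n = ccg_n)))
  locus_template(
    locus_id = "TOY",
    upstream_flank = "ATGAGCGAAGTTCGACGTTGCCGA",
    downstream_flank = "TGTTTACCCTAAGGGAGACGACAT",
    repeat_unit = "CAG",
    cassettes = cassettes,
    i_min = 1L, i_max = i_max)
}

edit_dist_matrix <- local({
  m <- matrix(-1L, 5, 5,
              dimnames = list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N")))
  diag(m) <- 0L
  m["N", ] <- -1L
  m[, "N"] <- -1L
  m
})

# exact infix edit distances of one read against every ladder member,
# minimum over both orientations (independent of the package's classifier)
oracle_ladder_costs <- function(read, ladder) {
  refs <- Biostrings::DNAStringSet(stats::setNames(ladder$sequence, ladder$id))
  one <- function(rd) {
    -Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(rep(rd, length(refs))), refs,
      type = "global-local", substitutionMatrix = edit_dist_matrix,
      gapOpening = 0, gapExtension = 1))
  }
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(read)))
  pmin(one(read), one(rc))
}

# expected classification from oracle costs under the package's decision rule
oracle_classify <- function(read, ladder, max_error_frac = 0.10, delta = 1L,
                            min_post_anchor = 12L) {
  tpl <- attr(ladder, "template")
  costs <- oracle_ladder_costs(read, ladder)
  m <- nchar(read)
  k <- ceiling(max_error_frac * m - 1e-9)
  best <- min(costs)
  cand <- ladder$i[costs == best]
  if (best > k) {
    list(reason = "max_error", i = NA_integer_, best = best)
  } else if (length(cand) > 1L ||
             sort(costs)[2] - best < delta) {
    list(reason = "tie", i = NA_integer_, best = best)
  } else if (m < nchar(tpl$upstream_flank) + 3L * cand + min_post_anchor) {
    list(reason = "too_short", i = NA_integer_, best = best)
  } else {
    list(reason = "ok", i = cand, best = best)
  }
}

# perfect read (full amplicon, optionally truncated) for repeat count i
perfect_read <- function(ladder, i, length = NA) {
  s <- ladder$sequence[match(i, ladder$i)]
  if (!is.na(length)) s <- substr(s, 1, length)
  s
}

substitute_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

random_hist <- function(i_min = 1L, i_max = 113L, n_bins = 12L) {
  idx <- sort(sample(seq.int(i_min, i_max), n_bins))
  repeat_histogram(stats::setNames(rpois(n_bins, 120) + 1, idx),
                   i_min = i_min, i_max = i_max)
}
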