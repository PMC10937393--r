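#' Sizing parameters
#'
#' Tunables of the ladder classifier. `delta` is the uniqueness margin in
#' edit-distance units: a read is assigned only when exactly one ladder
#' member attains the minimal cost and the runner-up (at a different repeat
#' index) is at least `delta` worse; with the default `delta = 1` any tie
#' leaves the read unassigned rather than breaking it arbitrarily, which
#' would bias the histogram by +/-1 repeat unit. `max_error_frac` bounds the
#' accepted edit distance at `ceiling(max_error_frac * read length)`.
#' `min_post_anchor` is the minimum number of post-tract nucleotides a read
#' must cover beyond the assigned tract, realizing the detection ceiling of
#' single-end reads. Base qualities are ignored throughout.
#'
#' @param delta Integer uniqueness margin, >= 1.
#' @param max_error_frac Maximum accepted edit distance as a fraction of
#'   read length.
#' @param min_post_anchor Minimum post-tract anchor length in nt.
#' @param min_reads Minimum assigned reads required by allele calling and
#'   structure detection.
#' @param min_separation Minimum repeat-unit separation between the two
#'   allele modes in [call_progenitor_lengths()].
#' @param prominence_frac Minimum secondary-mode height as a fraction of the
#'   primary mode.
#' @param smooth Logical; apply 3-point smoothing before mode finding
#'   (default off).
#' @return A `sizing_params` list.
#' @export
sizing_params <- function(delta = 1L, max_error_frac = 0.10,
                          min_post_anchor = 12L, min_reads = 200L,
                          min_separation = 5L, prominence_frac = 0.05,
                          smooth = FALSE) {
  delta <- as.integer(delta)
  if (is.na(delta) || delta < 1L) {
    stop_strgain("`delta` must be an integer >= 1", "strgain_config_error")
  }
  if (!is.numeric(max_error_frac) || max_error_frac < 0 || max_error_frac > 1) {
    stop_strgain("`max_error_frac` must be in [0, 1]", "strgain_config_error")
  }
  structure(
    list(delta = delta, max_error_frac = max_error_frac,
         min_post_anchor = as.integer(min_post_anchor),
         min_reads = as.integer(min_reads),
         min_separation = as.integer(min_separation),
         prominence_frac = prominence_frac, smooth = isTRUE(smooth)),
    class = "sizing_params")
}

reason_levels <- c("ok", "tie", "max_error", "too_short", "invalid_chars",
                   "empty_read")

ladder_parts <- function(ladder) {
  tpl <- ladder_template(ladder)
  list(upstream = tpl$upstream_flank,
       unit = tpl$repeat_unit,
       post = post_tract_seq(tpl),
       i_min = tpl$i_min, i_max = tpl$i_max,
       locus_id = tpl$locus_id)
}

#' Assign reads to ladder members by unique best semi-global alignment
#'
#' Each read is scored against every ladder member with a semi-global edit
#' distance (read aligned end to end, reference free at both ends, unit
#' mismatch/gap costs, `N` counts as a mismatch) in both orientations, and
#' assigned to the member with the strictly minimal cost when that minimum
#' is unique within the margin `delta` and does not exceed
#' `ceiling(max_error_frac * read length)`. Anything else is left
#' unassigned with a reason (`tie`, `max_error`, `too_short`,
#' `invalid_chars`).
#'
#' @param reads Character vector of read sequences (a data frame with a
#'   `sequence` column is also accepted, pipe-friendly).
#' @param ladder A `repeat_ladder` from [build_ladder()].
#' @param params A [sizing_params()].
#' @param read_id Optional read identifiers.
#' @return A tibble with one row per read: `read_id`, `assigned_i`,
#'   `best_score`, `margin` (cost gap to the best-scoring other repeat
#'   index; `NA` only for a single-member ladder), `orientation`, `reason`.
#' @export
assign_read <- function(reads, ladder, params = sizing_params(),
                        read_id = NULL) {
  if (is.data.frame(reads)) {
    read_id <- read_id %||% reads[["read_id"]]
    reads <- reads[["sequence"]]
  }
  stopifnot(is.character(reads))
  parts <- ladder_parts(ladder)
  res <- assign_reads_cpp(toupper(reads), parts$upstream, parts$unit,
                          parts$post, parts$i_min, parts$i_max,
                          params$max_error_frac, params$delta,
                          params$min_post_anchor)
  tibble::tibble(
    read_id = read_id %||% sprintf("read_%06d", seq_along(reads)),
    assigned_i = res$assigned_i,
    best_score = res$best_score,
    margin = res$margin,
    orientation = res$orientation,
    reason = reason_levels[res$reason + 1L])
}

#' Size all reads of a sample and accumulate the repeat-length histogram
#'
#' Streams a FASTQ file (plain or gzip) through [assign_read()] and returns
#' the per-index read counts `R_i` together with the per-read assignment log
#' and unassignment accounting. The result is deterministic and invariant
#' to read order.
#'
#' @param fastq Path to a FASTQ file, or a character vector of read
#'   sequences.
#' @param ladder A `repeat_ladder`.
#' @param params A [sizing_params()].
#' @param sample_id Sample label recorded on the histogram.
#' @return A `sizing_result` list: `histogram` (a `repeat_histogram`
#'   tibble), `assignments` (tibble) and `qc` (list with `n_reads`,
#'   `n_assigned`, `n_unassigned`, `unassigned_by_reason`).
#' @export
size_sample <- function(fastq, ladder, params = sizing_params(),
                        sample_id = NA_character_) {
  parts <- ladder_parts(ladder)
  if (is.character(fastq) && length(fastq) == 1L && file.exists(fastq)) {
    rec <- read_fastq_reads(fastq)
  } else {
    rec <- list(id = sprintf("read_%06d", seq_along(fastq)), seq = fastq)
  }
  if (length(rec$seq) == 0L) {
    rlang::warn(sprintf("no reads for sample '%s': empty histogram", sample_id))
    assignments <- assign_read(character(0), ladder, params)
  } else {
    assignments <- assign_read(rec$seq, ladder, params, read_id = rec$id)
  }
  hist <- new_repeat_histogram(
    counts = tabulate_counts(assignments$assigned_i, parts$i_min, parts$i_max),
    i_min = parts$i_min, i_max = parts$i_max,
    locus_id = parts$locus_id, sample_id = sample_id)
  unassigned <- assignments$reason[assignments$reason != "ok"]
  qc <- list(
    n_reads = nrow(assignments),
    n_assigned = sum(assignments$reason == "ok"),
    n_unassigned = length(unassigned),
    unassigned_by_reason = as.list(table(factor(unassigned,
                                                levels = reason_levels[-1]))))
  attr(hist, "n_unassigned") <- qc$n_unassigned
  structure(list(histogram = hist, assignments = assignments, qc = qc,
                 sample_id = sample_id),
            class = "sizing_result")
}

tabulate_counts <- function(assigned_i, i_min, i_max) {
  idx <- assigned_i[!is.na(assigned_i)]
  counts <- tabulate(idx - i_min + 1L, nbins = i_max - i_min + 1L)
  as.numeric(counts)
}

#' @export
print.sizing_result <- function(x, ...) {
  cat(sprintf("<sizing_result> sample %s: %d reads, %d assigned, %d unassigned\n",
              x$sample_id, x$qc$n_reads, x$qc$n_assigned, x$qc$n_unassigned))
  invisible(x)
}

# Reads a FASTQ file into ids + sequences. Biostrings does the parsing
# (gzip-transparent); on failure the file is re-scanned line-wise to name
# the offending record.
read_fastq_reads <- function(path) {
  if (!file.exists(path)) {
    stop_strgain(sprintf("FASTQ not found: %s", path), "strgain_io_error")
  }
  res <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq"),
    error = function(e) e)
  if (inherits(res, "error")) {
    idx <- locate_bad_fastq_record(path)
    stop_strgain(
      sprintf("malformed FASTQ record %d in '%s'", idx, path),
      "strgain_io_error")
  }
  ids <- sub("\\s.*$", "", names(res))
  list(id = ids, seq = toupper(as.character(res)))
}

locate_bad_fastq_record <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  rec <- 0L
  repeat {
    lines <- readLines(con, n = 4L)
    if (length(lines) == 0L) return(rec + 1L)
    rec <- rec + 1L
    if (length(lines) < 4L || !startsWith(lines[1], "@") ||
        !startsWith(lines[3], "+") ||
        nchar(lines[2]) != nchar(lines[4])) {
      return(rec)
    }
  }
}
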