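#' Construct a repeat-length histogram
#'
#' The histogram records `R_i`, the number of reads uniquely assigned to the
#' reference with `i` uninterrupted repeat units, over the full ladder range
#' so downstream statistics can index any bin directly. Normally produced by
#' [size_sample()]; this constructor exists for building histograms from
#' counts (e.g. in simulations or tests).
#'
#' @param counts Named numeric vector (`names` are repeat indices) or a data
#'   frame with columns `i` and `count`.
#' @param i_min,i_max Grid bounds; bins absent from `counts` are zero.
#' @param locus_id,sample_id Labels carried as attributes.
#' @return A `repeat_histogram` tibble with columns `i`, `count`.
#' @export
repeat_histogram <- function(counts, i_min = 1L, i_max = 113L,
                             locus_id = NA_character_,
                             sample_id = NA_character_) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$count, counts$i)
  }
  idx <- as.integer(names(counts))
  if (anyNA(idx)) {
    stop_strgain("`counts` must be named by integer repeat indices",
                 "strgain_config_error")
  }
  if (any(counts < 0)) {
    stop_strgain("histogram counts must be non-negative",
                 "strgain_config_error")
  }
  grid <- numeric(i_max - i_min + 1L)
  if (any(idx < i_min | idx > i_max)) {
    stop_strgain("count indices outside [i_min, i_max]",
                 "strgain_config_error")
  }
  for (k in seq_along(idx)) {   # accumulate (names may repeat)
    grid[idx[k] - i_min + 1L] <- grid[idx[k] - i_min + 1L] +
      as.numeric(counts[[k]])
  }
  new_repeat_histogram(grid, i_min, i_max, locus_id, sample_id)
}

new_repeat_histogram <- function(counts, i_min, i_max, locus_id, sample_id) {
  out <- tibble::tibble(i = seq.int(i_min, i_max), count = counts)
  attr(out, "i_min") <- as.integer(i_min)
  attr(out, "i_max") <- as.integer(i_max)
  attr(out, "locus_id") <- locus_id
  attr(out, "sample_id") <- sample_id
  class(out) <- c("repeat_histogram", class(out))
  out
}

as_repeat_histogram <- function(x) {
  if (inherits(x, "repeat_histogram")) return(x)
  if (inherits(x, "sizing_result")) return(x$histogram)
  if (is.data.frame(x) && all(c("i", "count") %in% names(x))) {
    return(repeat_histogram(x, i_min = min(x$i), i_max = max(x$i)))
  }
  stop_strgain("expected a repeat_histogram, sizing_result or i/count data frame",
               "strgain_config_error")
}

hist_n_assigned <- function(hist) sum(hist$count)

# count at a single bin; 0 outside the grid
hist_count <- function(hist, i) {
  pos <- match(i, hist$i)
  ifelse(is.na(pos), 0, hist$count[pos])
}

#' Write a histogram as TSV (columns `i`, `count`)
#' @param hist A `repeat_histogram` (or [size_sample()] result).
#' @param path Destination TSV.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(hist, path) {
  hist <- as_repeat_histogram(hist)
  readr::write_tsv(as.data.frame(hist), path)
  invisible(path)
}

#' Read a histogram TSV written by [write_histogram_tsv()]
#' @param path TSV with columns `i` and `count`.
#' @param locus_id,sample_id Labels to attach.
#' @return A `repeat_histogram`.
#' @export
read_histogram_tsv <- function(path, locus_id = NA_character_,
                               sample_id = NA_character_) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  repeat_histogram(df, i_min = min(df$i), i_max = max(df$i),
                   locus_id = locus_id, sample_id = sample_id)
}

#' Write the per-read assignment log as TSV
#' @param result A `sizing_result` (or assignment tibble).
#' @param path Destination TSV.
#' @return `path`, invisibly.
#' @export
write_assignments_tsv <- function(result, path) {
  df <- if (inherits(result, "sizing_result")) result$assignments else result
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write sizing QC (assignment accounting) as JSON
#' @param result A `sizing_result`.
#' @param path Destination JSON.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(result, path) {
  stopifnot(inherits(result, "sizing_result"))
  jsonlite::write_json(result$qc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
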