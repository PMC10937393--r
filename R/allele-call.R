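#' Call progenitor allele lengths from a non-expanding cell type
#'
#' The inherited normal (`N`) and mutant progenitor (`M`) repeat lengths are
#' the two modes of the read-length distribution in a cell type that does
#' not undergo somatic expansion (glia, granule cells). Mode finding is
#' local-maxima based on raw counts (optionally 3-point smoothed): the two
#' highest local maxima separated by at least `min_separation` repeat units
#' qualify, the secondary mode must reach `prominence_frac` of the primary
#' mode's count, and the smaller index is `N` by convention.
#'
#' @param hist A `repeat_histogram` (or [size_sample()] result) from the
#'   designated non-expanding reference sample.
#' @param params A [sizing_params()] supplying `min_reads`,
#'   `min_separation`, `prominence_frac` and `smooth`.
#' @param structure Optional `tract_structure` to record on the call.
#' @return An `allele_call` object with fields `N`, `M`,
#'   `source_sample_id`, `locus_id`, `structure`.
#' @export
call_progenitor_lengths <- function(hist, params = sizing_params(),
                                    structure = NULL) {
  hist <- as_repeat_histogram(hist)
  n_assigned <- hist_n_assigned(hist)
  if (n_assigned < params$min_reads) {
    stop_strgain(
      sprintf("insufficient reads for allele calling: %d assigned < %d required",
              round(n_assigned), params$min_reads),
      "strgain_allele_error")
  }
  y <- hist$count
  if (params$smooth && length(y) >= 3L) {
    y <- (c(0, y[-length(y)]) + y + c(y[-1], 0)) / 3
  }
  peaks <- local_maxima(hist$i, y)
  if (nrow(peaks) == 0L) {
    stop_strgain("no modes found in histogram", "strgain_allele_error")
  }
  peaks <- dplyr::arrange(peaks, dplyr::desc(.data$height))
  primary <- peaks[1, ]
  secondary <- dplyr::filter(
    peaks,
    abs(.data$i - primary$i) >= params$min_separation,
    .data$height >= params$prominence_frac * primary$height)
  if (nrow(secondary) == 0L) {
    stop_strgain(
      "single-mode histogram: only one qualifying mode (possible homozygosity or absent mutant allele)",
      "strgain_allele_error")
  }
  modes <- sort(c(primary$i, secondary$i[1]))
  if (modes[1] == modes[2]) {
    stop_strgain("degenerate allele call: N == M is unsupported",
                 "strgain_allele_error")
  }
  structure(
    list(N = modes[1], M = modes[2],
         source_sample_id = attr(hist, "sample_id"),
         locus_id = attr(hist, "locus_id"),
         structure = structure),
    class = "allele_call")
}

# strict local maxima; plateaus contribute their leftmost bin
local_maxima <- function(i, y) {
  n <- length(y)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  is_peak <- y > 0 & y > left & y >= right
  tibble::tibble(i = i[is_peak], height = y[is_peak])
}

#' @export
print.allele_call <- function(x, ...) {
  cat(sprintf("<allele_call> %s: N = %d, M = %d (reference sample %s)\n",
              x$locus_id %||% "?", x$N, x$M,
              x$source_sample_id %||% "?"))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.allele_call <- function(x, ...) {
  tibble::tibble(locus_id = x$locus_id %||% NA_character_,
                 N = x$N, M = x$M,
                 source_sample_id = x$source_sample_id %||% NA_character_,
                 atypical = if (is.null(x$structure)) NA else x$structure$atypical)
}

#' Serialize an allele call (and its tract structure) to JSON
#' @param call An `allele_call`.
#' @param path Destination JSON.
#' @return `path`, invisibly.
#' @export
write_allele_call_json <- function(call, path) {
  stopifnot(inherits(call, "allele_call"))
  payload <- list(
    locus_id = call$locus_id, N = call$N, M = call$M,
    source_sample_id = call$source_sample_id,
    structure = if (!is.null(call$structure)) unclass(call$structure))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
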