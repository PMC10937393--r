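#' Build the ladder of reference sequences for a locus
#'
#' The ladder is the ordered family of otherwise-identical reference
#' sequences that differ only in the number of uninterrupted repeat units in
#' the variable tract. Reads are sized by unique best alignment against this
#' family; the reference with index `i` is
#' `upstream_flank + repeat_unit x i + cassettes + downstream_flank`.
#'
#' @param template A [locus_template()].
#' @return A tibble of class `repeat_ladder` with columns `i` (integer repeat
#'   count), `id` (FASTA record id, e.g. `"HTT_ex1_CAG044"`) and `sequence`.
#'   The generating template is kept in the `template` attribute.
#' @examples
#' ladder <- build_ladder(htt_exon1_template())
#' nrow(ladder)   # 113 references
#' @export
build_ladder <- function(template) {
  stopifnot(inherits(template, "locus_template"))
  i <- seq.int(template$i_min, template$i_max)
  post <- post_tract_seq(template)
  seqs <- paste0(template$upstream_flank,
                 strrep(template$repeat_unit, i),
                 post)
  out <- tibble::tibble(
    i = as.integer(i),
    id = ladder_ref_id(template$locus_id, template$repeat_unit, i),
    sequence = seqs)
  attr(out, "template") <- template
  class(out) <- c("repeat_ladder", class(out))
  out
}

ladder_ref_id <- function(locus_id, unit, i) {
  sprintf("%s_%s%03d", locus_id, unit, i)
}

#' Parse the repeat index out of a ladder FASTA record id
#'
#' @param id Character vector of record ids such as `"HTT_ex1_CAG044"`.
#' @return Integer vector of repeat counts (`NA` where the id does not parse).
#' @export
parse_ladder_id <- function(id) {
  m <- regmatches(id, regexpr("_[ACGT]{3}([0-9]{3})$", id))
  out <- rep(NA_integer_, length(id))
  ok <- lengths(regmatches(id, gregexpr("_[ACGT]{3}[0-9]{3}$", id))) == 1L
  out[ok] <- as.integer(substr(m, nchar(m) - 2L, nchar(m)))
  out
}

ladder_template <- function(ladder) {
  tpl <- attr(ladder, "template")
  if (is.null(tpl)) {
    stop_strgain(
      "ladder has no attached locus template; build it with build_ladder()",
      "strgain_config_error")
  }
  tpl
}

#' Write a ladder as multi-FASTA
#'
#' Record ids encode the locus and the repeat index (`<locus>_<unit><iii>`)
#' so that the index can be parsed back with [parse_ladder_id()].
#'
#' @param ladder A `repeat_ladder` from [build_ladder()].
#' @param path Destination file (`.fa`/`.fasta`; gzip if the name ends `.gz`).
#' @return `path`, invisibly.
#' @export
write_ladder_fasta <- function(ladder, path) {
  stopifnot(inherits(ladder, "repeat_ladder"))
  dss <- Biostrings::DNAStringSet(stats::setNames(ladder$sequence, ladder$id))
  tryCatch(
    Biostrings::writeXStringSet(dss, path,
                                compress = grepl("\\.gz$", path)),
    error = function(e) {
      stop_strgain(sprintf("cannot write ladder FASTA to '%s': %s",
                           path, conditionMessage(e)),
                   "strgain_io_error")
    })
  invisible(path)
}

#' Read a ladder back from multi-FASTA
#'
#' @param path Multi-FASTA written by [write_ladder_fasta()].
#' @param template Optional [locus_template()] to re-attach so the ladder can
#'   be used for sizing.
#' @return A `repeat_ladder` tibble.
#' @export
read_ladder_fasta <- function(path, template = NULL) {
  if (!file.exists(path)) {
    stop_strgain(sprintf("ladder FASTA not found: %s", path),
                 "strgain_io_error")
  }
  dss <- Biostrings::readDNAStringSet(path)
  out <- tibble::tibble(
    i = parse_ladder_id(names(dss)),
    id = names(dss),
    sequence = unname(as.character(dss)))
  out <- dplyr::arrange(out, .data$i)
  if (!is.null(template)) attr(out, "template") <- template
  class(out) <- c("repeat_ladder", class(out))
  out
}
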