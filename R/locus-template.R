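#' Declare a fixed sequence cassette lying between the repeat tract and the
#' downstream flank
#'
#' Amplicon loci such as HTT exon 1 carry fixed sequence elements between the
#' variable repeat tract and the downstream flank: an interruption cassette
#' (e.g. the CAA-CAG element), spacer codons, and codon runs such as the CCG
#' (polyproline) tract. Cassettes are never counted in the uninterrupted
#' repeat index `i`; they only shape the reference sequences.
#'
#' @param name Cassette label, unique within a template.
#' @param seq Literal DNA sequence of the cassette. Give either `seq` or
#'   `unit` + `n`.
#' @param unit 3-nt codon repeated to form the cassette (e.g. `"CCG"`).
#' @param n Number of codon copies when `unit` is given.
#' @param interruption Logical; `TRUE` marks the cassette whose
#'   presence/absence defines an interruption of the repeat tract. Structure
#'   detection reports such cassettes as present/absent rather than counting
#'   codons.
#' @return A `locus_cassette` list with fields `name`, `seq`, `unit`,
#'   `n_codons`, `interruption`.
#' @export
locus_cassette <- function(name, seq = NULL, unit = NULL, n = NULL,
                           interruption = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_strgain("cassette `name` must be a non-empty string",
                 "strgain_config_error")
  }
  if (is.null(seq)) {
    if (is.null(unit) || is.null(n)) {
      stop_strgain(
        sprintf("cassette '%s': give either `seq` or both `unit` and `n`", name),
        "strgain_config_error")
    }
    check_dna(unit, sprintf("cassette '%s' unit", name))
    if (nchar(unit) != 3L) {
      stop_strgain(sprintf("cassette '%s' unit must be 3 nt", name),
                   "strgain_config_error")
    }
    n <- as.integer(n)
    if (is.na(n) || n < 0L) {
      stop_strgain(sprintf("cassette '%s' codon count must be >= 0", name),
                   "strgain_config_error")
    }
    seq <- strrep(unit, n)
  } else {
    check_dna(seq, sprintf("cassette '%s' seq", name), allow_empty = TRUE)
    if (nchar(seq) %% 3L != 0L) {
      stop_strgain(
        sprintf("cassette '%s' sequence length must be a codon multiple", name),
        "strgain_config_error")
    }
    unit <- NULL
    n <- nchar(seq) %/% 3L
  }
  structure(
    list(name = name, seq = seq, unit = unit, n_codons = as.integer(n),
         interruption = isTRUE(interruption)),
    class = "locus_cassette")
}

#' Describe an amplicon locus with a variable trinucleotide repeat tract
#'
#' A locus template is the declarative description from which the ladder of
#' reference sequences is generated: fixed upstream and downstream flanks, a
#' 3-nt repeat unit whose uninterrupted copy number `i` varies between
#' `i_min` and `i_max`, and an ordered list of fixed cassettes between the
#' tract and the downstream flank.
#'
#' @param locus_id Short locus label (e.g. `"HTT_ex1"`).
#' @param upstream_flank,downstream_flank Fixed DNA flanks (primer-proximal
#'   and distal). Must be non-empty and over A/C/G/T.
#' @param repeat_unit 3-nt repeat unit, default `"CAG"`.
#' @param cassettes Ordered list of [locus_cassette()] objects.
#' @param i_min,i_max Inclusive ladder bounds; `i_max` is capped at 113, the
#'   longest tract reliably sized from a 400-nt single-end read.
#' @return A `locus_template` object.
#' @seealso [build_ladder()], [apply_structure()]
#' @export
locus_template <- function(locus_id, upstream_flank, downstream_flank,
                           repeat_unit = "CAG", cassettes = list(),
                           i_min = 1L, i_max = 113L) {
  if (!is.character(locus_id) || length(locus_id) != 1L || !nzchar(locus_id)) {
    stop_strgain("`locus_id` must be a non-empty string", "strgain_config_error")
  }
  check_dna(upstream_flank, "upstream_flank")
  check_dna(downstream_flank, "downstream_flank")
  check_dna(repeat_unit, "repeat_unit")
  if (nchar(repeat_unit) != 3L) {
    stop_strgain("`repeat_unit` must be 3 nt", "strgain_config_error")
  }
  i_min <- as.integer(i_min); i_max <- as.integer(i_max)
  if (is.na(i_min) || i_min < 1L) {
    stop_strgain("`i_min` must be >= 1", "strgain_config_error")
  }
  if (is.na(i_max) || i_max > 113L) {
    stop_strgain("`i_max` must be <= 113", "strgain_config_error")
  }
  if (i_min > i_max) {
    stop_strgain("`i_min` must not exceed `i_max`", "strgain_config_error")
  }
  if (!is.list(cassettes) ||
      !all(vapply(cassettes, inherits, logical(1), "locus_cassette"))) {
    stop_strgain("`cassettes` must be a list of locus_cassette objects",
                 "strgain_config_error")
  }
  nms <- vapply(cassettes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop_strgain("cassette names must be unique", "strgain_config_error")
  }
  structure(
    list(locus_id = locus_id,
         upstream_flank = upstream_flank,
         downstream_flank = downstream_flank,
         repeat_unit = repeat_unit,
         cassettes = cassettes,
         i_min = i_min, i_max = i_max),
    class = "locus_template")
}

check_dna <- function(x, field, allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop_strgain(sprintf("`%s` must be a single DNA string", field),
                 "strgain_config_error")
  }
  if (!allow_empty && !nzchar(x)) {
    stop_strgain(sprintf("`%s` must be non-empty", field),
                 "strgain_config_error")
  }
  if (grepl("[^ACGT]", x)) {
    stop_strgain(
      sprintf("`%s` contains characters outside A/C/G/T", field),
      "strgain_config_error")
  }
  invisible(x)
}

#' @export
print.locus_template <- function(x, ...) {
  cat(sprintf("<locus_template> %s\n", x$locus_id))
  cat(sprintf("  repeat unit : %s, i in [%d, %d]\n",
              x$repeat_unit, x$i_min, x$i_max))
  cat(sprintf("  flanks      : %d nt upstream / %d nt downstream\n",
              nchar(x$upstream_flank), nchar(x$downstream_flank)))
  for (cs in x$cassettes) {
    cat(sprintf("  cassette    : %s (%d codons%s)\n", cs$name, cs$n_codons,
                if (cs$interruption) ", interruption" else ""))
  }
  invisible(x)
}

# Concatenated fixed sequence between the variable tract and the end of the
# amplicon (cassettes + downstream flank).
post_tract_seq <- function(template) {
  paste0(paste(vapply(template$cassettes, `[[`, character(1), "seq"),
               collapse = ""),
         template$downstream_flank)
}

#' Default HTT exon 1 template
#'
#' Canonical structure of the HTT exon 1 amplicon: a variable uninterrupted
#' CAG tract followed by the CAA-CAG interruption cassette, a CCG-CCA spacer,
#' the CCG (polyproline) tract and a CCT run, then the downstream flank.
#' Flank sequences here are synthetic placeholders (the algorithm is
#' structure-parametric); replace them with assay-specific flanks via the
#' arguments or a YAML locus config for real data.
#'
#' @param upstream_flank,downstream_flank Override the synthetic default
#'   flanks with assay-specific sequences.
#' @param ccg_n Codon count of the CCG tract in the canonical reference.
#' @param i_max Upper ladder bound (default 113).
#' @return A [locus_template()].
#' @export
htt_exon1_template <- function(
    upstream_flank = "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCT",
    downstream_flank = "CAACTTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCT",
    ccg_n = 7L, i_max = 113L) {
  locus_template(
    locus_id = "HTT_ex1",
    upstream_flank = upstream_flank,
    downstream_flank = downstream_flank,
    repeat_unit = "CAG",
    cassettes = list(
      locus_cassette("caa_cag", seq = "CAACAG", interruption = TRUE),
      locus_cassette("ccg_cca", seq = "CCGCCA"),
      locus_cassette("ccg_tract", unit = "CCG", n = ccg_n),
      locus_cassette("cct_run", unit = "CCT", n = 2L)),
    i_min = 1L, i_max = i_max)
}

#' Default ATXN3 exon 10 template
#'
#' ATXN3 exon 10 carries an uninterrupted CAG tract without an interruption
#' cassette; a single short fixed cassette precedes the downstream flank.
#' Flanks are synthetic placeholders, overridable for real assays.
#'
#' @inheritParams htt_exon1_template
#' @return A [locus_template()].
#' @export
atxn3_exon10_template <- function(
    upstream_flank = "GTTAGTTTTGGTTAGGCACGGAACGCTATCGAGCGCGTAAGCGCC",
    downstream_flank = "AACCCGCATTTACGAAGTACCCATCGTATGTAATAAGACCTCGAGTACGT",
    i_max = 113L) {
  locus_template(
    locus_id = "ATXN3_ex10",
    upstream_flank = upstream_flank,
    downstream_flank = downstream_flank,
    repeat_unit = "CAG",
    cassettes = list(locus_cassette("ggg_spacer", seq = "GGGTAA")),
    i_min = 1L, i_max = i_max)
}

#' Read a locus template from a YAML config file
#'
#' The config names flanks inline or by FASTA reference
#' (`upstream_flank: {fasta: path, id: record}`); cassettes are a list of
#' maps with `name` and either `seq` or `unit` + `n`, plus optional
#' `interruption: true`.
#'
#' @param path Path to a YAML file.
#' @return A [locus_template()].
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path)) {
    stop_strgain(sprintf("locus config not found: %s", path),
                 "strgain_io_error")
  }
  cfg <- yaml::read_yaml(path)
  flank <- function(x, field) {
    if (is.list(x)) {
      if (is.null(x$fasta) || is.null(x$id)) {
        stop_strgain(sprintf("`%s` FASTA reference needs `fasta` and `id`",
                             field), "strgain_config_error")
      }
      fa <- Biostrings::readDNAStringSet(x$fasta)
      if (!x$id %in% names(fa)) {
        stop_strgain(sprintf("record '%s' not found in %s", x$id, x$fasta),
                     "strgain_config_error")
      }
      as.character(fa[[x$id]])
    } else {
      as.character(x)
    }
  }
  cassettes <- lapply(cfg$cassettes %||% list(), function(cs) {
    locus_cassette(cs$name, seq = cs$seq, unit = cs$unit, n = cs$n,
                   interruption = isTRUE(cs$interruption))
  })
  locus_template(
    locus_id = cfg$locus_id,
    upstream_flank = flank(cfg$upstream_flank, "upstream_flank"),
    downstream_flank = flank(cfg$downstream_flank, "downstream_flank"),
    repeat_unit = cfg$repeat_unit %||% "CAG",
    cassettes = cassettes,
    i_min = cfg$i_min %||% 1L,
    i_max = cfg$i_max %||% 113L)
}

#' Rebuild a template so its cassettes match a detected tract structure
#'
#' When structure detection finds an atypical amplicon (interruption cassette
#' absent, or a codon-run cassette with a non-canonical length), the ladder
#' must be regenerated from a template matching that structure before reads
#' are re-sized. The input template is not modified.
#'
#' @param template A [locus_template()].
#' @param structure A `tract_structure` from [detect_structure()].
#' @return A new [locus_template()] whose cassettes match `structure`.
#' @export
apply_structure <- function(template, structure) {
  stopifnot(inherits(template, "locus_template"))
  if (!inherits(structure, "tract_structure")) {
    stop_strgain("`structure` must be a tract_structure", "strgain_config_error")
  }
  if (!identical(structure$locus_id, template$locus_id)) {
    stop_strgain(
      sprintf("structure is for locus '%s', template is '%s'",
              structure$locus_id, template$locus_id),
      "strgain_structure_error")
  }
  counts <- structure$cassette_codon_counts
  unknown <- setdiff(names(counts),
                     vapply(template$cassettes, `[[`, character(1), "name"))
  if (length(unknown)) {
    stop_strgain(sprintf("structure names unknown cassette(s): %s",
                         paste(unknown, collapse = ", ")),
                 "strgain_structure_error")
  }
  new_cassettes <- list()
  for (cs in template$cassettes) {
    if (cs$interruption && !isTRUE(structure$interruption_present)) next
    if (!is.null(cs$unit) && cs$name %in% names(counts)) {
      cs <- locus_cassette(cs$name, unit = cs$unit,
                           n = counts[[cs$name]],
                           interruption = cs$interruption)
    }
    new_cassettes <- c(new_cassettes, list(cs))
  }
  locus_template(template$locus_id, template$upstream_flank,
                 template$downstream_flank, template$repeat_unit,
                 new_cassettes, template$i_min, template$i_max)
}
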