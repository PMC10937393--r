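#' Detect the post-tract structure of an amplicon from assigned reads
#'
#' Reads are scanned (in their forward orientation) past the upstream flank
#' and the uninterrupted repeat run for the cassettes declared in the
#' template: fixed cassettes (including the interruption cassette) are
#' located by approximate matching with at most `max_cassette_mismatch`
#' mismatches, codon-run cassettes by exact run counting. The modal per-read
#' structure signature defines the sample's structure; it is flagged
#' `atypical` when it differs from the template. When a second structure
#' reaches `min_secondary_frac` of reads the call is flagged `conflicting`
#' (two structural alleles) and both are reported with their frequencies
#' rather than silently choosing.
#'
#' @param reads Character vector of read sequences, a FASTQ path, or a
#'   `sizing_result` (whose assignments supply orientations and filter to
#'   assigned reads).
#' @param template The [locus_template()] the reads were sized against.
#' @param params A [sizing_params()] (supplies `min_reads`).
#' @param max_cassette_mismatch Mismatch allowance per fixed cassette.
#' @param max_flank_mismatch Mismatch allowance in the upstream flank
#'   anchor.
#' @param min_secondary_frac Frequency at which a second structure is
#'   reported as a conflicting structural allele.
#' @return A `tract_structure` object: `locus_id`, `interruption_present`,
#'   `cassette_codon_counts` (named integer), `atypical`, `frequency`,
#'   `conflicting`, `alternatives` (tibble of signature frequencies).
#' @export
detect_structure <- function(reads, template, params = sizing_params(),
                             max_cassette_mismatch = 1L,
                             max_flank_mismatch = 2L,
                             min_secondary_frac = 0.3) {
  stopifnot(inherits(template, "locus_template"))
  seqs <- structure_read_seqs(reads)
  if (length(seqs) < params$min_reads) {
    stop_strgain(
      sprintf("insufficient reads for structure detection: %d < %d",
              length(seqs), params$min_reads),
      "strgain_structure_error")
  }
  sigs <- vapply(seqs, read_structure_signature, character(1),
                 template = template,
                 max_cassette_mismatch = max_cassette_mismatch,
                 max_flank_mismatch = max_flank_mismatch,
                 USE.NAMES = FALSE)
  sigs <- sigs[!is.na(sigs)]
  if (length(sigs) < params$min_reads) {
    stop_strgain(
      sprintf("only %d reads span the full cassette region (%d required)",
              length(sigs), params$min_reads),
      "strgain_structure_error")
  }
  tab <- sort(table(sigs), decreasing = TRUE)
  freq <- as.numeric(tab) / length(sigs)
  alternatives <- tibble::tibble(signature = names(tab), frequency = freq)
  modal <- parse_structure_signature(names(tab)[1], template)
  canonical <- canonical_signature(template)
  structure(
    list(locus_id = template$locus_id,
         interruption_present = modal$interruption_present,
         cassette_codon_counts = modal$counts,
         atypical = names(tab)[1] != canonical,
         frequency = freq[1],
         conflicting = length(freq) > 1L && freq[2] >= min_secondary_frac,
         alternatives = alternatives),
    class = "tract_structure")
}

structure_read_seqs <- function(reads) {
  if (inherits(reads, "sizing_result")) {
    asn <- reads$assignments
    if (!"sequence" %in% names(asn)) {
      stop_strgain(
        "sizing_result does not carry read sequences; pass the reads directly",
        "strgain_structure_error")
    }
    ok <- asn$reason == "ok"
    seqs <- asn$sequence[ok]
    rc <- asn$orientation[ok] == "reverse"
    seqs[rc] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rc])))
    return(seqs)
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    return(read_fastq_reads(reads)$seq)
  }
  stopifnot(is.character(reads))
  reads
}

# Per-read structure signature "name=count;..." in template cassette order,
# or NA when the read does not anchor or span the cassette region.
read_structure_signature <- function(seq, template, max_cassette_mismatch,
                                     max_flank_mismatch) {
  u <- template$upstream_flank
  lu <- nchar(u)
  if (nchar(seq) < lu + 3L) return(NA_character_)
  if (hamming(substr(seq, 1L, lu), u) > max_flank_mismatch) {
    return(NA_character_)
  }
  pos <- lu + 1L
  pos <- pos + 3L * count_unit_run(seq, pos, template$repeat_unit)
  parts <- character(length(template$cassettes))
  for (k in seq_along(template$cassettes)) {
    cs <- template$cassettes[[k]]
    if (is.null(cs$unit)) {
      len <- nchar(cs$seq)
      if (pos + len - 1L > nchar(seq)) return(NA_character_)
      if (hamming(substr(seq, pos, pos + len - 1L), cs$seq) <=
          max_cassette_mismatch) {
        parts[k] <- sprintf("%s=%d", cs$name, cs$n_codons)
        pos <- pos + len
      } else {
        parts[k] <- sprintf("%s=0", cs$name)
      }
    } else {
      run <- count_unit_run(seq, pos, cs$unit)
      # the codon after the run must be readable, else the count is censored
      if (pos + 3L * run + 2L > nchar(seq)) return(NA_character_)
      parts[k] <- sprintf("%s=%d", cs$name, run)
      pos <- pos + 3L * run
    }
  }
  if (pos - 1L > nchar(seq)) return(NA_character_)
  paste(parts, collapse = ";")
}

canonical_signature <- function(template) {
  paste(vapply(template$cassettes, function(cs) {
    sprintf("%s=%d", cs$name, cs$n_codons)
  }, character(1)), collapse = ";")
}

parse_structure_signature <- function(sig, template) {
  kv <- strsplit(strsplit(sig, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  counts <- stats::setNames(
    vapply(kv, function(x) as.integer(x[2]), integer(1)),
    vapply(kv, `[[`, character(1), 1))
  inter <- vapply(template$cassettes, `[[`, logical(1), "interruption")
  inter_names <- vapply(template$cassettes, `[[`, character(1),
                        "name")[inter]
  list(counts = counts,
       interruption_present = length(inter_names) == 0L ||
         all(counts[inter_names] > 0L))
}

hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

count_unit_run <- function(seq, pos, unit) {
  run <- 0L
  while (substr(seq, pos, pos + 2L) == unit) {
    run <- run + 1L
    pos <- pos + 3L
  }
  run
}

#' @export
print.tract_structure <- function(x, ...) {
  cat(sprintf("<tract_structure> %s: %s (%.1f%% of reads)%s%s\n",
              x$locus_id,
              if (x$atypical) "ATYPICAL" else "canonical",
              100 * x$frequency,
              if (!x$interruption_present) ", interruption absent" else "",
              if (x$conflicting) ", CONFLICTING structural alleles" else ""))
  for (nm in names(x$cassette_codon_counts)) {
    cat(sprintf("  %s: %d codons\n", nm, x$cassette_codon_counts[[nm]]))
  }
  invisible(x)
}

#' Re-size reads on a structure-matched ladder when the tract is atypical
#'
#' If the detected structure is canonical this is a no-op returning the
#' input sizing result; otherwise the template is rebuilt with
#' [apply_structure()], the ladder regenerated, and the reads re-sized.
#'
#' @param result The `sizing_result` obtained on the canonical ladder.
#' @param reads The same reads (character vector or FASTQ path).
#' @param template The canonical [locus_template()].
#' @param structure A `tract_structure` from [detect_structure()].
#' @param params A [sizing_params()].
#' @return A `sizing_result` (re-sized when atypical).
#' @export
resize_if_atypical <- function(result, reads, template, structure,
                               params = sizing_params()) {
  stopifnot(inherits(result, "sizing_result"),
            inherits(structure, "tract_structure"))
  if (!isTRUE(structure$atypical)) {
    return(result)
  }
  tpl2 <- apply_structure(template, structure)
  ladder2 <- build_ladder(tpl2)
  size_sample(reads, ladder2, params, sample_id = result$sample_id)
}
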