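#' Read and validate a sample manifest
#'
#' The manifest maps FASTQ files to donor, cell type and locus, and marks
#' which sample of each donor+locus is the non-expanding
#' `allele_reference` used for progenitor-allele calling.
#'
#' @param path TSV with columns `sample_id`, `donor_id`, `cell_type`,
#'   `locus_id`, `fastq_path`, `role`.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  validate_manifest(m)
}

validate_manifest <- function(m) {
  required <- c("sample_id", "donor_id", "cell_type", "locus_id",
                "fastq_path", "role")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop_strgain(sprintf("manifest lacks column(s): %s",
                         paste(missing, collapse = ", ")),
                 "strgain_config_error")
  }
  if (anyDuplicated(m$sample_id)) {
    stop_strgain("duplicate sample_id in manifest", "strgain_config_error")
  }
  if (!all(m$role %in% c("sample", "allele_reference"))) {
    stop_strgain("manifest `role` must be 'sample' or 'allele_reference'",
                 "strgain_config_error")
  }
  tibble::as_tibble(m)
}

#' Size one sample and compute its instability statistics
#'
#' Runs the per-sample pipeline stage: size the reads on the donor's
#' ladder, optionally check the tract structure and re-size on a
#' structure-matched ladder, then compute RoSE and MSLG against the donor's
#' progenitor allele call.
#'
#' @param reads Read sequences or FASTQ path.
#' @param ladder The donor's `repeat_ladder`.
#' @param allele_call The donor's `allele_call`.
#' @param params A [sizing_params()].
#' @param sample_id Sample label.
#' @param check_structure Detect structure and re-size when atypical.
#' @return A list with `stats` (one-row tibble), `sizing` (the
#'   `sizing_result`) and `structure` (or `NULL`).
#' @export
run_sample <- function(reads, ladder, allele_call, params = sizing_params(),
                       sample_id = NA_character_, check_structure = FALSE) {
  sizing <- size_sample(reads, ladder, params, sample_id = sample_id)
  struct <- NULL
  if (check_structure) {
    tpl <- ladder_template(ladder)
    struct <- detect_structure(reads, tpl, params)
    sizing <- resize_if_atypical(sizing, reads, tpl, struct, params)
  }
  stats <- instability_stats(sizing$histogram, allele_call)
  stats$n_unassigned <- sizing$qc$n_unassigned
  list(stats = stats, sizing = sizing, structure = struct)
}

#' Run the full cohort pipeline
#'
#' For every donor+locus: pool and size the `allele_reference` samples,
#' detect the tract structure (re-laddering when atypical), call the
#' progenitor lengths (N, M), then size every sample of that donor and
#' compute its instability statistics. Finally the chosen statistic is
#' compared across cell types. Per-sample errors are collected, not fatal:
#' every manifest sample appears either in the stats table or in
#' `failures` with a reason.
#'
#' @param manifest Manifest tibble (see [read_manifest()]).
#' @param templates Named list of [locus_template()]s keyed by `locus_id`
#'   (a single template is accepted and matched by its id).
#' @param params A [sizing_params()].
#' @param reads Optional named list of in-memory read vectors keyed by
#'   `sample_id` (used instead of `fastq_path`).
#' @param compare_stat Statistic compared across cell types (`"mslg"`,
#'   `"rose_mutant"` or `"rose_normal"`).
#' @param paired_pair,pair_by Optional ratio-paired comparison, see
#'   [compare_groups()].
#' @param check_structure Run structure detection on reference samples.
#' @param seed Recorded in the report for provenance (the pipeline itself
#'   is deterministic).
#' @return A `run_report` list: `stats`, `allele_calls`, `comparison`,
#'   `failures`, `qc`, `provenance`.
#' @export
run_cohort <- function(manifest, templates, params = sizing_params(),
                       reads = NULL, compare_stat = "mslg",
                       paired_pair = NULL, pair_by = "donor_id",
                       check_structure = FALSE, seed = NA_integer_) {
  manifest <- validate_manifest(manifest)
  manifest <- dplyr::arrange(manifest, .data$donor_id, .data$sample_id)
  if (inherits(templates, "locus_template")) {
    templates <- stats::setNames(list(templates), templates$locus_id)
  }
  get_reads <- function(row) {
    if (!is.null(reads) && row$sample_id %in% names(reads)) {
      return(reads[[row$sample_id]])
    }
    if (is.na(row$fastq_path) || !file.exists(row$fastq_path)) {
      stop_strgain(sprintf("FASTQ not found for sample '%s'", row$sample_id),
                   "strgain_io_error")
    }
    row$fastq_path
  }
  stats_rows <- list()
  failures <- list()
  allele_calls <- list()
  fail <- function(ids, reason) {
    failures[[length(failures) + 1L]] <<-
      tibble::tibble(sample_id = ids, reason = reason)
  }
  for (key in unique(paste(manifest$donor_id, manifest$locus_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- manifest[manifest$donor_id == parts[1] &
                    manifest$locus_id == parts[2], ]
    tpl <- templates[[parts[2]]]
    if (is.null(tpl)) {
      fail(sub$sample_id, sprintf("no template for locus '%s'", parts[2]))
      next
    }
    refs <- sub[sub$role == "allele_reference", ]
    if (nrow(refs) == 0L) {
      fail(sub$sample_id, "missing allele_reference for donor+locus")
      next
    }
    donor_res <- tryCatch({
      ladder <- build_ladder(tpl)
      ref_sizings <- lapply(seq_len(nrow(refs)), function(j) {
        size_sample(get_reads(refs[j, ]), ladder, params,
                    sample_id = refs$sample_id[j])
      })
      struct <- NULL
      if (check_structure) {
        struct <- detect_structure(get_reads(refs[1, ]), tpl, params)
        if (isTRUE(struct$atypical)) {
          tpl <- apply_structure(tpl, struct)
          ladder <- build_ladder(tpl)
          ref_sizings <- lapply(seq_len(nrow(refs)), function(j) {
            size_sample(get_reads(refs[j, ]), ladder, params,
                        sample_id = refs$sample_id[j])
          })
        }
      }
      pooled <- pool_histograms(lapply(ref_sizings, `[[`, "histogram"))
      call <- call_progenitor_lengths(pooled, params, structure = struct)
      list(ladder = ladder, call = call)
    }, strgain_error = function(e) e)
    if (inherits(donor_res, "error")) {
      fail(sub$sample_id,
           paste("allele calling failed:", conditionMessage(donor_res)))
      next
    }
    allele_calls[[key]] <- tibble::tibble(
      donor_id = parts[1], locus_id = parts[2],
      N = donor_res$call$N, M = donor_res$call$M,
      source_sample_id = donor_res$call$source_sample_id)
    for (j in seq_len(nrow(sub))) {
      row <- sub[j, ]
      res <- tryCatch({
        out <- run_sample(get_reads(row), donor_res$ladder, donor_res$call,
                          params, sample_id = row$sample_id,
                          check_structure = FALSE)
        dplyr::mutate(out$stats, donor_id = row$donor_id,
                      cell_type = row$cell_type, role = row$role)
      }, strgain_error = function(e) e)
      if (inherits(res, "error")) {
        fail(row$sample_id, conditionMessage(res))
      } else {
        stats_rows[[row$sample_id]] <- res
      }
    }
  }
  stats <- dplyr::bind_rows(stats_rows)
  comparison <- NULL
  if (nrow(stats) > 0L && compare_stat %in% names(stats)) {
    cmp_df <- tibble::tibble(group = stats$cell_type,
                             value = stats[[compare_stat]],
                             donor_id = stats$donor_id)
    ok_groups <- names(which(table(cmp_df$group) >= 2L))
    cmp_df <- cmp_df[cmp_df$group %in% ok_groups, ]
    if (length(ok_groups) >= 2L) {
      comparison <- tryCatch(
        compare_groups(cmp_df, paired_pair = paired_pair, pair_by = pair_by),
        strgain_error = function(e) NULL)
    }
  }
  structure(
    list(stats = stats,
         allele_calls = dplyr::bind_rows(allele_calls),
         comparison = comparison,
         failures = dplyr::bind_rows(failures),
         qc = if (nrow(stats)) stats[c("sample_id", "n_assigned",
                                       "n_unassigned",
                                       "n_intermediate_reads")],
         provenance = list(
           seed = seed, compare_stat = compare_stat,
           params = unclass(params),
           n_samples = nrow(manifest),
           package_version = as.character(utils::packageVersion("strgain")))),
    class = "run_report")
}

pool_histograms <- function(hists) {
  out <- hists[[1]]
  if (length(hists) > 1L) {
    for (h in hists[-1]) {
      stopifnot(identical(h$i, out$i))
      out$count <- out$count + h$count
    }
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d sample(s) scored, %d failure(s)\n",
              nrow(x$stats), nrow(x$failures)))
  if (!is.null(x$comparison)) {
    cat(sprintf("  %s across cell types: F = %.4g, p = %.4g\n",
                x$provenance$compare_stat, x$comparison$anova$F,
                x$comparison$anova$p))
  }
  if (nrow(x$failures)) print(x$failures)
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits per-sample stats TSV, the pairwise comparison TSV, and a
#' machine-readable JSON report embedding the resolved parameters for
#' provenance.
#'
#' @param report A `run_report`.
#' @param out_dir Output directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$stats, file.path(out_dir, "sample_stats.tsv"))
  if (nrow(report$failures)) {
    readr::write_tsv(report$failures, file.path(out_dir, "failures.tsv"))
  }
  if (!is.null(report$comparison)) {
    write_comparison_report(report$comparison,
                            tsv = file.path(out_dir, "comparison.tsv"))
  }
  payload <- list(
    stats = report$stats,
    allele_calls = report$allele_calls,
    failures = report$failures,
    comparison = if (!is.null(report$comparison)) {
      list(anova = report$comparison$anova,
           pairwise = tidy(report$comparison))
    },
    provenance = report$provenance)
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
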