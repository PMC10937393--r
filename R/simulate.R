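#' Expansion model for simulating amplicon reads with known truth
#'
#' Describes one sample's molecule population: a two-allele mixture (normal
#' length `N`, mutant progenitor length `M`), a somatic-expansion gain
#' distribution on the mutant allele (discretized gamma over gains `g >= 1`,
#' capped so `M + g` never exceeds the ladder ceiling), PCR stutter applied
#' per molecule around the true length with contraction bias
#' (`P(-1) = s`, `P(-2) = s^2/2`, `P(+1) = s/4`), and i.i.d. per-base
#' substitution error at rate `epsilon`. Reads are rendered from the locus
#' template and truncated to `read_length` nt from the upstream-primer end,
#' emulating single-end 400-nt amplicon sequencing; base qualities are
#' constant because the sizer ignores them.
#'
#' @param template A [locus_template()].
#' @param N,M Progenitor repeat counts of the normal and mutant allele
#'   (`N < M`).
#' @param allele_balance Fraction of molecules from the mutant allele.
#' @param p_unexpanded Fraction of mutant molecules remaining at `M`.
#' @param gain_mean,gain_shape Mean and shape of the gamma gain
#'   distribution (gains rounded to integers, floored at 1).
#' @param stutter_s Stutter intensity `s` (0 disables stutter).
#' @param epsilon Per-base substitution error rate.
#' @param read_length Read length in nt.
#' @return An `expansion_model` list.
#' @export
expansion_model <- function(template, N, M, allele_balance = 0.5,
                            p_unexpanded = 0.5, gain_mean = 22,
                            gain_shape = 4, stutter_s = 0.05,
                            epsilon = 0.005, read_length = 400L) {
  stopifnot(inherits(template, "locus_template"))
  N <- as.integer(N); M <- as.integer(M)
  if (N >= M) {
    stop_strgain("expansion model requires N < M", "strgain_config_error")
  }
  if (M > template$i_max) {
    stop_strgain("M exceeds the ladder ceiling", "strgain_config_error")
  }
  probs <- c(allele_balance, p_unexpanded, stutter_s, epsilon)
  if (any(probs < 0) || any(probs[1:2] > 1) || epsilon > 1 || stutter_s > 0.5) {
    stop_strgain("model probabilities out of range", "strgain_config_error")
  }
  m <- structure(
    list(template = template, N = N, M = M,
         allele_balance = allele_balance, p_unexpanded = p_unexpanded,
         gain_mean = gain_mean, gain_shape = gain_shape,
         stutter_s = stutter_s, epsilon = epsilon,
         read_length = as.integer(read_length)),
    class = "expansion_model")
  max_sizeable <- (m$read_length - nchar(template$upstream_flank) - 12L) %/% 3L
  if (template$i_max > max_sizeable) {
    rlang::warn(sprintf(
      paste("tract lengths above %d repeat units are not sizeable from",
            "%d-nt reads; simulated molecules beyond that length will be",
            "unassignable (detection ceiling)"),
      max_sizeable, m$read_length))
  }
  m
}

#' Cell-type expansion presets
#'
#' Named parameter sets emulating the instability behaviour of the cell
#' types studied at CAG disease loci: `"msn"` (striatal projection neurons;
#' most molecules expanded, roughly half of them by more than 20 repeat
#' units, mean somatic length gain around 22 RU), `"chat"` (cholinergic
#' interneurons; comparably unstable), `"pc"` (Purkinje-like mild
#' instability, mean gain around 5 RU), `"glia"` (stable reference cell
#' types, mean gain well under 1 RU).
#'
#' @param name One of `"msn"`, `"chat"`, `"pc"`, `"glia"`.
#' @return A named list of [expansion_model()] arguments.
#' @export
cell_type_preset <- function(name) {
  presets <- list(
    msn  = list(p_unexpanded = 0.10, gain_mean = 24.5, gain_shape = 4),
    chat = list(p_unexpanded = 0.15, gain_mean = 22.0, gain_shape = 4),
    pc   = list(p_unexpanded = 0.40, gain_mean = 8.3,  gain_shape = 3),
    glia = list(p_unexpanded = 0.80, gain_mean = 2.0,  gain_shape = 2))
  if (!name %in% names(presets)) {
    stop_strgain(sprintf("unknown preset '%s' (use %s)", name,
                         paste(names(presets), collapse = ", ")),
                 "strgain_config_error")
  }
  presets[[name]]
}

#' Simulate one sample's amplicon reads
#'
#' Draws each molecule's allele, true tract length (`N`, or `M` plus a gain
#' for expanded mutant molecules), applies per-molecule stutter, renders the
#' amplicon sequence, applies substitution errors and truncates to the read
#' length. Bitwise reproducible for a given seed.
#'
#' @param model An [expansion_model()].
#' @param n_reads Number of reads to simulate.
#' @param seed Integer seed.
#' @param fastq Optional output FASTQ path (gzip if it ends `.gz`); when
#'   `NULL` reads are only returned in memory.
#' @param sample_id Sample label used in read ids.
#' @return A list with `reads` (tibble `read_id`, `sequence`), `truth`
#'   (tibble `read_id`, `allele`, `true_len`, `obs_len`) and `fastq`
#'   (path or `NULL`).
#' @export
simulate_sample <- function(model, n_reads, seed, fastq = NULL,
                            sample_id = "sample") {
  stopifnot(inherits(model, "expansion_model"), n_reads >= 1)
  withr::local_seed(seed)
  tpl <- model$template
  mutant <- runif(n_reads) < model$allele_balance
  true_len <- integer(n_reads)
  true_len[!mutant] <- model$N
  n_mut <- sum(mutant)
  expanded <- runif(n_mut) >= model$p_unexpanded
  gains <- integer(n_mut)
  if (any(expanded)) {
    g <- pmax(1L, as.integer(round(rgamma(sum(expanded),
                                          shape = model$gain_shape,
                                          scale = model$gain_mean /
                                            model$gain_shape))))
    gains[expanded] <- pmin(g, tpl$i_max - model$M)
  }
  true_len[mutant] <- model$M + gains
  obs_len <- pmin(pmax(true_len + draw_stutter(n_reads, model$stutter_s),
                       tpl$i_min), tpl$i_max)
  post <- post_tract_seq(tpl)
  seqs <- paste0(tpl$upstream_flank, strrep(tpl$repeat_unit, obs_len), post)
  seqs <- substr(seqs, 1L, model$read_length)
  if (model$epsilon > 0) {
    seqs <- add_substitutions(seqs, model$epsilon)
  }
  ids <- sprintf("%s:%06d", sample_id, seq_len(n_reads))
  reads <- tibble::tibble(read_id = ids, sequence = seqs)
  truth <- tibble::tibble(
    read_id = ids,
    allele = ifelse(mutant, "mutant", "normal"),
    true_len = true_len,
    obs_len = obs_len)
  if (!is.null(fastq)) {
    write_fastq(reads, fastq)
  }
  list(reads = reads, truth = truth, fastq = fastq)
}

# per-molecule PCR stutter offsets over {-2,-1,0,+1} with contraction bias
draw_stutter <- function(n, s) {
  if (s <= 0) return(integer(n))
  probs <- c(`-2` = s^2 / 2, `-1` = s, `1` = s / 4)
  probs <- c(probs, `0` = 1 - sum(probs))
  offs <- as.integer(names(probs))
  offs[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

# i.i.d. substitutions at rate eps; errored bases become a different base
add_substitutions <- function(seqs, eps) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < eps)
    if (!length(hit)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  qual <- strrep("I", nchar(reads$sequence))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual),
             con)
  invisible(path)
}

#' Truth-table mean somatic length gain
#'
#' The simulation-truth counterpart of [mslg()]: the mean post-stutter
#' tract length over molecules at or above the progenitor length `M`,
#' minus `M`. Used to validate pipeline estimates against known truth.
#'
#' @param truth A truth tibble from [simulate_sample()].
#' @param M Progenitor repeat count.
#' @return Mean gain in repeat units.
#' @export
truth_mslg <- function(truth, M) {
  sel <- truth$obs_len >= M
  if (!any(sel)) {
    stop_strgain("no molecules at or above M in the truth table",
                 "strgain_undefined_statistic")
  }
  mean(truth$obs_len[sel]) - M
}

#' Cohort configuration for the simulator
#'
#' @param donors Tibble with columns `donor_id`, `N`, `M` (one row per
#'   donor), or an integer count (donors are then given progenitor lengths
#'   cycling through the common disease-causing range 42-45 with normal
#'   alleles 17-19).
#' @param cell_types Named character vector mapping cell-type label to
#'   preset name (see [cell_type_preset()]); names ending up with role
#'   `allele_reference` are given by `reference_cell_types`.
#' @param reference_cell_types Cell-type labels to mark as
#'   `allele_reference` in the manifest (default: the glia-preset types).
#' @param template A [locus_template()].
#' @param n_reads Reads per sample.
#' @param stutter_s,epsilon,read_length,allele_balance Shared model
#'   parameters.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(donors = 5L,
                          cell_types = c(dMSN = "msn", iMSN = "msn",
                                         CHAT_IN = "chat", glia = "glia"),
                          reference_cell_types = NULL,
                          template = htt_exon1_template(),
                          n_reads = 5000L, stutter_s = 0.05,
                          epsilon = 0.005, read_length = 400L,
                          allele_balance = 0.5) {
  if (is.numeric(donors)) {
    k <- as.integer(donors)
    donors <- tibble::tibble(
      donor_id = sprintf("donor%02d", seq_len(k)),
      N = rep(17:19, length.out = k),
      M = rep(42:45, length.out = k))
  }
  stopifnot(all(c("donor_id", "N", "M") %in% names(donors)))
  if (is.null(names(cell_types))) names(cell_types) <- cell_types
  if (is.null(reference_cell_types)) {
    reference_cell_types <- names(cell_types)[cell_types == "glia"]
  }
  if (!length(reference_cell_types)) {
    stop_strgain("cohort needs at least one allele_reference cell type",
                 "strgain_config_error")
  }
  structure(
    list(donors = tibble::as_tibble(donors), cell_types = cell_types,
         reference_cell_types = reference_cell_types, template = template,
         n_reads = as.integer(n_reads), stutter_s = stutter_s,
         epsilon = epsilon, read_length = as.integer(read_length),
         allele_balance = allele_balance),
    class = "cohort_config")
}

#' Simulate a donor-by-cell-type cohort
#'
#' Emits one FASTQ (and truth TSV) per donor x cell type, plus a sample
#' manifest with the `allele_reference` role marked, consumable by
#' [run_cohort()]. One global seed drives per-sample streams derived by
#' hashing the sample id, so cohorts are reproducible while samples stay
#' independent.
#'
#' @param config A [cohort_config()].
#' @param seed Integer global seed.
#' @param out_dir Output directory (created); when `NULL`, reads are kept
#'   in memory only (`fastq_path` is `NA` in the manifest and the reads are
#'   returned).
#' @return A list with `manifest` (tibble: `sample_id`, `donor_id`,
#'   `cell_type`, `locus_id`, `fastq_path`, `role`), `truth_summary`
#'   (per-sample truth MSLG), and (when `out_dir` is `NULL`) `samples`, a
#'   named list of [simulate_sample()] results.
#' @export
make_cohort <- function(config, seed, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  tpl <- config$template
  grid <- tidyr::expand_grid(
    donor_id = config$donors$donor_id,
    cell_type = names(config$cell_types))
  grid$sample_id <- paste(grid$donor_id, grid$cell_type, tpl$locus_id,
                          sep = "_")
  if (anyDuplicated(grid$sample_id)) {
    stop_strgain("duplicate sample ids in cohort design",
                 "strgain_config_error")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  samples <- list()
  rows <- vector("list", nrow(grid))
  truth_rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    donor <- config$donors[config$donors$donor_id == grid$donor_id[r], ]
    preset <- cell_type_preset(config$cell_types[[grid$cell_type[r]]])
    model <- expansion_model(
      tpl, N = donor$N, M = donor$M,
      allele_balance = config$allele_balance,
      p_unexpanded = preset$p_unexpanded,
      gain_mean = preset$gain_mean, gain_shape = preset$gain_shape,
      stutter_s = config$stutter_s, epsilon = config$epsilon,
      read_length = config$read_length)
    sid <- grid$sample_id[r]
    fq <- if (!is.null(out_dir)) file.path(out_dir, paste0(sid, ".fastq.gz"))
    sim <- simulate_sample(model, config$n_reads,
                           seed = sample_substream_seed(seed, sid),
                           fastq = fq, sample_id = sid)
    if (!is.null(out_dir)) {
      readr::write_tsv(sim$truth, file.path(out_dir, paste0(sid, "_truth.tsv")))
    } else {
      samples[[sid]] <- sim
    }
    role <- if (grid$cell_type[r] %in% config$reference_cell_types) {
      "allele_reference"
    } else {
      "sample"
    }
    rows[[r]] <- tibble::tibble(
      sample_id = sid, donor_id = grid$donor_id[r],
      cell_type = grid$cell_type[r], locus_id = tpl$locus_id,
      fastq_path = fq %||% NA_character_, role = role)
    truth_rows[[r]] <- tibble::tibble(
      sample_id = sid, donor_id = grid$donor_id[r],
      cell_type = grid$cell_type[r],
      truth_mslg = truth_mslg(sim$truth, donor$M))
  }
  manifest <- dplyr::bind_rows(rows)
  out <- list(manifest = manifest,
              truth_summary = dplyr::bind_rows(truth_rows))
  if (!is.null(out_dir)) {
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  } else {
    out$samples <- samples
  }
  out
}

# stable 31-bit substream seed from the global seed and the sample id
sample_substream_seed <- function(seed, sample_id) {
  h <- 0
  for (c in utf8ToInt(sample_id)) h <- (h * 31 + c) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}
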