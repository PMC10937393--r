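#' Classical one-way ANOVA across groups
#'
#' Fixed-effects one-way ANOVA on per-donor statistic values (MSLG or RoSE),
#' unequal group sizes allowed. A Welch correction is available behind the
#' `welch` flag but is off by default (the classical test is the one named
#' by the downstream multiple-comparison procedure).
#'
#' @param groups A named list of numeric vectors, or a data frame with
#'   columns `group` and `value`.
#' @param welch Use Welch's heteroscedastic ANOVA instead of the classical
#'   pooled-variance test.
#' @return A list with `F`, `p`, `df_between`, `df_within`, `ms_within`,
#'   `p_underflow` (TRUE when within-group variance is zero with distinct
#'   means and `p` is reported at the double floor).
#' @export
one_way_anova <- function(groups, welch = FALSE) {
  df <- as_group_df(groups)
  sizes <- table(df$group)
  if (length(sizes) < 2L) {
    stop_strgain("ANOVA needs at least 2 groups", "strgain_stats_error")
  }
  if (any(sizes < 2L)) {
    stop_strgain(
      sprintf("every group needs >= 2 values (offending: %s)",
              paste(names(sizes)[sizes < 2L], collapse = ", ")),
      "strgain_stats_error")
  }
  k <- length(sizes)
  n <- nrow(df)
  means <- tapply(df$value, df$group, mean)
  grand <- mean(df$value)
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum((df$value - means[as.character(df$group)])^2)
  df_b <- k - 1L
  df_w <- n - k
  underflow <- FALSE
  if (welch) {
    ht <- stats::oneway.test(value ~ group, data = df, var.equal = FALSE)
    Fstat <- unname(ht$statistic)
    p <- ht$p.value
    df_b <- unname(ht$parameter[1])
    df_w <- unname(ht$parameter[2])
  } else if (ss_within == 0 && ss_between > 0) {
    Fstat <- Inf
    p <- .Machine$double.xmin
    underflow <- TRUE
  } else if (ss_between == 0) {
    Fstat <- 0
    p <- 1
  } else {
    Fstat <- (ss_between / df_b) / (ss_within / df_w)
    p <- stats::pf(Fstat, df_b, df_w, lower.tail = FALSE)
  }
  list(F = Fstat, p = p, df_between = df_b, df_within = df_w,
       ms_within = ss_within / df_w, p_underflow = underflow)
}

as_group_df <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    df <- groups[c("group", "value")]
  } else {
    if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
      names(groups) <- paste0("group", seq_along(groups))
    }
    df <- tibble::tibble(
      group = rep(names(groups), lengths(groups)),
      value = unlist(groups, use.names = FALSE))
  }
  if (anyNA(df$value)) {
    stop_strgain("group values must not contain NA", "strgain_stats_error")
  }
  df$group <- factor(df$group)
  df
}

#' Holm-Sidak step-down adjustment of raw p values
#'
#' Sorts the raw p values ascending and adjusts the k-th smallest to
#' `1 - (1 - p_(k))^(m - k + 1)`, enforcing monotone non-decreasing
#' adjusted values and capping at 1; results are returned in the input
#' order. Not provided by [stats::p.adjust()], hence implemented from the
#' closed form.
#'
#' @param raw_p Numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
holm_sidak <- function(raw_p) {
  if (!is.numeric(raw_p) || anyNA(raw_p) ||
      any(raw_p < 0) || any(raw_p > 1)) {
    stop_strgain("p values must be numeric in [0, 1]", "strgain_stats_error")
  }
  m <- length(raw_p)
  if (m == 0L) return(numeric(0))
  ord <- order(raw_p)
  sorted <- raw_p[ord]
  adj <- 1 - (1 - sorted)^(m - seq_len(m) + 1)
  adj <- pmax(adj, sorted)  # guard the one-ulp case at exponent 1
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Ratio paired t-test
#'
#' Two-sided paired t-test on log-transformed values, i.e. a test of mean
#' log ratio zero — the standard definition of a ratio paired t-test. The
#' log base does not affect the statistic or the p value.
#'
#' @param x,y Positive paired numeric vectors of equal length >= 2.
#' @return A list with `t`, `p`, `df`, `mean_log_ratio`.
#' @export
ratio_paired_ttest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_strgain("`x` and `y` must be paired vectors of equal length >= 2",
                 "strgain_stats_error")
  }
  if (any(x <= 0) || any(y <= 0)) {
    stop_strgain("ratio paired t-test requires strictly positive values",
                 "strgain_stats_error")
  }
  d <- log(x) - log(y)
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1L, mean_log_ratio = 0))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L,
                mean_log_ratio = mean(d)))
  }
  ht <- stats::t.test(d)
  list(t = unname(ht$statistic), p = ht$p.value, df = n - 1L,
       mean_log_ratio = mean(d))
}

#' Compare a per-donor statistic across cell-type groups
#'
#' The cohort-level comparison applied to MSLG or RoSE values: classical
#' one-way ANOVA across groups followed by all pairwise comparisons using
#' the pooled within-group variance (t statistics on the ANOVA mean square
#' within, the conventional post-hoc construction) with Holm-Sidak
#' adjustment. Optionally a designated pair is additionally compared by a
#' ratio paired t-test (values matched by `pair_by`, typically donor).
#'
#' @param data A data frame with columns `group` and `value` (long format;
#'   extra columns such as `donor_id` are kept for pairing).
#' @param paired_pair Optional character vector of two group labels to
#'   compare by ratio paired t-test.
#' @param pair_by Column name used to match pairs (default `"donor_id"`).
#' @param welch Passed to [one_way_anova()].
#' @return A `group_comparison` object; see [tidy.group_comparison()] and
#'   [glance.group_comparison()].
#' @export
compare_groups <- function(data, paired_pair = NULL, pair_by = "donor_id",
                           welch = FALSE) {
  df <- as_group_df(data)
  anova <- one_way_anova(df, welch = welch)
  lv <- levels(df$group)
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  raw <- vapply(pairs, function(pr) {
    pooled_t_p(df, pr[1], pr[2], anova$ms_within, anova$df_within)
  }, numeric(1))
  pairwise <- tibble::tibble(
    group1 = vapply(pairs, `[[`, character(1), 1L),
    group2 = vapply(pairs, `[[`, character(1), 2L),
    raw_p = raw,
    adjusted_p = holm_sidak(raw))
  t_ratio <- NULL
  if (!is.null(paired_pair)) {
    stopifnot(length(paired_pair) == 2L)
    if (!pair_by %in% names(data)) {
      stop_strgain(sprintf("pairing column '%s' not found", pair_by),
                   "strgain_stats_error")
    }
    wide <- tidyr::pivot_wider(
      dplyr::filter(tibble::as_tibble(data), .data$group %in% paired_pair),
      id_cols = dplyr::all_of(pair_by),
      names_from = "group", values_from = "value")
    wide <- stats::na.omit(wide)
    t_ratio <- c(ratio_paired_ttest(wide[[paired_pair[1]]],
                                    wide[[paired_pair[2]]]),
                 list(pair = paired_pair, n_pairs = nrow(wide)))
  }
  structure(
    list(data = df, anova = anova, pairwise = pairwise,
         t_ratio_paired = t_ratio),
    class = "group_comparison")
}

# two-sided p of a pairwise pooled-variance t on the ANOVA within MS
pooled_t_p <- function(df, g1, g2, ms_within, df_within) {
  x <- df$value[df$group == g1]
  y <- df$value[df$group == g2]
  if (ms_within == 0) {
    return(if (mean(x) == mean(y)) 1 else .Machine$double.xmin)
  }
  tstat <- (mean(x) - mean(y)) /
    sqrt(ms_within * (1 / length(x) + 1 / length(y)))
  2 * stats::pt(abs(tstat), df_within, lower.tail = FALSE)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d groups, F = %.4g, p = %.4g\n",
              nlevels(x$data$group), x$anova$F, x$anova$p))
  print(x$pairwise)
  if (!is.null(x$t_ratio_paired)) {
    cat(sprintf("ratio paired t-test %s vs %s: t = %.4g, p = %.4g (n = %d)\n",
                x$t_ratio_paired$pair[1], x$t_ratio_paired$pair[2],
                x$t_ratio_paired$t, x$t_ratio_paired$p,
                x$t_ratio_paired$n_pairs))
  }
  invisible(x)
}

#' Tidiers for comparison and allele-call objects
#'
#' `tidy()` returns the pairwise comparison table (one row per group pair,
#' raw and Holm-Sidak adjusted p); `glance()` returns the one-row model
#' summary (F, overall p, degrees of freedom, and the ratio paired t-test
#' when requested).
#'
#' @param x A `group_comparison` or `allele_call` object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.group_comparison <- function(x, ...) {
  x$pairwise
}

#' @rdname tidiers
#' @export
glance.group_comparison <- function(x, ...) {
  out <- tibble::tibble(
    n_groups = nlevels(x$data$group),
    n_values = nrow(x$data),
    statistic = x$anova$F,
    p_value = x$anova$p,
    df_between = x$anova$df_between,
    df_within = x$anova$df_within,
    p_underflow = x$anova$p_underflow)
  if (!is.null(x$t_ratio_paired)) {
    out$t_ratio_paired <- x$t_ratio_paired$t
    out$p_ratio_paired <- x$t_ratio_paired$p
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write a comparison report as TSV + JSON
#' @param comparison A `group_comparison`.
#' @param tsv,json Destination paths (either may be `NULL` to skip).
#' @return Invisibly, the comparison.
#' @export
write_comparison_report <- function(comparison, tsv = NULL, json = NULL) {
  stopifnot(inherits(comparison, "group_comparison"))
  if (!is.null(tsv)) {
    readr::write_tsv(tidy(comparison), tsv)
  }
  if (!is.null(json)) {
    payload <- list(anova = comparison$anova,
                    pairwise = tidy(comparison),
                    t_ratio_paired = comparison$t_ratio_paired)
    jsonlite::write_json(payload, json, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(comparison)
}
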