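# Correlation analysis and the Ordered Selection Scheme (OSS).

#' Pearson correlation with a t-based two-sided p value
#'
#' @param x,y Equal-length numeric series (n >= 3) with nonzero variance.
#' @return Tibble with `r`, `p_value`, `n`.
#' @examples
#' pearson_r(1:10, (1:10)^2)
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (n != length(y)) {
    abort("Series lengths differ.", class = "icp_invalid_config")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need n >= 3.", class = "icp_invalid_config")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero-variance series; correlation undefined.",
          class = "icp_degenerate_input")
  }
  r <- stats::cor(x, y)
  r_c <- min(max(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_c * sqrt((n - 2) / (1 - r_c^2))
  tibble::tibble(r = r, p_value = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Correlation-strength bin of a coefficient
#'
#' Bins on `|r|` with the conventional boundaries: very strong (> 0.8),
#' strong (> 0.6 and <= 0.8), weak+ (> 0.4 and <= 0.6), weak (> 0.2 and
#' <= 0.4), none (<= 0.2). Boundary values fall in the lower bin (0.8 is
#' "strong").
#'
#' @param r Numeric vector of correlation coefficients, `|r| <= 1`.
#' @return Factor with levels none < weak < weak+ < strong < very strong.
#' @export
bin_strength <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    abort("|r| exceeds 1.", class = "icp_invalid_config")
  }
  a <- abs(r)
  lab <- ifelse(a > 0.8, "very strong",
         ifelse(a > 0.6, "strong",
         ifelse(a > 0.4, "weak+",
         ifelse(a > 0.2, "weak", "none"))))
  factor(lab, levels = c("none", "weak", "weak+", "strong", "very strong"))
}

#' Correlate every feature series with reference pressure
#'
#' Computes the Pearson coefficient between each (trial, variant, class)
#' feature series from [extract_features()] and its synchronized pressure,
#' with the t-based p value and the strength bin. Series with masked (NA)
#' sweeps keep their finite pairs; series left with fewer than 3 finite
#' pairs or zero variance are dropped with a warning.
#'
#' @param features Tidy feature table from [extract_features()] (possibly
#'   row-bound over trials and sensors).
#' @return Tibble of class `icp_corr`: grouping keys, `r`, `p_value`, `n`,
#'   `bin`.
#' @export
correlate_features <- function(features) {
  out <- features |>
    dplyr::group_by(.data$sensor_id, .data$trial_index, .data$placement,
                    .data$variant, .data$class) |>
    dplyr::group_modify(function(df, key) {
      ok <- is.finite(df$value) & is.finite(df$p_mmHg)
      if (sum(ok) < 3 || sd(df$value[ok]) == 0 || sd(df$p_mmHg[ok]) == 0) {
        return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                              n = sum(ok)))
      }
      pearson_r(df$value[ok], df$p_mmHg[ok])
    }) |>
    dplyr::ungroup()
  dropped <- sum(is.na(out$r))
  if (dropped > 0) {
    warn(sprintf("%d feature series dropped (degenerate or too short).",
                 dropped))
    out <- out[!is.na(out$r), ]
  }
  out$bin <- bin_strength(out$r)
  class(out) <- c("icp_corr", class(out))
  out
}

#' Ordered Selection Scheme over a correlation report
#'
#' Orders feature classes by correlation strength and keeps those whose
#' strength strictly exceeds the threshold. When the report carries several
#' rows per class (one per trial/variant), each class is scored by the mean
#' of `|r|` across its rows and gated by the median p value; a single-row-
#' per-class report is used as is. Selection additionally requires
#' statistical significance at `sig_level` (default 0.001, configurable).
#'
#' @param report An `icp_corr` or any tibble with `class`, `r`, `p_value`.
#' @param threshold Correlation-strength threshold (default 0.8,
#'   strict inequality).
#' @param sig_level Significance gate on the p value; `NULL` disables it.
#' @return Tibble of class `oss_selection`, ordered by score descending
#'   (ties keep class order a..l): `class`, `score` (mean `|r|`),
#'   `p_value`, `n_series`, `selected`.
#' @export
oss_select <- function(report, threshold = 0.8, sig_level = 0.001) {
  scored <- report |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(score = mean(abs(.data$r)),
                     p_value = median(.data$p_value),
                     n_series = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$class)
  scored$selected <- scored$score > threshold
  if (!is.null(sig_level)) {
    scored$selected <- scored$selected & scored$p_value < sig_level
  }
  if (!any(scored$selected)) {
    warn("OSS selection is empty at this threshold.")
  }
  class(scored) <- c("oss_selection", class(scored))
  scored
}

#' Counts per correlation-strength bin
#'
#' Summary used for flow (Sankey-style) reporting: how many scored feature
#' series fall in each strength bin; counts sum to the number of series.
#'
#' @param report An `icp_corr`.
#' @return Tibble with `bin`, `count`, `share` (percent).
#' @export
bin_summary <- function(report) {
  out <- report |>
    dplyr::count(.data$bin, name = "count", .drop = FALSE)
  out$share <- 100 * out$count / sum(out$count)
  out
}
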