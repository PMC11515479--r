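#' Pair an estimate stream with blood-gas references
#'
#' For every blood-gas analysis the latest non-withheld estimate within its
#' documented minute `[m, m + 60 s)` is paired with the measured PaCO2.
#' Blood gases whose documented minute holds no usable estimate are dropped
#' (and counted in attribute `n_dropped`).
#'
#' @param estimates Estimate record data frame (from [run_online()] or the
#'   baselines).
#' @param bgas Blood-gas data frame with columns `minute` and `paco2`.
#' @return Data frame with one row per paired blood gas: `minute`,
#'   `estimate_time`, `estimate`, `paco2`; attribute `n_dropped`.
#' @export
pair_estimates <- function(estimates, bgas) {
  usable <- estimates[estimates$withheld_reason == "none" &
                        !is.na(estimates$value), , drop = FALSE]
  rows <- lapply(seq_len(nrow(bgas)), function(k) {
    m <- bgas$minute[k]
    in_min <- usable[usable$time >= m & usable$time < m + 60, , drop = FALSE]
    if (nrow(in_min) == 0L) return(NULL)
    j <- which.max(in_min$time)
    data.frame(minute = m, estimate_time = in_min$time[j],
               estimate = in_min$value[j], paco2 = bgas$paco2[k])
  })
  keep <- !vapply(rows, is.null, TRUE)
  out <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(minute = numeric(), estimate_time = numeric(),
               estimate = numeric(), paco2 = numeric())
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Error metrics of paired estimates
#'
#' Differences are `estimate - paco2`. MAE is the mean absolute difference;
#' SD the sample standard deviation of the differences (n - 1 denominator,
#' the standard convention for the SD of method differences); SE = SD /
#' sqrt(n). Values are kept at full precision; rounding to two decimals
#' happens only at report formatting.
#'
#' @param pairs Data frame from [pair_estimates()] (or any frame with
#'   `estimate` and `paco2` columns), n >= 2.
#' @return List: `n`, `mean_diff`, `mae`, `sd`, `se` (all mmHg except `n`).
#' @export
error_metrics <- function(pairs) {
  d <- pairs$estimate - pairs$paco2
  n <- length(d)
  if (n < 2L) stop_insufficient("error_metrics needs at least 2 pairs")
  s <- stats::sd(d)
  list(n = n, mean_diff = mean(d), mae = mean(abs(d)), sd = s,
       se = s / sqrt(n))
}

#' Bland-Altman agreement with quantile limits
#'
#' Because the differences between estimate and reference are not normally
#' distributed, the limits of agreement are empirical quantiles of the
#' differences (default 2.5th and 97.5th percentiles), computed by linear
#' interpolation between order statistics at position `h = (n - 1) q + 1`
#' (the default quantile definition of R). The abscissa for plotting is the
#' mean of estimate and reference.
#'
#' @inheritParams error_metrics
#' @param q_low,q_high Quantile orders of the lower/upper limit.
#' @param method Label carried into the report.
#' @return Object of class `agreement_report`: `method`, `n`, `mean_diff`,
#'   `mae`, `sd`, `se`, `loa_low`, `loa_high`, plus a `plot_data` frame
#'   (`mean`, `difference`) for the Bland-Altman plot.
#' @export
bland_altman <- function(pairs, q_low = 0.025, q_high = 0.975,
                         method = "rlr") {
  if (!is.numeric(q_low) || !is.numeric(q_high) ||
      q_low < 0 || q_high > 1 || q_low >= q_high)
    stop_invalid_config("need 0 <= q_low < q_high <= 1")
  m <- error_metrics(pairs)
  d <- pairs$estimate - pairs$paco2
  loa <- unname(stats::quantile(d, c(q_low, q_high), type = 7))
  structure(
    c(list(method = method), m,
      list(loa_low = loa[1], loa_high = loa[2],
           plot_data = data.frame(mean = (pairs$estimate + pairs$paco2) / 2,
                                  difference = d))),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s (n = %d)\n", x$method, x$n))
  cat(sprintf("  mean diff %.2f, MAE %.2f, SD %.2f, SE %.2f mmHg\n",
              x$mean_diff, x$mae, x$sd, x$se))
  cat(sprintf("  95%% limits of agreement (quantiles): [%.2f, %.2f] mmHg\n",
              x$loa_low, x$loa_high))
  invisible(x)
}

#' Relative and absolute MAE reduction
#'
#' @param mae_ref Reference method MAE in mmHg (> 0).
#' @param mae_new Comparison method MAE in mmHg.
#' @return List with `abs` (mmHg) and `rel` (percent), both rounded to two
#'   decimal digits as reported.
#' @examples
#' relative_reduction(5.15, 3.80)   # abs 1.35, rel 26.21
#' @export
relative_reduction <- function(mae_ref, mae_new) {
  if (!is.numeric(mae_ref) || mae_ref <= 0)
    stop_domain("mae_ref must be > 0")
  ab <- mae_ref - mae_new
  list(abs = round(ab, 2), rel = round(100 * ab / mae_ref, 2))
}

#' Compare estimation methods on one trial
#'
#' Applies the study filters once to determine the kept blood-gas set: PaCO2
#' at or below the ceiling (skipped when `include_high_paco2`) and
#' trailing-averaged expiratory tidal volume at or above the floor at the
#' end of the documented minute. Every method stream is then paired against
#' this identical set; blood gases that any method fails to cover are
#' dropped from all, so all reports share the same n. Reports include the
#' MAE reduction of `"rlr"` relative to `"etco2"` when both streams are
#' supplied.
#'
#' @param streams Named list of estimate record data frames (names are the
#'   method labels, e.g. `rlr`, `etco2`, `etco2_offset`).
#' @param trial The `trial_recording` the streams were computed on (used to
#'   evaluate the Vte filter).
#' @param bgas Blood-gas data frame (`minute`, `paco2`).
#' @param cfg A [filter_config()].
#' @param include_high_paco2 If `TRUE`, keep blood gases above the PaCO2
#'   ceiling (extended evaluation).
#' @param online_cfg [online_config()] used for the Vte filter window.
#' @return Object of class `method_comparison`: `reports` (named list of
#'   `agreement_report`s), `n`, `mae_reduction_abs`, `mae_reduction_rel`,
#'   `filter_report`.
#' @export
compare_methods <- function(streams, trial, bgas, cfg = filter_config(),
                            include_high_paco2 = FALSE,
                            online_cfg = online_config()) {
  if (is.null(names(streams)) || any(!nzchar(names(streams))))
    stop_invalid_config("streams must be a named list of estimate frames")
  bgas <- bgas[order(bgas$minute), , drop = FALSE]
  # Vte at each BGA: trailing average ending with the documented minute.
  vte <- trailing_means(trial$channels[["Vte"]], bgas$minute + 60,
                        online_cfg$window,
                        trial$channel_specs[["Vte"]]$sampling_rate,
                        online_cfg$min_coverage)$mean
  samples <- data.frame(paco2 = bgas$paco2, Vte = vte,
                        complete = !is.na(vte))
  flt <- apply_filters(samples, cfg, include_high_paco2 = include_high_paco2)
  kept_idx <- which(!is.na(vte) & vte >= cfg$vte_min &
                      (include_high_paco2 | bgas$paco2 <= cfg$paco2_max))
  kept_bgas <- bgas[kept_idx, , drop = FALSE]

  pairs <- lapply(streams, pair_estimates, bgas = kept_bgas)
  # intersection of minutes every method managed to pair
  common <- Reduce(intersect, lapply(pairs, function(p) p$minute))
  pairs <- lapply(pairs, function(p) p[p$minute %in% common, , drop = FALSE])
  n <- length(common)
  if (n < 2L)
    stop_insufficient("fewer than 2 blood gases pairable by all methods")
  reports <- mapply(function(p, nm) bland_altman(p, method = nm),
                    pairs, names(pairs), SIMPLIFY = FALSE)
  red <- list(abs = NA_real_, rel = NA_real_)
  if (all(c("rlr", "etco2") %in% names(reports)))
    red <- relative_reduction(reports[["etco2"]]$mae, reports[["rlr"]]$mae)
  structure(
    list(reports = reports, n = n, mae_reduction_abs = red$abs,
         mae_reduction_rel = red$rel, filter_report = flt$report),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> n = %d blood gases\n", x$n))
  tab <- do.call(rbind, lapply(x$reports, function(r)
    data.frame(method = r$method, MAE = round(r$mae, 2),
               SD = round(r$sd, 2), SE = round(r$se, 2))))
  print(tab, row.names = FALSE)
  if (!is.na(x$mae_reduction_rel))
    cat(sprintf("  rlr vs etco2: MAE reduced by %.2f mmHg (%.2f%%)\n",
                x$mae_reduction_abs, x$mae_reduction_rel))
  invisible(x)
}
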