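#' Robust fitting configuration
#'
#' @param huber_k Huber tuning constant (default 1.345, giving 95% Gaussian
#'   efficiency).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the maximum coefficient change
#'   relative to the coefficient magnitude.
#' @param corr_threshold Selection stop: iteration ends once no candidate's
#'   absolute Pearson correlation with the current deviations exceeds this
#'   (default 0.2).
#' @param max_terms Safety cap on the number of selected terms.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(huber_k = 1.345, max_iter = 50L, tol = 1e-8,
                       corr_threshold = 0.2, max_terms = 10L) {
  if (!is.numeric(huber_k) || huber_k <= 0)
    stop_invalid_config("huber_k must be > 0")
  if (corr_threshold <= 0 || corr_threshold >= 1)
    stop_invalid_config("corr_threshold must lie in (0, 1)")
  structure(list(huber_k = huber_k, max_iter = as.integer(max_iter),
                 tol = tol, corr_threshold = corr_threshold,
                 max_terms = as.integer(max_terms)),
            class = "fit_config")
}

#' Sample Pearson correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Correlation in `[-1, 1]`, or `NA_real_` when either vector is
#'   (numerically) constant, so that callers can skip the candidate rather
#'   than crash.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop_invalid_config("x and y lengths differ")
  if (length(x) < 3L) stop_insufficient("pearson needs at least 3 points")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) ||
      sx <= 1e-12 * max(1, abs(mean(x))) ||
      sy <= 1e-12 * max(1, abs(mean(y)))) return(NA_real_)
  r <- sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
  max(-1, min(1, r))
}

#' Huber weights
#'
#' Weight function of the Huber M-estimator: residuals within `k` robust
#' scales get full weight 1; larger residuals are downweighted by
#' `k * scale / |r|`.
#'
#' @param residuals Numeric residual vector (mmHg).
#' @param scale Robust residual scale (> 0).
#' @param k Huber tuning constant.
#' @return Weights in `(0, 1]`.
#' @export
huber_weights <- function(residuals, scale, k = 1.345) {
  if (!is.numeric(scale) || scale <= 0)
    stop_degenerate_scale("scale must be > 0")
  u <- abs(residuals) / scale
  ifelse(u <= k, 1, k / u)
}

#' Robust residual scale
#'
#' `1.4826 *` median absolute deviation about the median, consistent for the
#' Gaussian SD.
#'
#' @param residuals Numeric vector (length >= 2).
#' @return Scale estimate in mmHg.
#' @export
robust_scale <- function(residuals) {
  if (length(residuals) < 2L)
    stop_insufficient("robust_scale needs at least 2 residuals")
  m <- stats::median(residuals)
  mad <- stats::median(abs(residuals - m))
  if (mad <= 0)
    stop_degenerate_scale("median absolute deviation is zero")
  1.4826 * mad
}

# Weighted least squares via QR; classed error on rank deficiency.
wls_solve <- function(Xd, y, w = NULL) {
  Xw <- if (is.null(w)) Xd else Xd * sqrt(w)
  yw <- if (is.null(w)) y else y * sqrt(w)
  qr_ <- qr(Xw)
  if (qr_$rank < ncol(Xd))
    stop_singular("design matrix is rank deficient")
  qr.coef(qr_, yw)
}

#' Huber M-estimator regression via IRLS
#'
#' Fits `y ~ intercept + X` with the Huber loss by iteratively reweighted
#' least squares: ordinary least squares initialisation, then repeated
#' weighted fits with [huber_weights()] until the maximum relative
#' coefficient change drops below `cfg$tol`. The robust scale is recomputed
#' each iteration from the current residuals ([robust_scale()]). When the
#' residual scale collapses to zero (exactly linear data) the current
#' solution is accepted as an exact fit.
#'
#' @param X Numeric matrix of regressors (no intercept column; one column
#'   per term, labelled), or a `design_matrix` restricted via `terms`.
#' @param y Response vector (mmHg).
#' @param cfg A [fit_config()].
#' @return A `paco2_model`. Term labels are taken from `colnames(X)`; bases
#'   and transforms are parsed back from the labels when they follow the
#'   canonical naming.
#' @export
fit_huber <- function(X, y, cfg = fit_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (n != length(y)) stop_invalid_config("nrow(X) must equal length(y)")
  if (n <= ncol(X) + 1L)
    stop_insufficient("need more rows than columns + 1")
  Xd <- cbind(`(Intercept)` = 1, X)
  beta <- wls_solve(Xd, y)
  scale_floor <- 1e-9 * max(1, max(abs(y)))
  converged <- FALSE
  scale <- NA_real_
  iter <- 0L
  for (iter in seq_len(cfg$max_iter)) {
    res <- y - drop(Xd %*% beta)
    m <- stats::median(res)
    mad_scale <- 1.4826 * stats::median(abs(res - m))
    if (mad_scale <= scale_floor) {  # exact (or near-exact) fit
      converged <- TRUE
      scale <- mad_scale
      break
    }
    scale <- mad_scale
    w <- huber_weights(res, scale, cfg$huber_k)
    beta_new <- wls_solve(Xd, y, w)
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta_new)))
    beta <- beta_new
    if (delta < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("fit_huber: IRLS did not converge within max_iter iterations")
  terms <- parse_labels(colnames(X))
  terms$coefficient <- as.numeric(beta[-1L])
  paco2_model(intercept = beta[1L], terms = terms, scale = scale,
              n_iter = iter, converged = converged, method = "huber-irls")
}

# Inverse of candidate_label(): recover (base, transform) from labels.
parse_labels <- function(labels) {
  base <- labels
  transform <- rep("identity", length(labels))
  sq <- grepl("\\^2$", labels)
  cb <- grepl("\\^3$", labels)
  lg <- grepl("^log\\(.*\\)$", labels)
  base[sq] <- sub("\\^2$", "", labels[sq])
  base[cb] <- sub("\\^3$", "", labels[cb])
  base[lg] <- sub("^log\\((.*)\\)$", "\\1", labels[lg])
  transform[sq] <- "square"
  transform[cb] <- "cube"
  transform[lg] <- "log"
  data.frame(base = base, transform = transform, label = labels,
             stringsAsFactors = FALSE)
}

#' Iterative residual-correlation variable selection
#'
#' Starting from the forced etCO2 term, candidates are added one at a time:
#' the initial deviations are the raw differences `PaCO2 - etCO2`; in every
#' iteration the not-yet-chosen candidate with the highest absolute Pearson
#' correlation to the current deviations is included (absolute value, so
#' negatively acting terms are selectable), the model
#' `{intercept, etCO2, chosen terms}` is refit with [fit_huber()], and the
#' deviations become its residuals. Selection stops once no candidate's
#' absolute correlation exceeds `cfg$corr_threshold` (default 0.2) or the
#' `max_terms` safety cap is reached. Candidates with undefined correlation
#' (constant columns, or deviations already numerically zero) are skipped.
#' Ties resolve to the candidate earlier in canonical catalogue order.
#'
#' @param dm A `design_matrix` from [build_design_matrix()] (contains the
#'   forced etCO2 column, the candidate matrix and the PaCO2 response).
#' @param cfg A [fit_config()].
#' @return List with `model` (final `paco2_model`) and `trace` (class
#'   `selection_trace`: data frame `steps` with `step`, `label`, `max_abs_r`,
#'   per-step model snapshots in `models`, and `stop_reason`, either
#'   `"threshold"` or `"max_terms"`).
#' @export
select_iteratively <- function(dm, cfg = fit_config()) {
  if (!inherits(dm, "design_matrix"))
    stop_invalid_config("dm must be a design_matrix")
  y <- dm$y
  forced_lab <- colnames(dm$forced)[1L]
  dev <- y - drop(dm$forced)   # raw PaCO2 - etCO2 deviation
  pool <- seq_len(ncol(dm$X))
  chosen <- integer(0)
  steps <- list()
  models <- list()
  model <- NULL
  stop_reason <- "threshold"
  while (length(chosen) < cfg$max_terms) {
    r <- vapply(pool, function(j) pearson(dm$X[, j], dev), 0)
    if (all(is.na(r)) || length(pool) == 0L) break
    best <- which.max(abs(r))   # first max wins: canonical-order tie-break
    if (is.na(r[best]) || abs(r[best]) <= cfg$corr_threshold) break
    j <- pool[best]
    chosen <- c(chosen, j)
    pool <- pool[-best]
    Xfit <- cbind(dm$forced, dm$X[, chosen, drop = FALSE])
    model <- fit_huber(Xfit, y, cfg)
    dev <- y - eval_linear(model, Xfit)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(chosen), label = colnames(dm$X)[j],
      max_abs_r = abs(r[best]), stringsAsFactors = FALSE)
    models[[length(steps)]] <- model
  }
  if (length(chosen) >= cfg$max_terms) stop_reason <- "max_terms"
  if (is.null(model)) {   # nothing selected: fit forced term alone
    model <- fit_huber(dm$forced, y, cfg)
  }
  trace <- structure(
    list(steps = if (length(steps)) do.call(rbind, steps) else
           data.frame(step = integer(), label = character(),
                      max_abs_r = numeric()),
         models = models, stop_reason = stop_reason),
    class = "selection_trace")
  list(model = model, trace = trace)
}

# Linear predictor of a fitted model on the exact columns it was fit to.
eval_linear <- function(model, X) {
  drop(model$intercept + X[, model$terms$label, drop = FALSE] %*%
         model$terms$coefficient)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d terms selected (stop: %s)\n",
              nrow(x$steps), x$stop_reason))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}
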