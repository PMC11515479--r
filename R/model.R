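#' Construct a fitted estimation model
#'
#' A linear model for PaCO2 on transformed covariates: an intercept plus one
#' coefficient per (base variable, transform) term.
#'
#' @param intercept Intercept in mmHg.
#' @param terms Data frame with columns `base`, `transform`, `coefficient`
#'   (a `label` column is added if absent). May have zero rows
#'   (intercept-only model).
#' @param scale Robust residual scale in mmHg (`NA` for frozen models).
#' @param n_iter Number of IRLS iterations performed.
#' @param converged Logical convergence flag.
#' @param method Fitting method label.
#' @return Object of class `paco2_model`.
#' @export
paco2_model <- function(intercept, terms, scale = NA_real_, n_iter = 0L,
                        converged = TRUE, method = "frozen") {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    stop_invalid_config("intercept must be a single finite number")
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (nrow(terms) > 0L) {
    need <- c("base", "transform", "coefficient")
    if (!all(need %in% names(terms)))
      stop_invalid_config("terms must have columns base, transform, coefficient")
    if (any(!is.finite(terms$coefficient)))
      stop_invalid_config("term coefficients must be finite")
    if (is.null(terms$label))
      terms$label <- mapply(candidate_label, terms$base, terms$transform,
                            USE.NAMES = FALSE)
  } else {
    terms <- data.frame(base = character(), transform = character(),
                        coefficient = numeric(), label = character(),
                        stringsAsFactors = FALSE)
  }
  structure(
    list(intercept = as.numeric(intercept), terms = terms,
         scale = as.numeric(scale), n_iter = as.integer(n_iter),
         converged = isTRUE(converged), method = method),
    class = "paco2_model"
  )
}

#' The frozen published estimation equation
#'
#' The RLR-PaCO2 estimator: PaCO2 is estimated as
#' `31.8164 + 0.8892 etCO2 - 0.0019 O2diff^2 - 0.0854 pctSpont
#'  + 0.002 Pmean^3 - 5.2879 log(Vte)`
#' with etCO2 in mmHg, O2diff = FiO2 - SpO2 in percentage points, pctSpont
#' the spontaneous breathing percentage, Pmean the mean airway pressure in
#' mbar and Vte the expiratory tidal volume in mL (natural logarithm).
#'
#' @return A `paco2_model` with the five published terms.
#' @examples
#' m <- published_model()
#' predict(m, data.frame(etCO2 = 40, FiO2 = 21, SpO2 = 91,
#'                       pctSpont = 0, Pmean = 12, Vte = 20))
#' @export
published_model <- function() {
  paco2_model(
    intercept = 31.8164,
    terms = data.frame(
      base = c("etCO2", "O2diff", "pctSpont", "Pmean", "Vte"),
      transform = c("identity", "square", "identity", "cube", "log"),
      coefficient = c(0.8892, -0.0019, -0.0854, 0.002, -5.2879),
      stringsAsFactors = FALSE
    ),
    method = "published"
  )
}

# Evaluate the model's linear predictor on a data frame of base variables.
# Derived oxygenation indices are computed from FiO2/SpO2 when needed.
# Missing required columns raise a missing-parameters condition; NA values
# propagate to NA predictions (the online loop withholds those upstream).
eval_model <- function(model, data) {
  data <- as.data.frame(data)
  need <- unique(model$terms$base)
  derived_needed <- intersect(need, .derived_variable_names)
  if (length(derived_needed) && !all(derived_needed %in% names(data)))
    data <- add_oxygen_indices(data)
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop_missing_parameters(paste0("missing covariates: ",
                                   paste(missing, collapse = ", ")))
  out <- rep(model$intercept, nrow(data))
  for (j in seq_len(nrow(model$terms))) {
    b <- model$terms$base[j]
    tr <- model$terms$transform[j]
    v <- data[[b]]
    if (tr == "log" && any(v <= 0, na.rm = TRUE))
      stop_domain(sprintf("log(%s) undefined: non-positive value", b))
    out <- out + model$terms$coefficient[j] * apply_transform(v, tr)
  }
  out
}

#' Predict PaCO2 from averaged covariates
#'
#' @param object A `paco2_model`.
#' @param newdata Data frame (or coercible) with one column per required base
#'   variable (FiO2 and SpO2 may stand in for the derived oxygenation
#'   indices). One row per prediction.
#' @param ... Unused.
#' @return Numeric vector of estimates in mmHg.
#' @export
predict.paco2_model <- function(object, newdata, ...) {
  eval_model(object, newdata)
}

#' @export
print.paco2_model <- function(x, digits = 4, ...) {
  cat(sprintf("<paco2_model> (%s%s)\n", x$method,
              if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  PaCO2 ~ %.*f", digits, x$intercept))
  for (j in seq_len(nrow(x$terms)))
    cat(sprintf(" %s %.*f * %s",
                if (x$terms$coefficient[j] < 0) "-" else "+",
                digits, abs(x$terms$coefficient[j]), x$terms$label[j]))
  cat("\n")
  if (is.finite(x$scale))
    cat(sprintf("  robust scale %.*f mmHg, %d IRLS iterations\n",
                digits, x$scale, x$n_iter))
  invisible(x)
}

#' Extract coefficients from a fitted PaCO2 model
#'
#' @param object A `paco2_model`.
#' @param ... Unused.
#' @return Named numeric vector: `(Intercept)` followed by term labels.
#' @export
coef.paco2_model <- function(object, ...) {
  c("(Intercept)" = object$intercept,
    stats::setNames(object$terms$coefficient, object$terms$label))
}
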