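#' @title Candidate feature catalogue and design matrix
#' @name feature_builder
#' @description
#' The regression considers, for each of the 17 base variables, the identity,
#' square and cube transforms, and additionally the natural logarithm for
#' variables that are strictly positive in every kept sample. The etCO2
#' identity term is always part of the model and is therefore excluded from
#' the candidate pool (its square, cube and log remain candidates).
NULL

.transforms <- c("identity", "square", "cube", "log")

apply_transform <- function(x, transform) {
  switch(transform,
    identity = x,
    square = x^2,
    cube = x^3,
    log = log(x),
    stop_invalid_config(sprintf("unknown transform '%s'", transform))
  )
}

candidate_label <- function(base, transform) {
  switch(transform,
    identity = base,
    square = paste0(base, "^2"),
    cube = paste0(base, "^3"),
    log = paste0("log(", base, ")")
  )
}

#' Derive the oxygenation indices
#'
#' Computes the two oxygenation indices from averaged FiO2 and SpO2:
#' `O2diff = FiO2 - SpO2` (a crude indicator of ventilation efficiency, in
#' percentage points) and `O2quot = SpO2 / FiO2` (related to the
#' SpO2/FiO2 ratio discussed as a non-invasive analogue of the Horowitz
#' quotient).
#'
#' @param fio2 Set fraction of inspired oxygen in percent (> 0).
#' @param spo2 Pulse-oximetric oxygen saturation in percent, within 0..100.
#' @return A list with numeric elements `O2diff` and `O2quot` (vectorised).
#' @examples
#' derive_oxygen_indices(21, 95)   # O2diff -74, O2quot ~4.52
#' @export
derive_oxygen_indices <- function(fio2, spo2) {
  if (any(!is.finite(fio2)) || any(fio2 <= 0))
    stop_domain("FiO2 must be > 0 to derive oxygenation indices")
  if (any(spo2 < 0 | spo2 > 100, na.rm = TRUE))
    stop_domain("SpO2 must lie in [0, 100]")
  list(O2diff = fio2 - spo2, O2quot = spo2 / fio2)
}

# Add O2diff/O2quot columns to a samples data frame if absent.
add_oxygen_indices <- function(samples) {
  if (!all(c("FiO2", "SpO2") %in% names(samples)))
    return(samples)
  idx <- derive_oxygen_indices(samples$FiO2, samples$SpO2)
  if (is.null(samples$O2diff)) samples$O2diff <- idx$O2diff
  if (is.null(samples$O2quot)) samples$O2quot <- idx$O2quot
  samples
}

#' Enumerate the candidate regressor catalogue
#'
#' For each base variable emits identity, square and cube descriptors, and a
#' natural-log descriptor for bases that are strictly positive in every
#' sample. The forced term (etCO2 identity by default) is excluded from the
#' pool because it is always present in the model. Order is canonical:
#' bases in catalogue order, transforms identity < square < cube < log.
#'
#' @param samples Data frame with one column per base variable (derived
#'   oxygenation indices are added automatically when FiO2/SpO2 are present).
#' @param bases Base variables to enumerate over; defaults to all 17.
#' @param forced Label of the forced model term excluded from the pool.
#' @return Data frame with columns `base`, `transform`, `label`.
#' @export
enumerate_candidates <- function(samples, bases = base_variables(),
                                 forced = "etCO2") {
  samples <- add_oxygen_indices(as.data.frame(samples))
  missing <- setdiff(bases, names(samples))
  if (length(missing))
    stop_build(paste0("samples lack base variables: ",
                      paste(missing, collapse = ", ")))
  if (nrow(samples) == 0L)
    stop_invalid_config("cannot enumerate candidates from zero samples")
  rows <- list()
  for (b in bases) {
    v <- samples[[b]]
    log_ok <- all(is.finite(v)) && all(v > 0)
    for (tr in .transforms) {
      if (tr == "log" && !log_ok) next
      lab <- candidate_label(b, tr)
      if (lab == forced) next
      rows[[length(rows) + 1L]] <- data.frame(
        base = b, transform = tr, label = lab, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the regression design matrix
#'
#' Applies each candidate transform to the averaged base values and assembles
#' the candidate matrix together with the forced etCO2 column and the PaCO2
#' response. Cells must be finite; a non-finite transformed value (e.g. the
#' log of a non-positive value) aborts with the offending row and column.
#'
#' @param samples Data frame of kept, complete averaged samples; must carry
#'   all base variables and a `paco2` column.
#' @param catalogue Candidate descriptor data frame from
#'   [enumerate_candidates()].
#' @param forced Name of the forced base variable (identity transform).
#' @return An object of class `design_matrix`: a list with the forced column
#'   `forced` (n x 1 matrix), candidate matrix `X` (n x p, canonical label
#'   columns), response `y`, `catalogue`, and row metadata `rows`.
#' @export
build_design_matrix <- function(samples, catalogue, forced = "etCO2") {
  samples <- add_oxygen_indices(as.data.frame(samples))
  if (is.null(samples$paco2))
    stop_build("samples must carry a 'paco2' response column")
  n <- nrow(samples)
  X <- matrix(NA_real_, n, nrow(catalogue),
              dimnames = list(NULL, catalogue$label))
  for (j in seq_len(nrow(catalogue))) {
    v <- apply_transform(samples[[catalogue$base[j]]], catalogue$transform[j])
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_build(sprintf("non-finite value in column '%s' at row %d",
                         catalogue$label[j], bad[1L]))
    X[, j] <- v
  }
  fx <- samples[[forced]]
  if (is.null(fx) || any(!is.finite(fx)))
    stop_build(sprintf("forced column '%s' missing or non-finite", forced))
  structure(
    list(
      forced = matrix(fx, ncol = 1L, dimnames = list(NULL, forced)),
      X = X,
      y = as.numeric(samples$paco2),
      catalogue = catalogue,
      rows = samples[, intersect(c("animal_id", "minute"), names(samples)),
                     drop = FALSE]
    ),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d samples, %d candidate columns (+ forced %s)\n",
              length(x$y), ncol(x$X), colnames(x$forced)[1L]))
  invisible(x)
}
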