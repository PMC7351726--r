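# Thermodynamic conversions between dock scores, inhibition constants and
# IC50-derived binding free energies.

#' Convert a binding free energy to an inhibition constant
#'
#' K_i = exp(Delta G / RT). More negative free energies give smaller
#' (tighter) inhibition constants; the map is strictly increasing in `dg`.
#'
#' @param dg Binding free energy, kcal/mol (any real value).
#' @param T Absolute temperature, K. Defaults to the docking convention
#'   298.15 K under which the study's K_i,pred column round-trips.
#' @param R_kcal Gas constant, kcal K^-1 mol^-1.
#' @return Inhibition constant, mol/L.
#' @examples
#' dg_to_ki(-14.09)          # ~4.7e-11 M, the series' best dock score
#' dg_to_ki(0)               # 1 M
#' @seealso [ki_to_dg()] for the inverse.
#' @export
dg_to_ki <- function(dg, T = 298.15, R_kcal = 1.987e-3) {
  stopifnot(T > 0, R_kcal > 0)
  exp(dg / (R_kcal * T))
}

#' Convert an inhibition constant to a binding free energy
#'
#' Delta G = RT ln(K_i), the inverse of [dg_to_ki()].
#'
#' @param ki Inhibition constant, mol/L; must be strictly positive.
#' @inheritParams dg_to_ki
#' @return Binding free energy, kcal/mol.
#' @examples
#' ki_to_dg(4.66e-11)   # back-converts to about -14.09 kcal/mol
#' @export
ki_to_dg <- function(ki, T = 298.15, R_kcal = 1.987e-3) {
  stopifnot(T > 0, R_kcal > 0)
  if (any(!is.finite(ki)) || any(ki <= 0))
    stop("inhibition constants must be positive and finite", call. = FALSE)
  R_kcal * T * log(ki)
}

#' Experimental binding free energy from a cell-based IC50
#'
#' Treats the IC50 as equal to the inhibition constant, converts uM to
#' mol/L and applies Delta G_exp = R T_exp ln(K_i) at the experimental
#' temperature convention (300 K by default). Censored entries (reported
#' only as exceeding the assay ceiling) yield `NA`: they carry no point
#' estimate and are excluded from any numeric computation.
#'
#' @param ic50_uM IC50 values in uM (vectorised).
#' @param censored Logical vector marking right-censored entries.
#' @param constants [thermo_constants()]; uses `R_kcal` and `T_exp`.
#' @return Delta G_exp in kcal/mol; `NA` for censored entries.
#' @examples
#' ic50_to_dg_exp(0.98)   # 6f on HL-60: about -8.25 kcal/mol
#' @export
ic50_to_dg_exp <- function(ic50_uM, censored = FALSE,
                           constants = thermo_constants()) {
  stopifnot(inherits(constants, "thermo_constants"))
  censored <- rep_len(censored, length(ic50_uM))
  quant <- !censored
  if (any(quant & (!is.finite(ic50_uM) | ic50_uM <= 0)))
    stop("quantified IC50 values must be positive and finite", call. = FALSE)
  out <- rep(NA_real_, length(ic50_uM))
  out[quant] <- constants$R_kcal * constants$T_exp * log(ic50_uM[quant] * 1e-6)
  out
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: requires at least three
#' pairs and non-degenerate variance on both axes.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Least-squares line with root-mean-square error
#'
#' Fits y = slope * x + intercept by ordinary least squares and reports the
#' root of the mean squared residual (in y-units), the error measure used
#' for the study's regression summaries.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `slope`, `intercept`, `rmse`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("undefined fit: zero variance in x", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       rmse = sqrt(mean(fit$residuals^2)))
}

#' Partition compounds by a docking-score threshold
#'
#' Virtual-screening rule of the study: compounds whose dock score is at or
#' below the threshold (set by the weaker reference inhibitor,
#' -10.69 kcal/mol) are classed as potential inhibitors. Ties pass.
#'
#' @param dock data.frame as from [load_docking()].
#' @param threshold Dock-score threshold, kcal/mol (negative).
#' @return List with character vectors `potential` and `below_threshold`.
#' @examples
#' screen_by_threshold(load_docking())
#' @export
screen_by_threshold <- function(dock, threshold = -10.69) {
  stopifnot(is.numeric(threshold), threshold < 0)
  if (is.null(dock) || nrow(dock) == 0)
    return(list(potential = character(), below_threshold = character()))
  pass <- dock$dg_dock <= threshold
  list(potential = dock$compound_id[pass],
       below_threshold = dock$compound_id[!pass])
}
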