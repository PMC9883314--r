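#' Density of pure water
#'
#' Kell's (1975) rational polynomial for the density of air-free water at
#' atmospheric pressure, accurate to well within 0.01 g/L of the NIST
#' reference tables over 0-40 degC and used here as the temperature
#' reference for density correction.
#'
#' @param T Temperature in degC, within the calibrated range 0-60.
#' @return Water density in g/L; vectorized.
#' @examples
#' water_density(20)  # 998.207
#' @export
water_density <- function(T) {
  if (!all(is.finite(T))) stop("water_density: non-finite temperature")
  if (any(T < 0 | T > 60))
    stop("water_density: temperature outside the calibrated 0-60 degC range")
  (999.83952 + 16.945176 * T - 7.9870401e-3 * T^2 - 46.170461e-6 * T^3 +
     105.56302e-9 * T^4 - 280.54253e-12 * T^5) / (1 + 16.879850e-3 * T)
}

#' Dynamic viscosity of pure water
#'
#' Vogel-type correlation `eta = 0.02414 * 10^(247.8/(T + 133.15))` mPa s,
#' adequate for ratio-based temperature correction over 0-60 degC.
#'
#' @param T Temperature in degC (0-60).
#' @return Viscosity in mPa s; vectorized.
#' @export
water_viscosity <- function(T) {
  if (!all(is.finite(T))) stop("water_viscosity: non-finite temperature")
  if (any(T < 0 | T > 60))
    stop("water_viscosity: temperature outside the calibrated 0-60 degC range")
  0.02414 * 10^(247.8 / (T + 133.15))
}

#' Temperature correction of density or viscosity readings
#'
#' Cross-multiplication against the pure-water reference: the reading at the
#' measurement temperature `T` is scaled by `ref(T0)/ref(T)` to the standard
#' process temperature `T0`. Valid for small temperature offsets where
#' deviations from ideal-solution behaviour are negligible; a warning is
#' issued when `|T - T0| > 5` K.
#'
#' @param value Measured density (g/L) or viscosity (mPa s); vectorized.
#' @param T Measurement temperature(s), degC.
#' @param T0 Standard process temperature, degC.
#' @param kind `"density"` (default) or `"viscosity"` — selects the water
#'   reference property.
#' @return Corrected value(s) at `T0`.
#' @export
temperature_correct <- function(value, T, T0, kind = c("density", "viscosity")) {
  kind <- match.arg(kind)
  if (any(abs(T - T0) > 5))
    warning("temperature_correct: |T - T0| > 5 K; ideal-solution ",
            "cross-multiplication may be inaccurate")
  ref <- switch(kind, density = water_density, viscosity = water_viscosity)
  value * ref(T0) / ref(T)
}

#' Fit the protein density increment from a dilution series
#'
#' Ordinary linear regression of temperature-corrected solution density on
#' protein concentration. The slope is the buffer-dependent density
#' increment per unit protein concentration (the partial-specific-volume
#' factor `a_prot`); the intercept is the protein-free buffer density.
#'
#' @param c_prot Protein concentrations of the dilution series (g/L), at
#'   least 3 distinct values.
#' @param rho_T0 Temperature-corrected densities (g/L), same length.
#' @return An object of class `protein_density_factor`: list with `a_prot`,
#'   `buffer_density`, `fit_r2`, `slope_se`, `n_points`.
#' @export
fit_partial_specific_factor <- function(c_prot, rho_T0) {
  if (length(c_prot) != length(rho_T0))
    stop("fit_partial_specific_factor: length mismatch")
  if (length(unique(c_prot)) < 3)
    stop("fit_partial_specific_factor: need >= 3 distinct concentrations")
  fit <- stats::lm(rho_T0 ~ c_prot)
  sm <- suppressWarnings(summary(fit))  # noiseless series: perfect fit
  structure(list(
    a_prot = unname(stats::coef(fit)[2]),
    buffer_density = unname(stats::coef(fit)[1]),
    fit_r2 = sm$r.squared,
    slope_se = sm$coefficients[2, 2],
    n_points = length(c_prot)),
    class = "protein_density_factor")
}

#' Subtract the protein contribution from a corrected density
#'
#' `rho_buffer = rho_T0 - a_prot * c_prot`: removes the protein's density
#' increment so the remainder tracks the buffer composition alone. The
#' factor fitted on the DF buffer is applied over the whole run as an
#' approximation (narrow pH/ionic-strength range).
#'
#' @param rho_T0 Temperature-corrected density (g/L); vectorized.
#' @param c_prot Protein concentration (g/L), >= 0; vectorized.
#' @param factor A [fit_partial_specific_factor()] result, or a bare numeric
#'   `a_prot`.
#' @return Buffer density at `T0` (g/L).
#' @export
protein_correct_density <- function(rho_T0, c_prot, factor) {
  a <- if (inherits(factor, "protein_density_factor")) factor$a_prot else factor
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a))
    stop("protein_correct_density: factor must be a fitted factor or scalar")
  if (any(c_prot < 0)) stop("protein_correct_density: c_prot must be >= 0")
  rho_T0 - a * c_prot
}

#' Convert a UV absorbance reading to protein concentration
#'
#' Beer-Lambert conversion `c = A280 / (extinction * pathlength)` without
#' scatter correction. Readings whose slope-regression coefficient of
#' determination is not above 0.97 are computed but flagged `rejected`
#' (variable-pathlength quality rule).
#'
#' @param A280 Pathlength-normalized absorbance at 280 nm (AU); vectorized.
#' @param r2 Slope-regression R^2 per reading (NA = no quality information,
#'   not rejected).
#' @param extinction Extinction coefficient (AU L / (g cm)), > 0.
#' @param pathlength Optical pathlength (cm), > 0.
#' @return Data frame with `concentration` (g/L) and logical `rejected`.
#' @export
absorbance_to_concentration <- function(A280, r2 = NA_real_, extinction,
                                        pathlength = 1) {
  if (!is.finite(extinction) || extinction <= 0)
    stop("absorbance_to_concentration: extinction must be > 0")
  if (!is.finite(pathlength) || pathlength <= 0)
    stop("absorbance_to_concentration: pathlength must be > 0")
  if (any(A280 < 0, na.rm = TRUE))
    stop("absorbance_to_concentration: A280 must be >= 0")
  n <- max(length(A280), length(r2))
  A280 <- rep_len(A280, n)
  r2 <- rep_len(r2, n)
  data.frame(concentration = A280 / (extinction * pathlength),
             rejected = !is.na(r2) & r2 <= 0.97)
}

#' Flag bubble-like artifacts in a sensor stream
#'
#' Air bubbles transiently lower the measured liquid density; readings more
#' than `threshold` median-absolute-deviations *below* a centred rolling
#' median are flagged. The MAD is computed from the residuals of the rolling
#' median over the whole stream.
#'
#' @param values Numeric sensor stream.
#' @param window Odd rolling-median window length (default 15).
#' @param threshold MAD multiplier (default 5).
#' @return Logical vector, `TRUE` where a downward artifact is flagged.
#' @export
flag_bubbles <- function(values, window = 15, threshold = 5) {
  n <- length(values)
  if (n < window) window <- max(3, if (n %% 2 == 1) n else n - 1)
  if (window %% 2 == 0) window <- window + 1
  med <- stats::runmed(values, k = window, endrule = "median")
  res <- values - med
  s <- stats::mad(res)
  if (s <= 0) s <- max(stats::sd(res), .Machine$double.eps)
  res < -threshold * s
}

#' Read / write sensor streams as CSV
#'
#' Density streams use columns `t, value, temperature`; UV streams use
#' `t, A280, r2`. Output adds any flag columns present and a provenance
#' header (lines starting with `#`).
#'
#' @param path CSV file path.
#' @return `read_sensor_csv`: a data frame (header lines skipped).
#' @export
read_sensor_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

#' @rdname read_sensor_csv
#' @param x Data frame to write.
#' @param header Optional character vector of provenance lines (written
#'   prefixed with `#`).
#' @export
write_sensor_csv <- function(x, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
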