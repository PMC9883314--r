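#' Diafiltration mass-balance parameters
#'
#' Bundles the constants of the constant-volume diafiltration (DF) model: a
#' well-mixed retentate tank fed with DF buffer at the same rate as permeate
#' is withdrawn. Species passage through the membrane is scaled by an
#' empirical sieving coefficient `kappa` (close to 1 for freely passing ions;
#' above or below 1 under Donnan-type interactions).
#'
#' @param c_in Inflow (DF-buffer) concentration of the species (mol/L or g/L).
#' @param F Permeate flow rate (mL/min), constant within the phase.
#' @param V Retentate volume (mL), constant during DF.
#' @param kappa Dimensionless empirical sieving coefficient (>= 0).
#' @return An object of class `df_params`.
#' @examples
#' p <- df_params(c_in = 0, F = 4.5, V = 45, kappa = 1)
#' df_ode_rhs(10, p)
#' @export
df_params <- function(c_in, F, V, kappa) {
  stopifnot(is.numeric(c_in), is.numeric(F), is.numeric(V), is.numeric(kappa))
  if (!all(is.finite(c(c_in, F, V, kappa))))
    stop("df_params: all parameters must be finite")
  if (F <= 0) stop("df_params: permeate flow F must be > 0")
  if (V <= 0) stop("df_params: retentate volume V must be > 0")
  if (kappa < 0) stop("df_params: sieving coefficient kappa must be >= 0")
  if (c_in < 0) stop("df_params: inflow concentration c_in must be >= 0")
  structure(list(c_in = c_in, F = F, V = V, kappa = kappa),
            class = "df_params")
}

#' Rate of change of a species concentration during diafiltration
#'
#' Right-hand side of the CSTR buffer-exchange balance
#' \deqn{dc/dt = c_{in} F/V - c F \kappa / V.}
#'
#' @param c Current retentate concentration (>= 0).
#' @param params A [df_params()] object.
#' @return Concentration rate of change (conc/min).
#' @export
df_ode_rhs <- function(c, params) {
  stopifnot(inherits(params, "df_params"))
  if (!all(is.finite(c))) stop("df_ode_rhs: non-finite concentration")
  if (any(c < 0)) stop("df_ode_rhs: concentration must be >= 0")
  params$c_in * params$F / params$V - c * params$F * params$kappa / params$V
}

#' Analytic diafiltration concentration profile
#'
#' Closed-form solution of the buffer-exchange balance over an interval of
#' constant flow and volume:
#' \deqn{c(t_0 + \Delta t) = c_{in}/\kappa -
#'       (c_{in}/\kappa - c_0)\, e^{-\kappa F \Delta t / V}.}
#' The concentration relaxes exponentially from `c0` towards the steady state
#' `c_in / kappa`. The degenerate fully retained case `kappa = 0` falls back
#' to linear accumulation `c0 + c_in * F * dt / V` (out-of-model limit); when
#' `c_in > 0` this is signalled with a warning of class
#' `ufdf_degenerate_growth` because no steady state exists.
#'
#' @param c0 Concentration at the start of the interval.
#' @param params A [df_params()] object.
#' @param dt Elapsed time (min), `>= 0`; may be a vector.
#' @return Concentration(s) after `dt`.
#' @export
df_concentration <- function(c0, params, dt) {
  stopifnot(inherits(params, "df_params"))
  if (!all(is.finite(c0)) || !all(is.finite(dt)))
    stop("df_concentration: non-finite inputs")
  if (any(dt < 0)) stop("df_concentration: dt must be >= 0")
  if (any(c0 < 0)) stop("df_concentration: c0 must be >= 0")
  if (params$kappa == 0) {
    if (params$c_in > 0)
      warning(structure(
        class = c("ufdf_degenerate_growth", "warning", "condition"),
        list(message = paste("kappa = 0 with c_in > 0: no steady state,",
                             "returning linear accumulation limit"),
             call = sys.call())))
    return(c0 + params$c_in * params$F * dt / params$V)
  }
  css <- params$c_in / params$kappa
  css - (css - c0) * exp(-params$kappa * params$F * dt / params$V)
}

#' Cumulative diafiltration volumes
#'
#' Number of retentate volumes exchanged after `dt` minutes at constant
#' permeate flow: `DV = F * dt / V`. One DV corresponds to one reactor volume
#' of DF buffer forced over the membrane.
#'
#' @param F Permeate flow rate (mL/min), > 0.
#' @param V Retentate volume (mL), > 0.
#' @param dt Elapsed time (min), >= 0; may be a vector.
#' @return Dimensionless diafiltration volume(s).
#' @export
diafiltration_volumes <- function(F, V, dt) {
  if (!all(is.finite(c(F, V, dt)))) stop("diafiltration_volumes: non-finite inputs")
  if (F <= 0 || V <= 0) stop("diafiltration_volumes: F and V must be > 0")
  if (any(dt < 0)) stop("diafiltration_volumes: dt must be >= 0")
  F * dt / V
}

#' Residual fraction of an original buffer species
#'
#' Fraction of a species initially present in the retentate that remains
#' after `dv` diafiltration volumes when the DF buffer contains none of it:
#' `exp(-kappa * dv)`. At `kappa = 1`, eight DV deplete the species to
#' `exp(-8)` (about 0.034%); a fully retained species (`kappa = 0`) never
#' washes out.
#'
#' @param dv Diafiltration volumes (>= 0); may be a vector.
#' @param kappa Sieving coefficient (>= 0).
#' @return Residual fraction(s) in `[0, 1]`.
#' @export
residual_fraction <- function(dv, kappa) {
  if (!all(is.finite(c(dv, kappa)))) stop("residual_fraction: non-finite inputs")
  if (any(dv < 0)) stop("residual_fraction: dv must be >= 0")
  if (kappa < 0) stop("residual_fraction: kappa must be >= 0")
  exp(-kappa * dv)
}
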