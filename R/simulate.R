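#' UF/DF process recipe
#'
#' Describes a multi-phase crossflow-filtration run: ultrafiltration (UF)
#' phases concentrate the fully retained protein by volume reduction at
#' constant permeate flow; diafiltration (DF) phases exchange buffer at
#' constant volume. Small solutes cross the membrane scaled by a per-species
#' sieving coefficient.
#'
#' @param name Recipe label.
#' @param phases Ordered list of phases, each `list(kind = "UF", target = )`
#'   (target protein concentration, g/L) or `list(kind = "DF", dv = )`
#'   (diafiltration volumes).
#' @param F Permeate flow rate (mL/min).
#' @param V0 Initial retentate volume (mL).
#' @param species Data frame with columns `name`, `c0` (initial retentate
#'   concentration), `c_in` (DF-buffer concentration), `kappa` (sieving
#'   coefficient) and `drho` (density increment, g/L per concentration
#'   unit).
#' @param protein List with `name`, `c0` (g/L), `extinction`
#'   (AU L / (g cm)) and `a_prot` (density increment per g/L).
#' @param T0 Standard process temperature (degC, default 20).
#' @return An object of class `process_recipe`.
#' @export
process_recipe <- function(name, phases, F, V0, species, protein, T0 = 20) {
  stopifnot(is.list(phases), length(phases) >= 1, is.data.frame(species))
  if (F <= 0 || V0 <= 0) stop("process_recipe: F and V0 must be > 0")
  need <- c("name", "c0", "c_in", "kappa", "drho")
  if (!all(need %in% names(species)))
    stop("process_recipe: species needs columns ", paste(need, collapse = ", "))
  if (any(species$kappa < 0) || any(species$c0 < 0) || any(species$c_in < 0))
    stop("process_recipe: species concentrations and kappa must be >= 0")
  cp <- protein$c0
  for (ph in phases) {
    if (!ph$kind %in% c("UF", "DF")) stop("process_recipe: phase kind must be UF or DF")
    if (ph$kind == "UF") {
      if (is.null(ph$target) || ph$target <= cp)
        stop("process_recipe: UF target must exceed the current protein concentration")
      cp <- ph$target
    } else if (is.null(ph$dv) || ph$dv <= 0) {
      stop("process_recipe: DF phase needs dv > 0")
    }
  }
  structure(list(name = name, phases = phases, F = F, V0 = V0,
                 species = species, protein = protein, T0 = T0),
            class = "process_recipe")
}

#' Simulate the true state of a UF/DF run
#'
#' Deterministic ground truth on a regular time grid. UF phases: the volume
#' shrinks at the permeate flow rate, the fully retained protein
#' concentrates as `c V0 / V`, and a species with sieving coefficient
#' `kappa` follows `c (V/V0)^(kappa - 1)` (mass balance with permeate
#' concentration `kappa c`). DF phases: constant volume, species follow the
#' analytic exponential-exchange solution ([df_concentration()]), protein
#' mass is conserved exactly. The sensor-side temperature carries a smooth
#' warm-up drift plus a small periodic ripple (the density sensor dissipates
#' heat into the stream).
#'
#' @param recipe A [process_recipe()].
#' @param dt Time step (min, default 0.25).
#' @param seed Recorded for provenance (the truth itself is deterministic).
#' @return Data frame of class `ground_truth`: columns `t` (min), `phase`,
#'   `V` (mL), `dv` (cumulative DV within the current DF phase), `c_prot`
#'   (g/L), `T` (sensor temperature, degC), and one `c_<species>` column per
#'   species. Attributes: `recipe`, `dt`, `seed`.
#' @export
simulate_process <- function(recipe, dt = 0.25, seed = NULL) {
  stopifnot(inherits(recipe, "process_recipe"))
  sp <- recipe$species
  n_sp <- nrow(sp)
  Fflow <- recipe$F

  rows <- list()
  t0 <- 0
  V <- recipe$V0
  c_prot <- recipe$protein$c0
  c_sp <- sp$c0
  uf_i <- 0L
  df_i <- 0L

  mk_row <- function(t, phase, V, dv, c_prot, c_sp) {
    r <- data.frame(t = t, phase = phase, V = V, dv = dv, c_prot = c_prot)
    for (j in seq_len(n_sp)) r[[paste0("c_", sp$name[j])]] <- c_sp[j]
    r
  }
  rows[[1]] <- mk_row(0, "start", V, 0, c_prot, c_sp)

  for (ph in recipe$phases) {
    if (ph$kind == "UF") {
      uf_i <- uf_i + 1L
      label <- paste0("UF", uf_i)
      V_end <- V * c_prot / ph$target
      if (V_end <= 0) stop("simulate_process: UF target unreachable (V -> 0)")
      duration <- (V - V_end) / Fflow
      tt <- seq(dt, duration, by = dt)
      if (length(tt) == 0 || tt[length(tt)] < duration - 1e-9)
        tt <- c(tt, duration)
      Vt <- V - Fflow * tt
      cpt <- c_prot * V / Vt
      cst <- vapply(seq_len(n_sp), function(j)
        c_sp[j] * (Vt / V)^(sp$kappa[j] - 1), numeric(length(tt)))
      cst <- matrix(cst, nrow = length(tt))
      for (i in seq_along(tt))
        rows[[length(rows) + 1]] <- mk_row(t0 + tt[i], label, Vt[i], 0,
                                           cpt[i], cst[i, ])
      t0 <- t0 + duration
      V <- V_end
      c_prot <- ph$target
      c_sp <- cst[length(tt), ]
    } else {
      df_i <- df_i + 1L
      label <- paste0("DF", df_i)
      duration <- ph$dv * V / Fflow
      tt <- seq(dt, duration, by = dt)
      if (length(tt) == 0 || tt[length(tt)] < duration - 1e-9)
        tt <- c(tt, duration)
      cst <- matrix(NA_real_, length(tt), n_sp)
      for (j in seq_len(n_sp)) {
        p <- df_params(c_in = sp$c_in[j], F = Fflow, V = V, kappa = sp$kappa[j])
        cst[, j] <- suppressWarnings(df_concentration(c_sp[j], p, tt))
      }
      dvt <- diafiltration_volumes(Fflow, V, tt)
      for (i in seq_along(tt))
        rows[[length(rows) + 1]] <- mk_row(t0 + tt[i], label, V, dvt[i],
                                           c_prot, cst[i, ])
      t0 <- t0 + duration
      c_sp <- cst[length(tt), ]
    }
  }
  truth <- do.call(rbind, rows)
  truth$T <- recipe$T0 + 1.8 * (1 - exp(-truth$t / 12)) +
    0.15 * sin(2 * pi * truth$t / 9.5)
  class(truth) <- c("ground_truth", "data.frame")
  attr(truth, "recipe") <- recipe
  attr(truth, "dt") <- dt
  attr(truth, "seed") <- seed
  truth
}

#' Raman spectral library for the simulator
#'
#' Per-component Gaussian band lists plus the protein-correlated background
#' continuum and the fixed sapphire (probe) bands.
#'
#' @param components Named list; each element a data frame `center` (1/cm),
#'   `width` (Gaussian sigma, 1/cm), `amplitude` (counts/s per concentration
#'   unit). Must contain an element `protein`; other names must match recipe
#'   species.
#' @param background_amp Background continuum amplitude (counts/s per g/L
#'   protein) — emulates concentration-correlated Rayleigh scattering.
#' @param sapphire_amp Amplitude of the fixed sapphire bands (counts/s).
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(components, background_amp = 5,
                             sapphire_amp = 400) {
  stopifnot(is.list(components), "protein" %in% names(components))
  for (nm in names(components)) {
    b <- components[[nm]]
    if (!all(c("center", "width", "amplitude") %in% names(b)))
      stop("spectral_library: component '", nm,
           "' needs center, width, amplitude")
    if (any(b$amplitude < 0)) stop("spectral_library: amplitudes must be >= 0")
  }
  structure(list(components = components, background_amp = background_amp,
                 sapphire_amp = sapphire_amp), class = "spectral_library")
}

.gauss_profile <- function(axis, bands, scale = 1) {
  out <- numeric(length(axis))
  for (i in seq_len(nrow(bands)))
    out <- out + bands$amplitude[i] * scale *
      exp(-(axis - bands$center[i])^2 / (2 * bands$width[i]^2))
  out
}

# Sapphire bands of the ball probe (positions fixed, intensities constant).
.SAPPHIRE <- data.frame(center = c(384, 418, 452, 753),
                        width = c(6, 6, 6, 8),
                        amplitude = c(1, 0.8, 0.6, 0.9))

#' Synthesize a Raman acquisition from ground truth
#'
#' Builds count-rate spectra as the sum of concentration-scaled Gaussian
#' component bands, a smooth background continuum proportional to the
#' protein concentration, fixed sapphire bands and a broad water band;
#' multiplies by the exposure to get counts; and adds shot-like
#' heteroscedastic noise (sigma proportional to sqrt(counts)). Whenever the
#' noiseless maximum count would exceed the detector saturation limit the
#' exposure time is halved (step-wise, never raised again), mimicking the
#' acquisition logic used with strongly scattering feeds. Optional bubble
#' artifacts replace single spectra with a broad distorted hump.
#'
#' @param truth A [simulate_process()] result.
#' @param library A [spectral_library()].
#' @param noise_level Shot-noise scale (0 = noiseless; default 1).
#' @param saturation_limit Detector full scale (counts, default 6e4).
#' @param exposure0_ms Initial exposure time (ms, default 800).
#' @param accumulations Acquisitions per spectrum (default 10).
#' @param axis Wavenumber axis (default 300-3100 1/cm at 2 1/cm).
#' @param bubble_rate Per-spectrum probability of a bubble artifact.
#' @param seed RNG seed (deterministic output for a given seed).
#' @return A [spectrum_series()] (counts) with attributes `exposure_events`
#'   (data frame of step-downs) and `artifact_log` (indices of injected
#'   bubble spectra).
#' @export
synthesize_raman <- function(truth, library, noise_level = 1,
                             saturation_limit = 6e4, exposure0_ms = 800,
                             accumulations = 10,
                             axis = seq(300, 3100, by = 2),
                             bubble_rate = 0, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(library, "spectral_library"))
  if (min(axis) > 300 || max(axis) < 3100 || max(diff(axis)) > 2)
    stop("synthesize_raman: axis must cover 300-3100 1/cm at >= 2 1/cm resolution")
  set.seed(seed)
  n <- nrow(truth)
  m <- length(axis)

  profiles <- lapply(library$components, function(b) .gauss_profile(axis, b))
  background <- library$background_amp * (exp(-(axis - 300) / 1200) + 0.3)
  fixed <- library$sapphire_amp * .gauss_profile(axis, .SAPPHIRE) +
    250 * exp(-(axis - 1640)^2 / (2 * 90^2)) + 60   # water band + offset

  rate <- matrix(rep(fixed, each = n), n, m)
  rate <- rate + truth$c_prot %o% (profiles$protein + background)
  for (nm in setdiff(names(profiles), "protein")) {
    col <- paste0("c_", nm)
    if (!col %in% names(truth))
      stop("synthesize_raman: library component '", nm, "' not in ground truth")
    rate <- rate + truth[[col]] %o% profiles[[nm]]
  }

  exposure_ms <- numeric(n)
  expo <- exposure0_ms
  events <- list()
  for (i in seq_len(n)) {
    while (max(rate[i, ]) * (expo / 1000) * accumulations > saturation_limit &&
           expo > 1) {
      expo <- expo / 2
      events[[length(events) + 1]] <- data.frame(index = i, t = truth$t[i],
                                                 exposure_ms = expo)
    }
    exposure_ms[i] <- expo
  }

  counts <- rate * (exposure_ms / 1000) * accumulations
  if (noise_level > 0) {
    counts <- counts + matrix(stats::rnorm(n * m), n, m) *
      sqrt(pmax(counts, 1)) * noise_level
    counts[counts < 0] <- 0
  }

  artifact_idx <- integer(0)
  if (bubble_rate > 0) {
    hit <- stats::runif(n) < bubble_rate
    artifact_idx <- which(hit)
    for (i in artifact_idx) {
      lift <- 0.5 * max(counts[i, ]) *
        exp(-(axis - stats::runif(1, 600, 1400))^2 / (2 * 350^2))
      counts[i, ] <- counts[i, ] * stats::runif(1, 0.4, 0.7) + lift
    }
  }

  out <- spectrum_series(axis, counts, exposure_ms, truth$t,
                         accumulations = accumulations, unit = "counts")
  attr(out, "exposure_events") <-
    if (length(events)) do.call(rbind, events)
    else data.frame(index = integer(0), t = numeric(0), exposure_ms = numeric(0))
  attr(out, "artifact_log") <- artifact_idx
  out
}

#' Synthesize a density-sensor stream from ground truth
#'
#' True density at the standard temperature is water plus linear solute
#' increments plus the protein term `a_prot * c_prot`; the measured value is
#' mapped to the (drifting) sensor temperature by inverse cross-
#' multiplication, with Gaussian sensor noise and optional downward bubble
#' spikes (air lowers the apparent liquid density).
#'
#' @param truth A [simulate_process()] result.
#' @param a_prot Protein density increment (g/L per g/L).
#' @param drho Named vector of density increments per species concentration
#'   unit (names matching recipe species); defaults to the recipe's.
#' @param noise_sd Sensor noise sd (g/L, default 0.05).
#' @param bubble_rate Per-reading artifact probability.
#' @param seed RNG seed.
#' @return Data frame: `t`, `value` (measured density, g/L), `temperature`
#'   (degC). Attributes: `artifact_log` (indices), `rho_buffer_T0` (true
#'   protein-free density at `T0`), `T0`.
#' @export
synthesize_density <- function(truth, a_prot = NULL, drho = NULL,
                               noise_sd = 0.05, bubble_rate = 0, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  recipe <- attr(truth, "recipe")
  if (is.null(a_prot)) a_prot <- recipe$protein$a_prot
  if (is.null(drho)) drho <- stats::setNames(recipe$species$drho,
                                             recipe$species$name)
  set.seed(seed)
  T0 <- recipe$T0
  rho_buffer <- rep(water_density(T0), nrow(truth))
  for (nm in names(drho)) rho_buffer <- rho_buffer + truth[[paste0("c_", nm)]] * drho[[nm]]
  rho_T0 <- rho_buffer + a_prot * truth$c_prot
  rho_meas <- rho_T0 * water_density(truth$T) / water_density(T0)
  if (noise_sd > 0) rho_meas <- rho_meas + stats::rnorm(nrow(truth), 0, noise_sd)
  artifact_idx <- integer(0)
  if (bubble_rate > 0) {
    hit <- stats::runif(nrow(truth)) < bubble_rate
    artifact_idx <- which(hit)
    rho_meas[artifact_idx] <- rho_meas[artifact_idx] -
      stats::runif(length(artifact_idx), 1.5, 8)
  }
  out <- data.frame(t = truth$t, value = rho_meas, temperature = truth$T)
  attr(out, "artifact_log") <- artifact_idx
  attr(out, "rho_buffer_T0") <- rho_buffer
  attr(out, "T0") <- T0
  out
}

#' Synthesize a UV-absorbance stream from ground truth
#'
#' Beer-Lambert absorbance at 280 nm with Gaussian noise; the per-reading
#' slope-regression quality `r2` sits near 1 with occasional dips below the
#' 0.97 acceptance threshold to exercise the quality filter.
#'
#' @param truth A [simulate_process()] result.
#' @param extinction Extinction coefficient (AU L / (g cm)); defaults to the
#'   recipe's.
#' @param pathlength Pathlength (cm, default 1).
#' @param noise_sd Absorbance noise sd (AU, default 0.005).
#' @param dip_rate Probability of a low-quality reading (default 0.02).
#' @param seed RNG seed.
#' @return Data frame `t`, `A280`, `r2`; attribute `dip_log` (indices of
#'   injected low-quality readings).
#' @export
synthesize_uv <- function(truth, extinction = NULL, pathlength = 1,
                          noise_sd = 0.005, dip_rate = 0.02, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  recipe <- attr(truth, "recipe")
  if (is.null(extinction)) extinction <- recipe$protein$extinction
  if (extinction <= 0) stop("synthesize_uv: extinction must be > 0")
  set.seed(seed)
  n <- nrow(truth)
  A <- extinction * pathlength * truth$c_prot
  if (noise_sd > 0) A <- pmax(A + stats::rnorm(n, 0, noise_sd), 0)
  r2 <- pmin(1 - abs(stats::rnorm(n, 0, 0.003)), 1)
  dips <- which(stats::runif(n) < dip_rate)
  r2[dips] <- stats::runif(length(dips), 0.85, 0.969)
  out <- data.frame(t = truth$t, A280 = A, r2 = r2)
  attr(out, "dip_log") <- dips
  out
}

#' Case-study presets for the simulator
#'
#' Recipes and spectral libraries shaped after three typical UF/DF runs:
#' * `"lysozyme"` — 10 to 20 g/L UF, citrate-to-phosphate DF over 4 DV,
#'   final UF to 40 g/L; strong protein bands, moderate background.
#' * `"mab"` — 2.79 to 25 g/L UF, 8 DV into glycine/histidine buffer, final
#'   UF to about 100 g/L; dominant concentration-correlated background and
#'   an initial 1200 ms exposure that steps down as the background grows
#'   (histidine contributes no distinct bands).
#' * `"bsab"` — 11.49 to 25 g/L UF, 8 DV into dilute phosphate/TRIS, final
#'   UF to about 80 g/L; includes a depleting process-related impurity with
#'   bands at 881 and 930 1/cm as a PCA confounder.
#'
#' Permeate flow (4.5 mL/min), initial volumes, extinction coefficients and
#' density increments are plausible working values, not measured ones.
#'
#' @param name `"lysozyme"`, `"mab"` or `"bsab"`.
#' @return List with elements `recipe` ([process_recipe()]), `library`
#'   ([spectral_library()]), `exposure0_ms`, and `pathlength`.
#' @export
ufdf_preset <- function(name = c("lysozyme", "mab", "bsab")) {
  name <- match.arg(name)
  band <- function(center, width, amplitude)
    data.frame(center = center, width = width, amplitude = amplitude)
  protein_bands <- band(c(1006, 1360, 1448, 1549, 2942),
                        c(8, 12, 12, 14, 20), c(6, 3.5, 4.5, 3, 8))
  switch(name,
    lysozyme = list(
      recipe = process_recipe(
        name = "lysozyme",
        phases = list(list(kind = "UF", target = 20),
                      list(kind = "DF", dv = 4),
                      list(kind = "UF", target = 40)),
        F = 4.5, V0 = 90,
        species = data.frame(
          name = c("citrate", "phosphate"),
          c0 = c(50, 0), c_in = c(0, 50), kappa = c(1, 1),
          drho = c(0.075, 0.055)),
        protein = list(name = "lysozyme", c0 = 10, extinction = 2.64,
                       a_prot = 0.27)),
      library = spectral_library(
        components = list(
          protein = transform(protein_bands, amplitude = amplitude * 2),
          citrate = band(c(840, 952, 1412), c(9, 9, 10), c(1.2, 2.5, 1.8)),
          phosphate = band(c(877, 990, 1078), c(8, 8, 9), c(0.6, 2.2, 0.8))),
        background_amp = 8, sapphire_amp = 400),
      exposure0_ms = 800, pathlength = 1),
    mab = list(
      recipe = process_recipe(
        name = "mab",
        phases = list(list(kind = "UF", target = 25),
                      list(kind = "DF", dv = 8),
                      list(kind = "UF", target = 100)),
        F = 4.5, V0 = 200,
        species = data.frame(
          name = c("glycine", "histidine", "stock_salt"),
          c0 = c(0, 0, 140), c_in = c(250, 25, 0), kappa = c(1, 1, 1),
          drho = c(0.0031, 0.009, 0.042)),
        protein = list(name = "mab", c0 = 2.79, extinction = 1.45,
                       a_prot = 0.26)),
      library = spectral_library(
        components = list(
          protein = protein_bands,
          glycine = band(c(899, 1332, 1413, 1446, 2972),
                         c(8, 9, 9, 9, 14), c(0.45, 0.3, 0.32, 0.12, 0.5)),
          # histidine omitted: 10-fold lower concentration, no visible bands
          stock_salt = band(1048, 9, 0.35)),
        background_amp = 55, sapphire_amp = 400),
      exposure0_ms = 1200, pathlength = 1),
    bsab = list(
      recipe = process_recipe(
        name = "bsab",
        phases = list(list(kind = "UF", target = 25),
                      list(kind = "DF", dv = 8),
                      list(kind = "UF", target = 80)),
        F = 4.5, V0 = 100,
        species = data.frame(
          name = c("impurity", "tris", "phosphate"),
          c0 = c(8, 30, 0), c_in = c(0, 1.3, 2.2), kappa = c(1, 1, 1),
          drho = c(0.05, 0.012, 0.055)),
        protein = list(name = "bsab", c0 = 11.49, extinction = 1.6,
                       a_prot = 0.255)),
      library = spectral_library(
        components = list(
          protein = transform(protein_bands, amplitude = amplitude * 0.9),
          impurity = band(c(881, 930), c(8, 8), c(1.4, 1.1)),
          tris = band(c(1066, 1470), c(9, 10), c(0.05, 0.06)),
          phosphate = band(c(877, 990, 1078), c(8, 8, 9),
                           c(0.02, 0.07, 0.025))),
        background_amp = 18, sapphire_amp = 400),
      exposure0_ms = 800, pathlength = 1))
}
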