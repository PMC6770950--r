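#' Kinetic parameters of a simulated renneting batch
#'
#' Parameterizes the three-phase coagulation kinetics used by the
#' synthetic-data generator: a liquid phase that decays as milk destabilizes,
#' a transient aggregation phase that rises and falls around the sol-gel
#' transition, and a gel phase that grows to a plateau.
#'
#' The three concentration profiles are built from two logistic sigmoids with
#' a common time scale `steepness`, centred `pulse_width / 2` minutes before
#' and after `transition_time`. The transition-phase pulse is the difference
#' of the two sigmoids, so it peaks exactly at `transition_time`. When
#' `transition_amplitude` is left `NULL` it defaults to the natural height of
#' that difference, in which case the three phase fractions sum exactly to
#' one at every time point (mass-balance closure). Supplying an explicit
#' amplitude rescales the pulse and breaks exact closure, as do faults.
#'
#' @param transition_time Centre of the sol-gel transition, minutes,
#'   in (0, 30).
#' @param steepness Time scale of the phase changes, minutes, > 0.
#' @param transition_amplitude Peak height of the transition-phase pulse,
#'   in (0, 1], or `NULL` for the closure-preserving default.
#' @param pulse_width Separation (minutes) between the liquid-phase decay
#'   midpoint and the gel-phase rise midpoint, > 0.
#' @param gel_plateau Asymptotic level of the gel-phase profile, in (0, 1].
#'   Reduced by the weak-gel fault archetypes.
#' @return An object of class `kinetic_params`.
#' @seealso [make_concentration_profiles()], [apply_fault()]
#' @examples
#' kp <- kinetic_params(transition_time = 7)
#' kp$transition_amplitude
#' @export
kinetic_params <- function(transition_time = 7,
                           steepness = 1,
                           transition_amplitude = NULL,
                           pulse_width = 5,
                           gel_plateau = 1) {
  check_number(transition_time, "transition_time", 0, 30,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(steepness, "steepness", 0, Inf, closed_lower = FALSE)
  check_number(pulse_width, "pulse_width", 0, Inf, closed_lower = FALSE)
  check_number(gel_plateau, "gel_plateau", 0, 1, closed_lower = FALSE)
  natural <- 2 * stats::plogis(pulse_width / (2 * steepness)) - 1
  if (is.null(transition_amplitude)) {
    transition_amplitude <- natural
  }
  check_number(transition_amplitude, "transition_amplitude", 0, 1,
               closed_lower = FALSE)
  structure(
    list(
      transition_time = transition_time,
      steepness = steepness,
      transition_amplitude = transition_amplitude,
      pulse_width = pulse_width,
      gel_plateau = gel_plateau
    ),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  transition_time: %.3g min\n", x$transition_time))
  cat(sprintf("  steepness:       %.3g min\n", x$steepness))
  cat(sprintf("  amplitude:       %.3g\n", x$transition_amplitude))
  cat(sprintf("  pulse_width:     %.3g min\n", x$pulse_width))
  cat(sprintf("  gel_plateau:     %.3g\n", x$gel_plateau))
  invisible(x)
}

#' Specify a coagulation fault archetype
#'
#' Three fault archetypes are supported, mirroring deliberate process
#' failures in rennet coagulation experiments: `half_rennet` (half the
#' enzyme dose: delayed, weaker transition), `heating_off` (vat heating
#' switched off after rennet addition: slowed kinetics throughout), and
#' `half_cacl2` (half the calcium chloride dose: delayed transition and a
#' weaker final gel).
#'
#' @param kind One of `"half_rennet"`, `"heating_off"`, `"half_cacl2"`.
#' @param severity Fault severity in (0, 1]; 0 is the no-fault limit.
#' @param onset Minutes after batch start at which the fault takes effect,
#'   in \[0, 30\]. A late onset attenuates the effect proportionally.
#' @return An object of class `fault_spec`.
#' @export
fault_spec <- function(kind = c("half_rennet", "heating_off", "half_cacl2"),
                       severity = 0.5, onset = 0) {
  kind <- match.arg(kind)
  check_number(severity, "severity", 0, 1)
  check_number(onset, "onset", 0, 30)
  structure(list(kind = kind, severity = severity, onset = onset),
            class = "fault_spec")
}

#' Apply a fault archetype to batch kinetics
#'
#' Transforms in-control kinetic parameters into faulted ones. The scaling
#' rules are part of this generator's contract (they are phenomenological,
#' not fitted to any instrument):
#'
#' * `half_rennet`: `transition_time` scaled by `1 + 0.6 s`,
#'   `transition_amplitude` by `1 - 0.5 s`, `steepness` by `1 + 0.5 s`,
#'   `gel_plateau` by `1 - 0.4 s` (less cleaved casein gives a delayed,
#'   weaker transition and a weaker final network);
#' * `heating_off`: `transition_time` scaled by `1 + 0.8 s`,
#'   `steepness` by `1 + 2 s`, `gel_plateau` by `1 - 0.5 s` (cooling milk
#'   slows every phase and sets a poor gel);
#' * `half_cacl2`: `transition_time` scaled by `1 + 0.6 s`,
#'   `transition_amplitude` by `1 - 0.6 s`, `gel_plateau` by `1 - 0.5 s`
#'   (calcium-starved aggregation is slower and the network weaker);
#'
#' where `s = severity * (1 - onset / 30)` is the onset-attenuated severity.
#' At the default in-control transition time (7 min) every archetype at
#' severity 0.5 shifts the transition-phase peak by more than 2 minutes,
#' which is what makes the faults detectable by the downstream control
#' charts. At severity 0 the parameters are returned unchanged.
#'
#' @param kinetics A [kinetic_params()] object.
#' @param fault A [fault_spec()] object.
#' @return A `kinetic_params` object with the fault applied.
#' @export
apply_fault <- function(kinetics, fault) {
  stopifnot(inherits(kinetics, "kinetic_params"), inherits(fault, "fault_spec"))
  s <- fault$severity * (1 - fault$onset / 30)
  k <- kinetics
  if (fault$kind == "half_rennet") {
    k$transition_time <- kinetics$transition_time * (1 + 0.6 * s)
    k$transition_amplitude <- kinetics$transition_amplitude * (1 - 0.5 * s)
    k$steepness <- kinetics$steepness * (1 + 0.5 * s)
    k$gel_plateau <- kinetics$gel_plateau * (1 - 0.4 * s)
  } else if (fault$kind == "heating_off") {
    k$transition_time <- kinetics$transition_time * (1 + 0.8 * s)
    k$steepness <- kinetics$steepness * (1 + 2 * s)
    k$gel_plateau <- kinetics$gel_plateau * (1 - 0.5 * s)
  } else if (fault$kind == "half_cacl2") {
    k$transition_time <- kinetics$transition_time * (1 + 0.6 * s)
    k$transition_amplitude <- kinetics$transition_amplitude * (1 - 0.6 * s)
    k$gel_plateau <- kinetics$gel_plateau * (1 - 0.5 * s)
  } else {
    abort_bad_arg(sprintf("Unknown fault kind '%s'.", fault$kind))
  }
  k$transition_time <- min(k$transition_time, 29.5)
  kinetic_params(
    transition_time = k$transition_time,
    steepness = k$steepness,
    transition_amplitude = k$transition_amplitude,
    pulse_width = k$pulse_width,
    gel_plateau = k$gel_plateau
  )
}

#' Concentration profiles of the three coagulation phases
#'
#' Evaluates the three phase-fraction profiles on a time grid: a decreasing
#' logistic (liquid milk), a unimodal pulse peaking at the transition time
#' (casein aggregation), and an increasing logistic (gel network). All
#' entries lie in \[0, 1\] and each column has a single local maximum.
#'
#' @param kinetics A [kinetic_params()] object.
#' @param times Strictly increasing acquisition times in minutes,
#'   length >= 5.
#' @return An `M x 3` matrix with columns `liquid`, `transition`, `gel`.
#' @examples
#' C <- make_concentration_profiles(kinetic_params(transition_time = 7), 1:30)
#' which.max(C[, "transition"])
#' @export
make_concentration_profiles <- function(kinetics, times) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  if (length(times) < 5L || any(diff(times) <= 0)) {
    abort_bad_arg("`times` must be strictly increasing with length >= 5.")
  }
  tt <- kinetics$transition_time
  s <- kinetics$steepness
  delta <- kinetics$pulse_width / 2
  sig1 <- stats::plogis((times - (tt - delta)) / s)
  sig3 <- stats::plogis((times - (tt + delta)) / s)
  natural <- 2 * stats::plogis(delta / s) - 1
  pulse <- (kinetics$transition_amplitude / natural) * (sig1 - sig3)
  C <- cbind(
    liquid = 1 - sig1,
    transition = pmin(pulse, 1),
    gel = kinetics$gel_plateau * sig3
  )
  rownames(C) <- NULL
  C
}

#' Default instrument wavenumber grid
#'
#' The working spectral grid: 1730 evenly spaced wavenumbers spanning
#' 12,500 down to 5,824 cm^-1 (spacing about 3.86 cm^-1). With
#' `full = TRUE` the grid is extended at the same spacing down to about
#' 4,000 cm^-1, emulating the raw instrument range before the noisy
#' low-wavenumber region is discarded by [reduce_range()].
#'
#' @param full Extend the grid down to ~4,000 cm^-1.
#' @return Numeric vector of wavenumbers in decreasing order.
#' @export
default_wavenumber_grid <- function(full = FALSE) {
  step <- (12500 - 5824) / 1729
  n <- if (full) 2201L else 1730L
  12500 - step * (seq_len(n) - 1)
}

#' Simulated pure-component spectral profiles
#'
#' Builds three non-negative near-infrared spectral profiles as sums of
#' Gaussian bands. Every component has bands near the three diagnostic
#' positions of coagulating milk spectra — 6,900 cm^-1 (O-H stretching of
#' water), 8,600 and 10,800 cm^-1 (C-H of lipids) — with
#' component-specific amplitudes and widths (plus small seeded jitter), so
#' the profiles overlap heavily yet stay linearly independent.
#'
#' @param grid Wavenumber grid (cm^-1); must cover the three band centres
#'   and stay within roughly 3,500-13,500 cm^-1.
#' @param seed Integer seed fixing the band jitter; same seed, identical
#'   output.
#' @return A `3 x N` non-negative matrix, rows `liquid`, `transition`,
#'   `gel`.
#' @export
make_spectral_profiles <- function(grid = default_wavenumber_grid(),
                                   seed = 0L) {
  if (min(grid) < 3500 || max(grid) > 13500) {
    abort_bad_arg("`grid` has wavenumbers outside the supported 3,500-13,500 cm^-1 range.")
  }
  if (min(grid) > 6500 || max(grid) < 11200) {
    abort_bad_arg("`grid` must cover the 6,900, 8,600 and 10,800 cm^-1 band positions.")
  }
  centers <- c(6900, 8600, 10800)
  # base band amplitudes per component (rows) and band (cols)
  amp <- rbind(
    liquid = c(1.00, 0.25, 0.35),
    transition = c(0.75, 0.45, 0.15),
    gel = c(0.55, 0.70, 0.50)
  )
  wid <- rbind(
    liquid = c(260, 350, 420),
    transition = c(320, 280, 380),
    gel = c(230, 330, 300)
  )
  shift <- rbind(
    liquid = c(0, 0, 0),
    transition = c(60, -40, 30),
    gel = c(-50, 45, -35)
  )
  with_seed(seed, {
    jit_amp <- matrix(stats::runif(9, 0.9, 1.1), 3, 3)
    jit_shift <- matrix(stats::runif(9, -15, 15), 3, 3)
  })
  S <- matrix(0, nrow = 3, ncol = length(grid),
              dimnames = list(rownames(amp), NULL))
  for (f in 1:3) {
    for (b in 1:3) {
      mu <- centers[b] + shift[f, b] + jit_shift[f, b]
      S[f, ] <- S[f, ] +
        amp[f, b] * jit_amp[f, b] * exp(-0.5 * ((grid - mu) / wid[f, b])^2)
    }
  }
  sv <- svd(S, nu = 0, nv = 0)$d
  if (sv[3] <= 1e-6 * sv[1]) {
    abort_bad_arg("Generated spectral profiles are numerically dependent; change the seed.")
  }
  S
}

#' Ground truth for a simulated batch
#'
#' Bundles the true concentration and spectral profiles of the bilinear
#' model `D = C S^T + E` together with the noise level, for use by
#' [simulate_batch()] and by recovery tests.
#'
#' @param kinetics A [kinetic_params()] object.
#' @param times Acquisition times in minutes (default 1..30, one spectrum
#'   per minute).
#' @param grid Wavenumber grid, see [default_wavenumber_grid()].
#' @param noise_sd Standard deviation of the additive i.i.d. Gaussian
#'   absorbance noise (default 0.003 absorbance units, placing simulated
#'   residuals in the range reported for well-fit renneting spectra).
#' @param spectra_seed Seed passed to [make_spectral_profiles()].
#' @return An object of class `ground_truth` with elements `C_true`
#'   (`M x 3`), `S_true` (`3 x N`), `times`, `wavenumbers`, `noise_sd`,
#'   `kinetics`.
#' @export
ground_truth <- function(kinetics = kinetic_params(),
                         times = 1:30,
                         grid = default_wavenumber_grid(),
                         noise_sd = 0.003,
                         spectra_seed = 0L) {
  check_number(noise_sd, "noise_sd", 0, Inf)
  C <- make_concentration_profiles(kinetics, times)
  S <- make_spectral_profiles(grid, seed = spectra_seed)
  structure(
    list(C_true = C, S_true = S, times = times, wavenumbers = grid,
         noise_sd = noise_sd, kinetics = kinetics),
    class = "ground_truth"
  )
}

#' Simulate one renneting batch
#'
#' Realizes the bilinear model `D = C_true S_true + E` with i.i.d. zero-mean
#' Gaussian noise of standard deviation `truth$noise_sd`. The returned batch
#' carries the seed, kinetics and fault specification in its metadata so a
#' run can be replayed exactly.
#'
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed for the noise realization.
#' @param batch_id Optional batch identifier stored in metadata.
#' @param fault Optional [fault_spec()] recorded in metadata (the fault must
#'   already be applied to the kinetics via [apply_fault()]).
#' @param meta Optional named list of extra metadata (temperature, pH, fat).
#' @return A [spectral_batch()] object.
#' @export
simulate_batch <- function(truth, seed = 1L, batch_id = "batch",
                           fault = NULL, meta = list()) {
  stopifnot(inherits(truth, "ground_truth"))
  if (ncol(truth$C_true) != nrow(truth$S_true)) {
    abort_bad_arg("`C_true` and `S_true` have incompatible inner dimensions.")
  }
  D0 <- truth$C_true %*% truth$S_true
  E <- if (truth$noise_sd > 0) {
    with_seed(seed, matrix(stats::rnorm(length(D0), 0, truth$noise_sd),
                           nrow(D0), ncol(D0)))
  } else {
    matrix(0, nrow(D0), ncol(D0))
  }
  meta <- c(
    list(batch_id = batch_id, seed = seed, noise_sd = truth$noise_sd,
         kinetics = truth$kinetics, fault = fault),
    meta
  )
  spectral_batch(times = truth$times, wavenumbers = truth$wavenumbers,
                 absorbance = D0 + E, meta = meta)
}

#' Simulate a rheological time-curing curve
#'
#' Generates elastic-modulus readings from the logistic growth model
#' `G'(t) = a / (1 + exp(-(t - b) / c))` plus Gaussian noise. The viscous
#' modulus is generated as a smaller, slightly delayed logistic of the same
#' shape, which is enough to exercise curve handling (only G' is modelled
#' downstream).
#'
#' @param fit A [sigmoid_params()] (or fitted [fit_sigmoid()]) object with
#'   elements `a` (plateau, Pa), `b` (midpoint, min), `c` (time scale, min).
#' @param times Measurement times in minutes.
#' @param noise_sd Noise standard deviation in Pa.
#' @param seed Integer seed.
#' @return A tibble of class `rheology_curve` with columns `time_min`,
#'   `g_prime`, `g_double_prime`.
#' @export
simulate_rheology <- function(fit, times = 1:30, noise_sd = 0, seed = 1L) {
  a <- fit$a; b <- fit$b; cc <- fit$c
  check_number(a, "a", 0, Inf, closed_lower = FALSE)
  if (!is.numeric(cc) || length(cc) != 1L || cc == 0) {
    abort_bad_arg("`c` must be a nonzero time scale.")
  }
  check_number(noise_sd, "noise_sd", 0, Inf)
  g1 <- a / (1 + exp(-(times - b) / cc))
  g2 <- 0.35 * a / (1 + exp(-(times - b - 1) / cc))
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(2 * length(times), 0, noise_sd), ncol = 2))
    g1 <- g1 + noise[, 1]
    g2 <- g2 + noise[, 2]
  }
  out <- tibble::tibble(time_min = as.numeric(times), g_prime = g1,
                        g_double_prime = g2)
  class(out) <- c("rheology_curve", class(out))
  out
}

#' Logistic growth parameters
#'
#' Light-weight container for the three parameters of the logistic
#' time-curing model `y = a / (1 + exp(-(x - b) / c))`, used both to
#' simulate rheology and as the result of [fit_sigmoid()].
#'
#' @param a Plateau (Pa), > 0.
#' @param b Midpoint time (min).
#' @param c Time scale (min), nonzero; positive for a growing curve.
#' @return An object of class `sigmoid_fit`.
#' @export
sigmoid_params <- function(a, b, c) {
  check_number(a, "a", 0, Inf, closed_lower = FALSE)
  check_number(b, "b")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c == 0) {
    abort_bad_arg("`c` must be a single nonzero number.")
  }
  structure(list(a = a, b = b, c = c, rss = NA_real_, n = NA_integer_),
            class = "sigmoid_fit")
}

#' Illustrative mapping from operating conditions to kinetics
#'
#' Maps vat temperature, milk pH and fat content onto kinetic parameters.
#' No quantitative kinetic law links these operating conditions to
#' coagulation timing, so the mapping is illustrative: warmer, more acidic,
#' leaner milk coagulates faster, with effect sizes chosen to spread
#' transition times over roughly 5-17 minutes across the usual
#' cheese-making ranges (30-40 degC, pH 6.3-6.7, fat 0.1-5 g/100 mL).
#'
#' @param temperature_c Coagulation temperature, degrees Celsius.
#' @param ph Milk pH.
#' @param fat Fat content, g/100 mL.
#' @return A [kinetic_params()] object.
#' @export
kinetics_from_conditions <- function(temperature_c = 35, ph = 6.5,
                                     fat = 2.55) {
  tt <- 7 + 0.45 * (35 - temperature_c) + 14 * (ph - 6.5) + 0.12 * (fat - 2.55)
  st <- 1 + 0.03 * (35 - temperature_c) + 0.8 * (ph - 6.5)
  kinetic_params(
    transition_time = clamp(tt, 4, 18),
    steepness = clamp(st, 0.6, 2.5)
  )
}
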