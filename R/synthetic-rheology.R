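# Seeded generators for rheometer inputs. Every generator returns its
# ground truth in the "truth" attribute and takes one explicit seed; the
# caller's RNG state is never touched (withr::with_seed).

#' Parameters for a synthetic gelation time sweep
#'
#' @param crossover_time target gel point (G' = G'' crossing), minutes > 0.
#' @param Gp_plateau,Gpp_plateau long-time storage/loss moduli, Pa > 0.
#'   `Gp_plateau <= Gpp_plateau` describes a material that never gels.
#' @param rise_timescale saturation timescale of G', minutes > 0.
#' @param noise_sd_rel sd of multiplicative log-normal noise, >= 0.
#' @param seed integer seed.
#' @return a `gelation_params` list.
#' @export
gelation_params <- function(crossover_time, Gp_plateau = 1000,
                            Gpp_plateau = 300,
                            rise_timescale = crossover_time / 3,
                            noise_sd_rel = 0, seed = 1L) {
  if (crossover_time <= 0) stop("crossover_time must be > 0")
  if (Gp_plateau <= 0 || Gpp_plateau <= 0) stop("plateau moduli must be > 0")
  if (rise_timescale <= 0) stop("rise_timescale must be > 0")
  if (noise_sd_rel < 0) stop("noise_sd_rel must be >= 0")
  structure(list(crossover_time = crossover_time, Gp_plateau = Gp_plateau,
                 Gpp_plateau = Gpp_plateau, rise_timescale = rise_timescale,
                 noise_sd_rel = noise_sd_rel, seed = as.integer(seed)),
            class = "gelation_params")
}

#' Simulate a gelation time sweep
#'
#' Phenomenological crosslinking kinetics: G' rises as a saturating
#' exponential toward `Gp_plateau` while the loss tangent decays
#' monotonically on a log scale from 10 at t = 0 toward
#' `Gpp_plateau / Gp_plateau`, with its decay timescale solved so that
#' tan delta = 1 (the G'-G'' crossover) falls exactly at
#' `crossover_time`. The construction guarantees exactly one crossing in
#' any window containing the crossover; when `Gp_plateau <= Gpp_plateau`
#' the loss tangent never drops below one and no crossing exists.
#'
#' @param params a [gelation_params()].
#' @param sampling strictly increasing time grid, minutes, >= 10 points.
#' @return a [rheo_sweep()] (`time_sweep`) with attribute `truth = params`.
#' @export
simulate_gelation_timesweep <- function(params, sampling) {
  stopifnot(inherits(params, "gelation_params"))
  t <- as.numeric(sampling)
  if (length(t) < 10L) stop("time grid must have at least 10 points")
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing")
  if (any(t < 0)) stop("time grid must be non-negative")

  r0 <- 0.01                                # G'(0) / Gp_plateau
  Gp <- params$Gp_plateau * (1 - (1 - r0) * exp(-t / params$rise_timescale))
  L0 <- log(10)                             # tan delta at t = 0
  Linf <- log(params$Gpp_plateau / params$Gp_plateau)
  if (Linf < 0) {
    # decay timescale so log tan delta crosses 0 exactly at crossover_time
    tau2 <- params$crossover_time / log((L0 - Linf) / (-Linf))
    logtan <- Linf + (L0 - Linf) * exp(-t / tau2)
  } else {
    # never-gelling material: tan delta stays >= 1 for all t
    logtan <- Linf + (L0 - Linf) * exp(-t / params$rise_timescale)
  }
  Gpp <- Gp * exp(logtan)

  if (params$noise_sd_rel > 0) {
    withr::with_seed(params$seed, {
      Gp <- Gp * exp(stats::rnorm(length(t), 0, params$noise_sd_rel))
      Gpp <- Gpp * exp(stats::rnorm(length(t), 0, params$noise_sd_rel))
    })
  }
  out <- rheo_sweep("time_sweep", t, Gp, Gpp, temperature = 25)
  attr(out, "truth") <- params
  out
}

#' Parameters for a synthetic yield-stress amplitude sweep
#'
#' @param sigma_y stress amplitude where G' = G'', Pa > 0.
#' @param Gp0,Gpp0 low-amplitude (LVE) plateau moduli, Pa; `Gpp0 < Gp0`
#'   is required (a solid at rest).
#' @param stress_grid log-spaced stress amplitudes, Pa. The default spans
#'   0.1 Pa to `max(100, 2 * sigma_y)` Pa so yield points above the
#'   nominal 0.1-100 Pa protocol range remain in-window.
#' @param noise_sd_rel sd of multiplicative log-normal noise, >= 0.
#' @param seed integer seed.
#' @return a `yield_sweep_params` list.
#' @export
yield_sweep_params <- function(sigma_y, Gp0 = 1000, Gpp0 = 100,
                               stress_grid = NULL, noise_sd_rel = 0,
                               seed = 1L) {
  if (sigma_y <= 0) stop("sigma_y must be > 0")
  if (Gp0 <= 0 || Gpp0 <= 0) stop("plateau moduli must be > 0")
  if (Gpp0 >= Gp0) stop("Gpp0 must be below Gp0 (solid regime at rest)")
  if (is.null(stress_grid))
    stress_grid <- exp(seq(log(0.1), log(max(100, 2 * sigma_y)), length.out = 60))
  stress_grid <- as.numeric(stress_grid)
  if (any(stress_grid <= 0) || any(diff(stress_grid) <= 0))
    stop("stress_grid must be positive and strictly increasing")
  if (sigma_y <= min(stress_grid) || sigma_y >= max(stress_grid))
    stop("sigma_y must lie strictly inside the stress grid")
  structure(list(sigma_y = sigma_y, Gp0 = Gp0, Gpp0 = Gpp0,
                 stress_grid = stress_grid, noise_sd_rel = noise_sd_rel,
                 seed = as.integer(seed)),
            class = "yield_sweep_params")
}

#' Simulate a yielding amplitude sweep
#'
#' G' decays logistically with stress amplitude while the loss tangent
#' follows a power law in stress, equal to `Gpp0/Gp0` at the lowest grid
#' stress and exactly 1 at `sigma_y`. Hence G' > G'' strictly below the
#' yield point and G'' > G' strictly above it.
#'
#' @param params a [yield_sweep_params()].
#' @return a [rheo_sweep()] (`amplitude_sweep`) with attribute `truth`.
#' @export
simulate_yield_sweep <- function(params) {
  stopifnot(inherits(params, "yield_sweep_params"))
  s <- params$stress_grid
  # tan delta = (sigma / sigma_y)^alpha with alpha > 0 anchored at the
  # lowest grid stress
  alpha <- log(params$Gp0 / params$Gpp0) / log(params$sigma_y / s[1])
  logtan <- alpha * log(s / params$sigma_y)
  Gp <- params$Gp0 / (1 + (s / params$sigma_y)^2)
  Gpp <- Gp * exp(logtan)
  if (params$noise_sd_rel > 0) {
    withr::with_seed(params$seed, {
      eps <- stats::rnorm(length(s), 0, params$noise_sd_rel)
      # same noise on both moduli keeps the crossing location exact
      Gp <- Gp * exp(eps)
      Gpp <- Gpp * exp(eps)
    })
  }
  out <- rheo_sweep("amplitude_sweep", s, Gp, Gpp)
  attr(out, "truth") <- params
  out
}

#' Parameters for a synthetic power-law flow curve
#'
#' @param K consistency index, Pa s^n, > 0.
#' @param n flow index, 0 < n <= 1 (n = 1 is Newtonian).
#' @param rate_grid strictly increasing shear rates, 1/s; default 50
#'   log-spaced points over 1-100 1/s (the flow-test protocol range).
#' @param noise_sd_rel sd of multiplicative log-normal noise, >= 0.
#' @param seed integer seed.
#' @return a `power_law_params` list.
#' @export
power_law_params <- function(K, n, rate_grid = NULL, noise_sd_rel = 0,
                             seed = 1L) {
  if (K <= 0) stop("K must be > 0")
  if (n <= 0 || n > 1) stop("n must be in (0, 1]")
  if (is.null(rate_grid))
    rate_grid <- exp(seq(log(1), log(100), length.out = 50))
  rate_grid <- as.numeric(rate_grid)
  if (any(rate_grid <= 0) || any(diff(rate_grid) <= 0))
    stop("rate_grid must be positive and strictly increasing")
  if (noise_sd_rel < 0) stop("noise_sd_rel must be >= 0")
  structure(list(K = K, n = n, rate_grid = rate_grid,
                 noise_sd_rel = noise_sd_rel, seed = as.integer(seed)),
            class = "power_law_params")
}

#' Simulate a shear-thinning flow curve
#'
#' \eqn{\eta(\dot\gamma) = K \dot\gamma^{n-1}} times multiplicative
#' log-normal noise.
#'
#' @param params a [power_law_params()].
#' @return a [flow_curve()] with attribute `truth = params`.
#' @export
simulate_flow_curve <- function(params) {
  stopifnot(inherits(params, "power_law_params"))
  eta <- params$K * params$rate_grid^(params$n - 1)
  if (params$noise_sd_rel > 0) {
    withr::with_seed(params$seed, {
      eta <- eta * exp(stats::rnorm(length(eta), 0, params$noise_sd_rel))
    })
  }
  out <- flow_curve(params$rate_grid, eta)
  attr(out, "truth") <- params
  out
}

#' Simulate a three-interval thixotropic recovery trace
#'
#' Emulates the recovery protocol (0.5%, 100%, 0.5% strain amplitude for
#' 100, 200 and 100 s): G' sits at `plateau1` in interval 1, drops to
#' `yielded_level` in interval 2, and relaxes exponentially (5 s
#' timescale) toward `recovery_fraction * plateau1` in interval 3. G'' is
#' 0.3 G' in the solid intervals and 2 G' while yielded.
#'
#' @param plateau1 first-interval storage-modulus plateau, Pa > 0.
#' @param yielded_level G' during the high-strain interval, Pa, must not
#'   exceed `plateau1` (yielding lowers G').
#' @param recovery_fraction fraction of `plateau1` recovered in interval
#'   3, in 0 to 1.
#' @param seed integer seed.
#' @param noise_sd_rel sd of multiplicative log-normal noise, >= 0.
#' @param dt sampling step, seconds.
#' @return a [rheo_sweep()] (`recovery`, abscissa seconds) with `truth`.
#' @export
simulate_recovery_trace <- function(plateau1, yielded_level,
                                    recovery_fraction, seed = 1L,
                                    noise_sd_rel = 0, dt = 1) {
  if (plateau1 <= 0) stop("plateau1 must be > 0")
  if (yielded_level < 0) stop("yielded_level must be >= 0")
  if (yielded_level > plateau1)
    stop("yielded_level must not exceed plateau1 (yielding lowers G')")
  if (recovery_fraction < 0 || recovery_fraction > 1)
    stop("recovery_fraction must be in [0, 1]")
  t <- seq(dt, 400, by = dt)
  target <- recovery_fraction * plateau1
  Gp <- ifelse(t <= 100, plateau1,
        ifelse(t <= 300, yielded_level,
               target - (target - yielded_level) * exp(-(t - 300) / 5)))
  Gpp <- ifelse(t > 100 & t <= 300, 2 * pmax(Gp, 1e-12), 0.3 * Gp)
  if (noise_sd_rel > 0) {
    withr::with_seed(seed, {
      Gp <- Gp * exp(stats::rnorm(length(t), 0, noise_sd_rel))
      Gpp <- Gpp * exp(stats::rnorm(length(t), 0, noise_sd_rel))
    })
  }
  out <- rheo_sweep("recovery", t, Gp, Gpp)
  attr(out, "truth") <- list(plateau1 = plateau1,
                             yielded_level = yielded_level,
                             recovery_fraction = recovery_fraction)
  out
}

#' Simulate a linear-viscoelastic frequency sweep
#'
#' Convenience generator for LVE summaries: near-constant moduli with a
#' weak power-law frequency dependence, as fully crosslinked gels show.
#'
#' @param Gp_lve,Gpp_lve plateau moduli, Pa > 0.
#' @param freq_grid strictly increasing frequencies, Hz; default 20
#'   log-spaced points over 0.1-22.5 Hz.
#' @param slope common log-log slope of both moduli vs frequency.
#' @param noise_sd_rel sd of multiplicative log-normal noise.
#' @param seed integer seed.
#' @return a [rheo_sweep()] (`freq_sweep`).
#' @export
simulate_freq_sweep <- function(Gp_lve, Gpp_lve, freq_grid = NULL,
                                slope = 0.05, noise_sd_rel = 0, seed = 1L) {
  if (Gp_lve <= 0 || Gpp_lve <= 0) stop("moduli must be > 0")
  if (is.null(freq_grid))
    freq_grid <- exp(seq(log(0.1), log(22.5), length.out = 20))
  f <- as.numeric(freq_grid)
  Gp <- Gp_lve * (f / 1)^slope
  Gpp <- Gpp_lve * (f / 1)^slope
  if (noise_sd_rel > 0) {
    withr::with_seed(seed, {
      Gp <- Gp * exp(stats::rnorm(length(f), 0, noise_sd_rel))
      Gpp <- Gpp * exp(stats::rnorm(length(f), 0, noise_sd_rel))
    })
  }
  out <- rheo_sweep("freq_sweep", f, Gp, Gpp)
  attr(out, "truth") <- list(Gp_lve = Gp_lve, Gpp_lve = Gpp_lve, slope = slope)
  out
}
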