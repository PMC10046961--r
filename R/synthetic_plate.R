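#' Pulse kernel shape parameters
#'
#' Shape of one synthetic calcium transient: a linear rise over `rise_time`
#' to the pulse amplitude followed by exponential decay. Defaults (2 s rise,
#' 8 s decay constant) resemble whole-well transients of synchronized
#' neuronal oscillations sampled at 2 Hz. Per-event amplitudes are drawn
#' lognormal with mean `amplitude_mean` and coefficient of variation
#' `amplitude_cv`.
#'
#' @param rise_time Rise time in seconds (> 0).
#' @param decay_time_constant Exponential decay time constant in seconds (> 0).
#' @param amplitude_mean Mean pulse amplitude in RLU (> 0).
#' @param amplitude_cv Coefficient of variation of amplitudes, in [0, 1).
#' @return A list of class `calosc_pulse_shape`.
#' @export
pulse_shape <- function(rise_time = 2, decay_time_constant = 8,
                        amplitude_mean = 100, amplitude_cv = 0.25) {
  if (rise_time <= 0 || decay_time_constant <= 0 || amplitude_mean <= 0)
    stop("pulse shape parameters must be strictly positive")
  if (amplitude_cv < 0 || amplitude_cv >= 1)
    stop("amplitude_cv must be in [0, 1)")
  structure(list(rise_time = rise_time,
                 decay_time_constant = decay_time_constant,
                 amplitude_mean = amplitude_mean,
                 amplitude_cv = amplitude_cv),
            class = "calosc_pulse_shape")
}

#' Per-well generative model
#'
#' Baseline behaviour of one well: oscillation rate (pulses per 10 minutes,
#' below 25 for healthy interior wells), within-well rate jitter (CV of the
#' Gamma-distributed inter-pulse intervals; small values give the nearly
#' constant within-well rate seen in stable cultures), baseline fluorescence,
#' linear photobleaching drift, additive Gaussian noise, and an edge flag
#' (edge wells oscillate with inflated jitter and are excluded from
#' treatment).
#'
#' @param base_rate Pulses per 10 min; must be in [0, 25] unless `is_edge`.
#' @param rate_jitter_cv CV of inter-pulse intervals (>= 0; 0 = regular).
#' @param baseline_level Baseline fluorescence in RLU.
#' @param drift_slope Linear drift in RLU/s (photobleaching is negative).
#' @param noise_sd SD of additive Gaussian noise in RLU (>= 0).
#' @param is_edge Edge-well flag.
#' @return A list of class `calosc_well_model`.
#' @export
well_model <- function(base_rate = 12, rate_jitter_cv = 0.2,
                       baseline_level = 1000, drift_slope = -0.01,
                       noise_sd = 5, is_edge = FALSE) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (rate_jitter_cv < 0) stop("rate_jitter_cv must be >= 0")
  if (base_rate < 0) stop("base_rate must be >= 0")
  if (!is_edge && base_rate > 25)
    stop("non-edge wells must have base_rate <= 25 pulses/10 min")
  structure(list(base_rate = base_rate, rate_jitter_cv = rate_jitter_cv,
                 baseline_level = baseline_level, drift_slope = drift_slope,
                 noise_sd = noise_sd, is_edge = is_edge),
            class = "calosc_well_model")
}

#' Treatment effect model
#'
#' Multiplicative effect of a treatment on a well's oscillations after an
#' onset delay: the event rate is multiplied by `rate_multiplier`
#' (0 = complete cessation, i.e. a -100% change in peak number) and event
#' amplitudes by `amplitude_multiplier`.
#'
#' @param rate_multiplier Rate multiplier (>= 0).
#' @param amplitude_multiplier Amplitude multiplier (>= 0).
#' @param onset_delay Seconds after the window start before the effect
#'   applies (events before the delay follow the baseline rate).
#' @return A list of class `calosc_drug_effect`.
#' @export
drug_effect <- function(rate_multiplier = 1, amplitude_multiplier = 1,
                        onset_delay = 0) {
  if (rate_multiplier < 0 || amplitude_multiplier < 0)
    stop("effect multipliers must be >= 0")
  if (onset_delay < 0) stop("onset_delay must be >= 0")
  structure(list(rate_multiplier = rate_multiplier,
                 amplitude_multiplier = amplitude_multiplier,
                 onset_delay = onset_delay),
            class = "calosc_drug_effect")
}

#' Effect model calibrated to a reported dose summary
#'
#' Converts a reported mean percent change in peak number into the rate
#' multiplier that reproduces it in expectation:
#' `rate_multiplier = 1 + mean_delta_pct / 100`.
#'
#' @param summary A one-row data.frame (as returned by
#'   [load_dose_summaries()]) or list with element `mean_delta_pct`.
#' @return A [drug_effect()] object.
#' @examples
#' effect_from_dose_summary(list(mean_delta_pct = 110))$rate_multiplier
#' @export
effect_from_dose_summary <- function(summary) {
  m <- summary$mean_delta_pct
  if (length(m) != 1L || is.na(m)) stop("summary must carry one mean_delta_pct")
  if (m < -100) stop("mean_delta_pct below the -100% cessation floor")
  drug_effect(rate_multiplier = 1 + m / 100)
}

# Run code under a temporary RNG state; NULL seed uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Gamma-renewal event onsets over [0, duration). The first onset is drawn
# uniform on one mean interval (approximate equilibrium start), subsequent
# intervals are Gamma with the given CV, floored at the refractory period.
draw_onsets <- function(rate_per_10min, cv, duration, refractory = 2) {
  if (rate_per_10min <= 0) return(numeric(0))
  mu <- 600 / rate_per_10min
  n_max <- ceiling(duration / mu * 4 + 25)
  first <- stats::runif(1, 0, mu)
  ivl <- if (cv <= 0) rep(mu, n_max) else
    stats::rgamma(n_max, shape = 1 / cv^2, rate = 1 / (cv^2 * mu))
  onsets <- first + cumsum(c(0, pmax(ivl, refractory)))[seq_len(n_max)]
  onsets[onsets < duration]
}

draw_amplitudes <- function(n, shape) {
  if (n == 0L) return(numeric(0))
  if (shape$amplitude_cv <= 0) return(rep(shape$amplitude_mean, n))
  sdlog <- sqrt(log(1 + shape$amplitude_cv^2))
  shape$amplitude_mean * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

render_pulses <- function(onsets, amps, shape, duration, rate_hz) {
  n <- round(duration * rate_hz)
  tt <- seq(0, by = 1 / rate_hz, length.out = n)
  sig <- numeric(n)
  for (k in seq_along(onsets)) {
    t0 <- onsets[k]
    peak <- t0 + shape$rise_time
    tail_end <- min(duration, peak + 12 * shape$decay_time_constant)
    i0 <- max(1L, floor(t0 * rate_hz) + 1L)
    i1 <- min(n, ceiling(tail_end * rate_hz) + 1L)
    idx <- i0:i1
    rel <- tt[idx]
    v <- ifelse(rel <= peak,
                amps[k] * (rel - t0) / shape$rise_time,
                amps[k] * exp(-(rel - peak) / shape$decay_time_constant))
    v[rel < t0] <- 0
    sig[idx] <- sig[idx] + pmax(v, 0)
  }
  sig
}

#' Simulate one well's recording window
#'
#' Generates a fluorescence trace as baseline + linear drift + a sum of
#' pulse kernels (linear rise, exponential decay) + additive Gaussian noise,
#' with pulse onsets from a Gamma renewal process (refractory period 2 s),
#' and returns the injected events as ground truth. Identical seeds give
#' bit-identical output.
#'
#' @param model A [well_model()].
#' @param shape A [pulse_shape()].
#' @param duration Window length in seconds (default 1200 s = 20 min).
#' @param rate_hz Sampling rate, 2 or 10 samples/s.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param effect Optional [drug_effect()] applied to this window: events
#'   after `onset_delay` follow `base_rate * rate_multiplier` with amplitudes
#'   scaled by `amplitude_multiplier`.
#' @param well_id,window Passed to [new_trace()].
#' @return A list with elements `trace` (a [new_trace()] object) and `truth`
#'   (data.frame of `onset`, `peak_time`, `amplitude`, one row per injected
#'   event, times strictly increasing and inside the window).
#' @examples
#' sim <- simulate_well(well_model(base_rate = 12), seed = 1)
#' nrow(sim$truth)
#' @export
simulate_well <- function(model = well_model(), shape = pulse_shape(),
                          duration = 1200, rate_hz = 2, seed = NULL,
                          effect = NULL, well_id = "B2", window = "baseline") {
  if (duration <= 0) stop("duration must be positive")
  if (!rate_hz %in% c(2, 10)) stop("rate_hz must be 2 or 10")
  with_seed(seed, {
    refractory <- 2
    if (is.null(effect) ||
        (effect$rate_multiplier == 1 && effect$onset_delay == 0)) {
      onsets <- draw_onsets(model$base_rate, model$rate_jitter_cv, duration,
                            refractory)
      amp_mult <- if (is.null(effect)) 1 else effect$amplitude_multiplier
      amp_from <- rep(amp_mult, length(onsets))
    } else {
      d0 <- min(effect$onset_delay, duration)
      pre <- draw_onsets(model$base_rate, model$rate_jitter_cv, d0, refractory)
      post <- d0 + draw_onsets(model$base_rate * effect$rate_multiplier,
                               model$rate_jitter_cv, duration - d0, refractory)
      if (length(pre) && length(post) && post[1] - pre[length(pre)] < refractory)
        post <- post[-1]
      onsets <- c(pre, post)
      amp_from <- c(rep(1, length(pre)),
                    rep(effect$amplitude_multiplier, length(post)))
    }
    keep <- onsets + shape$rise_time < duration
    onsets <- onsets[keep]
    amp_from <- amp_from[keep]
    amps <- draw_amplitudes(length(onsets), shape) * amp_from
    sig <- render_pulses(onsets, amps, shape, duration, rate_hz)
    n <- round(duration * rate_hz)
    tt <- seq(0, by = 1 / rate_hz, length.out = n)
    noise <- if (model$noise_sd > 0) stats::rnorm(n, 0, model$noise_sd) else 0
    values <- model$baseline_level + model$drift_slope * tt + sig + noise
    list(
      trace = new_trace(values, rate_hz, well_id = well_id, window = window),
      truth = data.frame(onset = onsets,
                         peak_time = onsets + shape$rise_time,
                         amplitude = amps)
    )
  })
}

#' Simulate a full plate (baseline and post-treatment windows)
#'
#' For every assigned well in a 384-well plate map, simulates a baseline
#' window and a post-treatment window. Post-window events follow the well's
#' baseline rate multiplied by the treatment's `rate_multiplier` (after its
#' onset delay); vehicle wells get an identity effect. Per-well baseline
#' rates are drawn uniformly from `base_rate_range`, emulating the
#' well-to-well rate variability of real plates. Edge wells may be simulated
#' (with `simulate_edges = TRUE`) with `edge_jitter_factor`-inflated rate
#' jitter, but must never carry a treatment.
#'
#' @param plate_map A plate map from [make_plate_map()] (384 rows; columns
#'   `well`, `treatment`, `concentration`, `role`).
#' @param effects Named list mapping treatment names to [drug_effect()]
#'   objects. Treatments named in the map must appear here; `"DMSO"` defaults
#'   to the identity effect when omitted.
#' @param shape A [pulse_shape()] shared by all wells.
#' @param duration,rate_hz Window length (s) and sampling rate.
#' @param seed Optional integer seed for the whole plate.
#' @param base_rate_range Range of per-well baseline rates (pulses/10 min).
#' @param rate_jitter_cv,baseline_level,drift_slope,noise_sd Shared
#'   [well_model()] parameters.
#' @param edge_jitter_factor Multiplier on `rate_jitter_cv` for edge wells.
#' @param simulate_edges Also simulate wells with role `edge_unused`.
#' @return An object of class `calosc_plate`: list with `traces` (named list,
#'   one entry per simulated well, each with `$baseline` and `$post`
#'   traces), `truth` (data.frame of injected events: `well`, `window`,
#'   `onset`, `peak_time`, `amplitude`), `map` (the plate map), and
#'   `effects`.
#' @examples
#' map <- make_plate_map(data.frame(treatment = c("DMSO", "drugA"),
#'                                  concentration = c(NA, 10),
#'                                  n_wells = c(4, 4)))
#' plate <- simulate_plate(map, effects = list(drugA = drug_effect(2)), seed = 1)
#' names(plate$traces[[1]])
#' @export
simulate_plate <- function(plate_map, effects = list(), shape = pulse_shape(),
                           duration = 1200, rate_hz = 2, seed = NULL,
                           base_rate_range = c(8, 24), rate_jitter_cv = 0.2,
                           baseline_level = 1000, drift_slope = -0.01,
                           noise_sd = 5, edge_jitter_factor = 3,
                           simulate_edges = FALSE) {
  validate_plate_map(plate_map)
  assigned <- !is.na(plate_map$treatment)
  if (any(assigned & plate_map$role == "edge_unused")) {
    bad <- plate_map$well[assigned & plate_map$role == "edge_unused"][1]
    stop("treatment assigned to edge well ", bad)
  }
  for (tr in setdiff(unique(plate_map$treatment[assigned]), "DMSO")) {
    if (is.null(effects[[tr]]))
      stop("no effect model supplied for treatment ", tr)
  }
  todo <- plate_map[assigned |
                      (simulate_edges & plate_map$role == "edge_unused"), ,
                    drop = FALSE]
  with_seed(seed, {
    traces <- vector("list", nrow(todo))
    names(traces) <- todo$well
    truth <- vector("list", nrow(todo))
    for (i in seq_len(nrow(todo))) {
      edge <- todo$role[i] == "edge_unused"
      model <- well_model(
        base_rate = stats::runif(1, base_rate_range[1], base_rate_range[2]),
        rate_jitter_cv = rate_jitter_cv * if (edge) edge_jitter_factor else 1,
        baseline_level = baseline_level, drift_slope = drift_slope,
        noise_sd = noise_sd, is_edge = edge)
      eff <- if (edge || is.na(todo$treatment[i])) NULL
             else effects[[todo$treatment[i]]]
      base <- simulate_well(model, shape, duration, rate_hz, seed = NULL,
                            effect = NULL, well_id = todo$well[i],
                            window = "baseline")
      post <- simulate_well(model, shape, duration, rate_hz, seed = NULL,
                            effect = eff, well_id = todo$well[i],
                            window = "post")
      traces[[i]] <- list(baseline = base$trace, post = post$trace)
      tag <- function(window, tr) {
        if (!nrow(tr)) return(NULL)
        cbind(data.frame(well = todo$well[i], window = window,
                         stringsAsFactors = FALSE), tr)
      }
      truth[[i]] <- rbind(tag("baseline", base$truth), tag("post", post$truth))
    }
    structure(list(traces = traces, truth = do.call(rbind, truth),
                   map = plate_map, effects = effects),
              class = "calosc_plate")
  })
}

#' @export
print.calosc_plate <- function(x, ...) {
  cat(sprintf("<calosc_plate> %d simulated wells x 2 windows, %d treatments\n",
              length(x$traces),
              length(unique(stats::na.omit(x$map$treatment)))))
  invisible(x)
}
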