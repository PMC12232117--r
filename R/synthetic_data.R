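#' Bout model for synthetic lick sessions
#'
#' Parameterizes the bout-structured lick trains the generator draws:
#' expected bout count, a log-normal bout-duration distribution, the
#' intra-bout lick rate, and inter-bout gaps as a minimum plus exponential
#' excess. The minimum gap must exceed 10 s so generated bouts are
#' separable under the 10-s bout-splitting rule.
#'
#' @param bouts_per_session Expected number of bouts (Poisson mean).
#' @param bout_duration_meanlog,bout_duration_sdlog Log-normal parameters
#'   of bout duration in seconds.
#' @param intra_bout_lick_rate_hz Lick rate inside bouts, in (0, 12].
#' @param inter_bout_gap_min_s Minimum gap between bouts, must be > 10.
#' @param inter_bout_gap_mean_excess_s Mean of the exponential excess
#'   added to the minimum gap.
#' @param session_duration_s Session length, seconds.
#' @return A `bout_model` list.
#' @export
bout_model <- function(bouts_per_session = 20,
                       bout_duration_meanlog = log(12),
                       bout_duration_sdlog = 0.5,
                       intra_bout_lick_rate_hz = 8,
                       inter_bout_gap_min_s = 12,
                       inter_bout_gap_mean_excess_s = 30,
                       session_duration_s = 1800) {
  if (bouts_per_session < 0) stop("bouts_per_session must be >= 0",
                                  call. = FALSE)
  if (intra_bout_lick_rate_hz <= 0 || intra_bout_lick_rate_hz > 12)
    stop("intra_bout_lick_rate_hz must be in (0, 12]", call. = FALSE)
  if (inter_bout_gap_min_s <= 10)
    stop("inter_bout_gap_min_s must exceed 10 s (bout separability)",
         call. = FALSE)
  if (session_duration_s <= 0)
    stop("session_duration_s must be positive", call. = FALSE)
  structure(list(bouts_per_session = bouts_per_session,
                 bout_duration_meanlog = bout_duration_meanlog,
                 bout_duration_sdlog = bout_duration_sdlog,
                 intra_bout_lick_rate_hz = intra_bout_lick_rate_hz,
                 inter_bout_gap_min_s = inter_bout_gap_min_s,
                 inter_bout_gap_mean_excess_s = inter_bout_gap_mean_excess_s,
                 session_duration_s = session_duration_s),
            class = "bout_model")
}

#' Condition presets for the bout model
#'
#' Behavioral presets mirroring the ordering of the four study conditions:
#' food-restricted dark-phase sessions have the most and longest bouts,
#' ad-libitum light-phase the fewest, and sucralose sessions have bouts
#' about half the caloric-solution length. Numeric values are module
#' choices, not measured quantities.
#'
#' @param condition One of `"Restricted"`, `"Light"`, `"Dark"`,
#'   `"Sucralose"`.
#' @return A `bout_model`.
#' @export
condition_bout_model <- function(condition = c("Restricted", "Light",
                                               "Dark", "Sucralose")) {
  condition <- match.arg(condition)
  switch(condition,
    Restricted = bout_model(bouts_per_session = 20,
                            bout_duration_meanlog = log(12)),
    Dark       = bout_model(bouts_per_session = 12,
                            bout_duration_meanlog = log(10)),
    Light      = bout_model(bouts_per_session = 8,
                            bout_duration_meanlog = log(10)),
    Sucralose  = bout_model(bouts_per_session = 20,
                            bout_duration_meanlog = log(6)))
}

#' Ground truth for synthetic photometry
#'
#' Fixes the injected bout-locked transient (piecewise-linear suppression
#' with optional post-bout rebound), the photobleaching time constant,
#' shared motion-artifact times and the additive noise level. With the
#' defaults (`fs_hz = 100`, 0.1-s analysis bins) the nominal peri-event
#' amplitude of the injected kernel is about
#' `transient_amplitude / (noise_sd * sqrt(2) / sqrt(fs * bin))` baseline-z
#' units; the shipped defaults give ~2 z.
#'
#' @param transient_amplitude Suppression depth, raw signal units.
#' @param suppression_onset_s Seconds after bout start at which the
#'   suppression ramp (1 s long) begins.
#' @param suppression_offset_s Seconds after bout end at which suppression
#'   ends; values beyond the 10-s post window give sustained suppression.
#' @param rebound Logical; if `TRUE` the kernel overshoots above baseline
#'   after `rebound_onset_s` (paraventricular-like), otherwise it recovers
#'   monotonically to baseline (ventromedial-like).
#' @param rebound_onset_s Seconds after bout end at which the rebound
#'   plateau is reached.
#' @param rebound_amplitude Plateau height of the rebound, raw units.
#' @param bleach_tau_s Exponential photobleaching time constant.
#' @param artifact_times_s Times of shared motion artifacts, seconds.
#' @param noise_sd Additive white-noise SD per channel, raw units.
#' @param seed Integer seed stored with the truth.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(transient_amplitude = 0.027,
                         suppression_onset_s = 0.5,
                         suppression_offset_s = 2.8,
                         rebound = TRUE,
                         rebound_onset_s = 4.4,
                         rebound_amplitude = transient_amplitude / 2,
                         bleach_tau_s = 600,
                         artifact_times_s = numeric(0),
                         noise_sd = 0.03,
                         seed = 1L) {
  stopifnot(is.finite(transient_amplitude), is.finite(noise_sd),
            suppression_onset_s >= 0, suppression_offset_s >= 0,
            rebound_onset_s >= 0, bleach_tau_s > 0, noise_sd >= 0)
  structure(list(transient_amplitude = transient_amplitude,
                 suppression_onset_s = suppression_onset_s,
                 suppression_offset_s = suppression_offset_s,
                 rebound = isTRUE(rebound),
                 rebound_onset_s = rebound_onset_s,
                 rebound_amplitude = rebound_amplitude,
                 bleach_tau_s = bleach_tau_s,
                 artifact_times_s = as.numeric(artifact_times_s),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Region presets for the injected transient
#'
#' `pvh_truth()`: suppression from 1.5 s after bout start until 2.8 s after
#' bout end, then a rebound above baseline from 4.4 s post-bout.
#' `vmh_truth()`: suppression from 0.2 s after bout start, sustained beyond
#' the 10-s post-bout window.
#'
#' @param ... Overrides passed to [ground_truth()].
#' @return A `ground_truth`.
#' @export
pvh_truth <- function(...) {
  args <- list(suppression_onset_s = 1.5, suppression_offset_s = 2.8,
               rebound = TRUE, rebound_onset_s = 4.4)
  do.call(ground_truth, utils::modifyList(args, list(...)))
}

#' @rdname pvh_truth
#' @export
vmh_truth <- function(...) {
  args <- list(suppression_onset_s = 0.2, suppression_offset_s = 15,
               rebound = FALSE, rebound_onset_s = 18)
  do.call(ground_truth, utils::modifyList(args, list(...)))
}

#' Generate a synthetic lick session
#'
#' Places a Poisson number of bouts sequentially: gaps between bouts are
#' the model minimum plus exponential excess, bout durations are
#' log-normal, and licks inside a bout are evenly spaced at the intra-bout
#' rate with mild jitter (first and last lick pinned to the bout
#' endpoints). Bouts that would overrun the session are dropped. The
#' generated bout boundaries are attached as attribute `"truth_bouts"`.
#'
#' @param model A [bout_model()].
#' @param condition Condition label for the session.
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   session exactly.
#' @param mouse_id,region Metadata passed through to the session.
#' @return A `lick_session` with attribute `truth_bouts` (data.frame
#'   `start_s`, `end_s`, `n_licks`).
#' @export
gen_lick_session <- function(model, condition = "Restricted", seed = 1L,
                             mouse_id = "m1", region = "none") {
  stopifnot(inherits(model, "bout_model"))
  local_seed(seed, {
    n_target <- stats::rpois(1, model$bouts_per_session)
    licks <- numeric(0)
    tb <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     n_licks = integer(0))
    cursor <- 0
    for (b in seq_len(n_target)) {
      gap <- model$inter_bout_gap_min_s +
        stats::rexp(1, 1 / model$inter_bout_gap_mean_excess_s)
      start <- cursor + gap
      dur <- stats::rlnorm(1, model$bout_duration_meanlog,
                           model$bout_duration_sdlog)
      rate <- model$intra_bout_lick_rate_hz
      n_licks <- max(3L, as.integer(round(dur * rate)) + 1L)
      dur <- max(dur, (n_licks - 1L) * 0.05)  # keep ILIs physical
      end <- start + dur
      if (end + 10 > model$session_duration_s) break
      t <- seq(start, end, length.out = n_licks)
      if (n_licks > 2) {
        ili <- dur / (n_licks - 1)
        jit <- stats::runif(n_licks - 2L, -0.2 * ili, 0.2 * ili)
        t[2:(n_licks - 1L)] <- t[2:(n_licks - 1L)] + jit
      }
      licks <- c(licks, sort(t))
      tb <- rbind(tb, data.frame(start_s = start, end_s = end,
                                 n_licks = n_licks))
      cursor <- end
    }
    sess <- lick_session(licks, session_duration_s =
                           model$session_duration_s,
                         mouse_id = mouse_id, region = region,
                         condition = condition)
    attr(sess, "truth_bouts") <- tb
    sess
  })
}

# Piecewise-linear bout-locked transient kernel evaluated at times t
# (seconds) for one bout [start, end]. Suppression ramps down over 1 s
# from truth$suppression_onset_s after bout start, holds at -A through the
# bout and until suppression_offset_s after bout end, then either recovers
# to baseline over 3 s (no rebound) or rises to +rebound_amplitude by
# rebound_onset_s, holds through the 10-s post window, and returns to zero
# by 13 s post-bout.
transient_kernel <- function(t, start, end, truth) {
  A <- truth$transient_amplitude
  if (A == 0) return(numeric(length(t)))
  on <- truth$suppression_onset_s
  k <- numeric(length(t))
  tl <- t - start             # time since bout start
  tau <- t - end              # time since bout end
  ramp <- tl >= on & tl < on + 1 & tau < 0
  k[ramp] <- -A * (tl[ramp] - on)
  held <- tl >= on + 1 & tau < 0
  k[held] <- -A
  off <- truth$suppression_offset_s
  post_held <- tau >= 0 & tau < off
  k[post_held] <- -A
  if (truth$rebound) {
    R <- truth$rebound_amplitude
    ron <- max(truth$rebound_onset_s, off + 1e-9)
    rise <- tau >= off & tau < ron
    k[rise] <- -A + (A + R) * (tau[rise] - off) / (ron - off)
    plateau <- tau >= ron & tau < 10
    k[plateau] <- R
    decay <- tau >= 10 & tau < 13
    k[decay] <- R * (1 - (tau[decay] - 10) / 3)
  } else {
    rec <- tau >= off & tau < off + 3
    k[rec] <- -A * (1 - (tau[rec] - off) / 3)
  }
  k
}

#' Generate a synthetic two-channel photometry recording
#'
#' The isosbestic control channel is exponential bleach + shared artifacts
#' + white noise; the sensor channel is the same bleach and artifacts
#' scaled by a common channel gain, plus the bout-locked transient kernel
#' from `truth` and independent noise. With zero amplitude, zero noise and
#' no artifacts the sensor channel is exactly `gain` times the control.
#'
#' @param session A `lick_session`; bouts are taken from its
#'   `truth_bouts` attribute when present, else detected with the default
#'   bout rule.
#' @param truth A [ground_truth()].
#' @param fs_hz Sampling rate, must be >= 20 Hz to support 0.1-s bins.
#' @param bleach_amp,bleach_floor Exponential bleach amplitude and
#'   asymptote, raw units.
#' @param signal_gain Channel gain relating sensor to control optics.
#' @param artifact_amp,artifact_width_s Gaussian bump amplitude and SD for
#'   shared motion artifacts.
#' @return A [photometry_recording()].
#' @export
gen_photometry <- function(session, truth, fs_hz = 100,
                           bleach_amp = 80, bleach_floor = 20,
                           signal_gain = 1.0, artifact_amp = 10,
                           artifact_width_s = 0.2) {
  stopifnot(inherits(session, "lick_session"),
            inherits(truth, "ground_truth"))
  if (fs_hz < 20)
    stop("fs_hz must be >= 20 Hz to support 0.1-s analysis bins",
         call. = FALSE)
  dur <- session$session_duration_s
  n <- as.integer(round(dur * fs_hz))
  t <- (seq_len(n) - 1) / fs_hz
  bleach <- bleach_floor + bleach_amp * exp(-t / truth$bleach_tau_s)
  artifact <- numeric(n)
  for (ta in truth$artifact_times_s) {
    w <- artifact_width_s
    idx <- which(t > ta - 5 * w & t < ta + 5 * w)
    artifact[idx] <- artifact[idx] +
      artifact_amp * exp(-(t[idx] - ta)^2 / (2 * w^2))
  }
  tb <- attr(session, "truth_bouts")
  if (is.null(tb)) tb <- detect_bouts(session)
  kern <- numeric(n)
  for (i in seq_len(nrow(tb)))
    kern <- kern + transient_kernel(t, tb$start_s[i], tb$end_s[i], truth)
  local_seed(truth$seed, {
    noise_c <- if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd)
               else numeric(n)
    noise_s <- if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd)
               else numeric(n)
    ctrl <- bleach + artifact + noise_c
    sig <- signal_gain * (bleach + artifact) + kern + noise_s
    photometry_recording(ch_signal = sig, ch_control = ctrl,
                         fs_hz = fs_hz, t0_s = 0)
  })
}

#' Generate a synthetic multispout session
#'
#' One head-fixed session of 100 trials with 3-s access to one of five
#' sucrose concentrations (0, 5, 10, 20, 30 percent), 20 trials of each in
#' pseudorandom order. Per-trial lick counts are negative-binomial with
#' mean `rate * 3 s * effect` (effect applied only under treatment), an
#' overdispersed count model.
#'
#' @param mouse Mouse id.
#' @param treatment `"vehicle"` or `"L-histidine"`.
#' @param rates Named numeric vector of lick rates (Hz) for concentrations
#'   `"0","5","10","20","30"`; all must be present and >= 0.
#' @param effect Multiplicative treatment factor on the rate (applied when
#'   `treatment != "vehicle"`).
#' @param seed Integer seed.
#' @param dispersion Negative-binomial size parameter.
#' @param mouse_factor Multiplicative per-animal scale on all rates.
#' @param access_s Access time per trial, seconds.
#' @return A data.frame `mouse, treatment, trial, concentration_pct,
#'   licks` of class `multispout_session`.
#' @export
gen_multispout_session <- function(mouse, treatment = "vehicle",
                                   rates = multispout_default_rates(),
                                   effect = 1.0, seed = 1L,
                                   dispersion = 4, mouse_factor = 1,
                                   access_s = 3) {
  conc <- c("0", "5", "10", "20", "30")
  if (!all(conc %in% names(rates)))
    stop("rates must name all concentrations: ",
         paste(setdiff(conc, names(rates)), collapse = ", "),
         call. = FALSE)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  fac <- if (identical(treatment, "vehicle")) 1 else effect
  local_seed(seed, {
    order_conc <- sample(rep(conc, each = 20))
    mu <- rates[order_conc] * access_s * fac * mouse_factor
    licks <- stats::rnbinom(100, size = dispersion, mu = mu)
    out <- data.frame(mouse = as.character(mouse),
                      treatment = treatment, trial = seq_len(100),
                      concentration_pct = as.numeric(order_conc),
                      licks = as.integer(licks))
    structure(out, class = c("multispout_session", "data.frame"))
  })
}

#' Default multispout concentration-rate table
#'
#' Lick rates (Hz) monotone in sucrose concentration, scaled so a vehicle
#' session totals about 572 licks over its 100 trials.
#' @return Named numeric vector over concentrations 0, 5, 10, 20, 30.
#' @export
multispout_default_rates <- function() {
  c(`0` = 0.84, `5` = 1.40, `10` = 1.90, `20` = 2.45, `30` = 2.95)
}

#' Generate a full multispout cohort
#'
#' Each mouse receives both a vehicle and a treated session with a shared
#' per-animal log-normal rate multiplier, so treatment comparisons are
#' within-subject as in the crossover design.
#'
#' @param n_mice Number of mice.
#' @param rates Concentration-rate table, see
#'   [multispout_default_rates()].
#' @param effect Multiplicative treatment factor (default 0.4278, the
#'   treated/vehicle ratio of session totals the generator is calibrated
#'   to).
#' @param mouse_sdlog SD of the per-animal log-normal multiplier.
#' @param dispersion Negative-binomial size.
#' @param seed Integer seed.
#' @return Long data.frame of all trials, class `multispout_cohort`.
#' @export
gen_multispout_cohort <- function(n_mice = 8,
                                  rates = multispout_default_rates(),
                                  effect = 0.4278, mouse_sdlog = 0.3,
                                  dispersion = 4, seed = 1L) {
  setup <- local_seed(seed, list(
    mf = stats::rlnorm(n_mice, 0, mouse_sdlog),
    session_seeds = sample.int(.Machine$integer.max - 1L, 2L * n_mice)))
  out <- vector("list", 2L * n_mice)
  k <- 0L
  for (m in seq_len(n_mice)) {
    for (tr in c("vehicle", "L-histidine")) {
      k <- k + 1L
      out[[k]] <- gen_multispout_session(
        mouse = sprintf("m%02d", m), treatment = tr, rates = rates,
        effect = effect, dispersion = dispersion,
        mouse_factor = setup$mf[m], seed = setup$session_seeds[k])
    }
  }
  res <- do.call(rbind, out)
  structure(res, class = c("multispout_cohort", "data.frame"))
}

#' Generate a synthetic in vitro ROI trace
#'
#' A timelapse of ROI mean gray values: flat baseline, then after ligand
#' addition a saturating rise to `f0 * (1 + peak_dff)` with an exponential
#' time constant, plus white noise.
#'
#' @param n_frames Total frames.
#' @param ligand_frame Frame of ligand addition (>= 11 so 10 baseline
#'   frames exist).
#' @param f0 Baseline mean gray value.
#' @param peak_dff Plateau fractional response.
#' @param rise_frames Exponential rise constant, frames.
#' @param noise_sd Noise SD, gray values.
#' @param seed Integer seed.
#' @return An [roi_trace()].
#' @export
gen_roi_trace <- function(n_frames = 60, ligand_frame = 20, f0 = 100,
                          peak_dff = 1.5, rise_frames = 3, noise_sd = 1,
                          seed = 1L) {
  stopifnot(ligand_frame >= 11, n_frames > ligand_frame)
  fr <- seq_len(n_frames)
  mu <- rep(f0, n_frames)
  post <- fr >= ligand_frame
  mu[post] <- f0 * (1 + peak_dff * (1 - exp(-(fr[post] - ligand_frame + 1) /
                                              rise_frames)))
  vals <- local_seed(seed, mu + stats::rnorm(n_frames, 0, noise_sd))
  roi_trace(pmax(vals, 0), ligand_frame = ligand_frame)
}

#' Generate null peri-event snips
#'
#' Snips of pure white noise with no injected signal, binned on the
#' standard layout and z-scored to their own baselines — the null
#' condition for calibrating the consecutive-bin significance rule.
#'
#' @param n_snips Number of snips.
#' @param seed Integer seed.
#' @param layout Snip layout, defaults to [snip_layout()].
#' @param noise_sd Per-bin noise SD (unit by default; z-scoring makes the
#'   scale immaterial).
#' @return A z-scored `snip_set`.
#' @export
gen_null_snips <- function(n_snips, seed = 1L, layout = snip_layout(),
                           noise_sd = 1) {
  raw <- local_seed(seed,
    matrix(stats::rnorm(n_snips * layout$n_bins, 0, noise_sd),
           nrow = n_snips))
  sn <- structure(list(raw = raw, z = NULL,
                       bouts = data.frame(start_s = rep(NA_real_, n_snips),
                                          end_s = NA_real_,
                                          n_licks = NA_integer_,
                                          duration_s = NA_real_),
                       artifact = rep(FALSE, n_snips),
                       baseline_mean = rep(NA_real_, n_snips),
                       baseline_sd = rep(NA_real_, n_snips),
                       layout = layout, n_skipped_edge = 0L,
                       n_skipped_short = 0L),
                  class = "snip_set")
  zscore_snips(sn)
}
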