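#' Configuration for the synthetic go/no-go photometry session generator
#'
#' Builds a validated configuration describing one simulated learning run:
#' the behavioral acquisition sigmoids, the evoked fluorescence components,
#' the calcium indicator kernel, movement statistics, licking, and the video
#' frame geometry. Defaults describe a typical run: ~1600 trials learned
#' within 1200--2000 trials, 50/50 go/no-go, 30 Hz photometry and camera,
#' a fast frequency-tuned sensory transient from 50 ms and a late
#' choice-dependent ramp from 200 ms whose amplitude grows with the
#' behavioral sigmoid.
#'
#' @param n_trials number of trials in the learning run.
#' @param go_fraction probability that a trial presents the go sound.
#' @param sampling_rate photometry sampling rate, Hz.
#' @param trial_window c(start, end) of the trial-aligned trace in seconds
#'   relative to stimulus onset; must span the onset and the pre-cue
#'   baseline (visual cue at -2 s).
#' @param baseline_window per-trial baseline window (seconds), must end at or
#'   before the visual cue.
#' @param behavior list with elements \code{hit} and \code{cr}, each a list
#'   \code{(a, b, c, floor)}: the acquisition sigmoid
#'   \code{rate(t) = floor + a * plogis((t - b)/c)} for the hit rate and the
#'   correct-rejection rate (false-alarm rate = 1 - CR rate). Requires
#'   \code{0 <= floor}, \code{0 <= a}, \code{floor + a <= 1}.
#' @param stim_response list \code{(onset_s, duration_s, amplitude,
#'   nogo_gain, onset_boost, onset_boost_duration_s)}: a sustained drive of
#'   the stated dF/F amplitude during the stimulus, scaled by
#'   \code{nogo_gain} on no-go trials, with a stronger onset transient for
#'   the first \code{onset_boost_duration_s}.
#' @param choice_response list \code{(onset_s, duration_s, amplitude, sign,
#'   fa_gain)}: a drive on lick trials starting at \code{onset_s} whose
#'   amplitude follows the hit-rate acquisition sigmoid rescaled to
#'   \code{[0, amplitude]} (so the neural "response curve" is sigmoid-like by
#'   construction); \code{sign = -1} reproduces the suppressed, tuned-away
#'   cohort; \code{fa_gain} scales it on false-alarm (no-go lick) trials.
#' @param calcium_kernel list \code{(rise_s, decay_s)} for the
#'   difference-of-exponentials indicator kernel (GCaMP6f-like defaults,
#'   50 ms rise / 400 ms decay), normalised to unit sum so a sustained drive
#'   of amplitude A plateaus at A.
#' @param noise_sd per-frame white-noise SD injected into the drive before
#'   kernel convolution (the kernel shapes its spectrum; effective dF/F
#'   noise SD is about 0.19 * noise_sd at the default kernel and 30 Hz).
#' @param baseline_f mean raw-fluorescence baseline (arbitrary units).
#' @param baseline_jitter_sd per-trial fractional jitter of the baseline.
#' @param movement list \code{(prob, lick_coupled, lick_prob, coupling,
#'   burst_duration_s, onset_mean_s, onset_sd_s)}; \code{prob} is an
#'   acquisition-sigmoid schedule \code{(a, b, c, floor)} for the per-trial
#'   probability of a spontaneous body burst (movement probability grows
#'   with learning); \code{lick_coupled = TRUE} adds jaw motion spanning
#'   every lick bout plus, with probability \code{lick_prob}, an
#'   anticipatory body burst on the lick trial; \code{coupling} is the
#'   additive dF/F drive during movement (0 disables contamination, the
#'   default: the clean-signal world).
#' @param lick_latency list \code{(mean_s, sd_s)} of the first lick time,
#'   truncated to the response window (1, 4] s.
#' @param lick_rate_hz,lick_train_end_s rate and end of the lick bout that
#'   follows the first lick.
#' @param frame list \code{(height, width, rate, noise_sd)} for the body
#'   camera: 8-bit frames, default 30 Hz.
#' @param tuning list \code{(best_freq_hz, bandwidth_oct, amplitude)} for the
#'   passive frequency-tuning generator (log-Gaussian tuning).
#' @param go_freq_hz,nogo_freq_hz pure-tone frequencies (0.5 octave apart).
#' @param seed integer; identical configurations (same seed) give
#'   bit-identical outputs.
#' @return a validated list of class \code{sim_config}.
#' @export
#' @examples
#' cfg <- sim_config(n_trials = 200, seed = 42)
#' trials <- simulate_behavior(cfg)
sim_config <- function(n_trials = 1600L,
                       go_fraction = 0.5,
                       sampling_rate = 30,
                       trial_window = c(-3, 4),
                       baseline_window = c(-2.5, -2),
                       behavior = list(
                         hit = list(a = 0.12, b = 900, c = 100, floor = 0.70),
                         cr  = list(a = 0.62, b = 900, c = 100, floor = 0.30)),
                       stim_response = list(
                         onset_s = 0.05, duration_s = 1.0, amplitude = 0.06,
                         nogo_gain = 0.25, onset_boost = 5,
                         onset_boost_duration_s = 0.1),
                       choice_response = list(
                         onset_s = 0.2, duration_s = 2.8, amplitude = 0.05,
                         sign = 1, fa_gain = 1),
                       calcium_kernel = list(rise_s = 0.05, decay_s = 0.4),
                       noise_sd = 0.1,
                       baseline_f = 1.0,
                       baseline_jitter_sd = 0.02,
                       movement = list(
                         prob = list(a = 0.45, b = 900, c = 100, floor = 0.15),
                         lick_coupled = TRUE, lick_prob = 0.5, coupling = 0,
                         burst_duration_s = 1.5,
                         onset_mean_s = 0.5, onset_sd_s = 0.15),
                       lick_latency = list(mean_s = 1.4, sd_s = 0.25),
                       lick_rate_hz = 6,
                       lick_train_end_s = 3.0,
                       frame = list(height = 32L, width = 32L, rate = 30,
                                    noise_sd = 2),
                       tuning = list(best_freq_hz = 10000,
                                     bandwidth_oct = 1.0, amplitude = 0.08),
                       go_freq_hz = 10000,
                       nogo_freq_hz = 10000 / 2^0.5,
                       seed = 1L) {
  cfg <- list(
    n_trials = as.integer(n_trials), go_fraction = go_fraction,
    sampling_rate = sampling_rate, trial_window = trial_window,
    baseline_window = baseline_window, behavior = behavior,
    stim_response = stim_response, choice_response = choice_response,
    calcium_kernel = calcium_kernel, noise_sd = noise_sd,
    baseline_f = baseline_f, baseline_jitter_sd = baseline_jitter_sd,
    movement = movement, lick_latency = lick_latency,
    lick_rate_hz = lick_rate_hz, lick_train_end_s = lick_train_end_s,
    frame = frame, tuning = tuning,
    go_freq_hz = go_freq_hz, nogo_freq_hz = nogo_freq_hz,
    seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot_scalar_prob(cfg$go_fraction, "go_fraction")
  if (cfg$n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  if (cfg$sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  tw <- cfg$trial_window
  if (length(tw) != 2L || tw[1] >= tw[2])
    stop("trial_window must be an increasing (start, end) pair", call. = FALSE)
  if (tw[1] > 0 || tw[2] < 0)
    stop("trial_window must span stimulus onset (time 0)", call. = FALSE)
  for (nm in c("hit", "cr")) {
    s <- cfg$behavior[[nm]]
    if (s$a < 0 || s$floor < 0 || s$a + s$floor > 1)
      stop(sprintf(
        "behavior$%s: rates floor + a*plogis(.) must stay in [0, 1] (a=%g, floor=%g)",
        nm, s$a, s$floor), call. = FALSE)
    if (s$c <= 0) stop("behavior sigmoid steepness c must be > 0", call. = FALSE)
  }
  mv <- cfg$movement$prob
  if (mv$a < 0 || mv$floor < 0 || mv$a + mv$floor > 1)
    stop("movement$prob schedule must stay in [0, 1]", call. = FALSE)
  if (is.null(cfg$movement$lick_prob)) cfg$movement$lick_prob <- 0.5
  stopifnot_scalar_prob(cfg$movement$lick_prob, "movement$lick_prob")
  for (d in c(cfg$calcium_kernel$rise_s, cfg$calcium_kernel$decay_s,
              cfg$stim_response$duration_s, cfg$choice_response$duration_s,
              cfg$movement$burst_duration_s, cfg$lick_latency$sd_s))
    if (d <= 0) stop("all durations and kernel time constants must be > 0",
                     call. = FALSE)
  if (cfg$calcium_kernel$rise_s >= cfg$calcium_kernel$decay_s)
    stop("calcium kernel rise_s must be shorter than decay_s", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  nper <- (tw[2] - tw[1]) * cfg$sampling_rate
  if (nper < (cfg$stim_response$onset_s + 0.1) * cfg$sampling_rate)
    stop("sampling_rate x trial_window too small to contain the stimulus period",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_trials, "trials,",
      sprintf("go fraction %.2f, %g Hz, window [%g, %g] s, seed %d\n",
              x$go_fraction, x$sampling_rate, x$trial_window[1],
              x$trial_window[2], x$seed))
  invisible(x)
}

#' Preset simulation worlds
#'
#' Named configurations used throughout the test battery and the acceptance
#' report: \describe{
#'   \item{standard}{the default learning run (sensory transient at 0.05 s,
#'     choice ramp at 0.2 s scheduled to the behavioral sigmoid).}
#'   \item{noise}{a pure-noise run (all evoked amplitudes 0), 500 trials:
#'     the null world for shuffle-band calibration.}
#'   \item{movement_only}{constant behavioral rates, no evoked components,
#'     strong additive movement coupling (0.2 dF/F) during lick-coupled
#'     bursts centred in the stimulus window: the movement-artifact world.}
#'   \item{tuned_away}{the suppressed cohort: choice sign -1, passive
#'     tuning peaked away from the go frequency.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @param b inflection trial of the behavioral acquisition sigmoids
#'   (standard / tuned_away presets; default 900).
#' @param n_trials override of the preset's run length.
#' @return a \code{sim_config}.
#' @export
sim_preset <- function(name = c("standard", "noise", "movement_only",
                                "tuned_away"),
                       seed = 1L, b = 900, n_trials = NULL) {
  name <- match.arg(name)
  beh <- function(b) list(hit = list(a = 0.12, b = b, c = 100, floor = 0.70),
                          cr = list(a = 0.62, b = b, c = 100, floor = 0.30))
  cfg <- switch(
    name,
    standard = sim_config(behavior = beh(b), seed = seed),
    noise = sim_config(
      n_trials = 500, behavior = beh(b),
      stim_response = list(onset_s = 0.05, duration_s = 1, amplitude = 0,
                           nogo_gain = 0.25, onset_boost = 5,
                           onset_boost_duration_s = 0.1),
      choice_response = list(onset_s = 0.2, duration_s = 2.8,
                             amplitude = 0, sign = 1, fa_gain = 1),
      seed = seed),
    movement_only = sim_config(
      n_trials = 300,
      behavior = list(hit = list(a = 0, b = 900, c = 100, floor = 0.6),
                      cr = list(a = 0, b = 900, c = 100, floor = 0.5)),
      stim_response = list(onset_s = 0.05, duration_s = 1, amplitude = 0,
                           nogo_gain = 0.25, onset_boost = 5,
                           onset_boost_duration_s = 0.1),
      choice_response = list(onset_s = 0.2, duration_s = 2.8,
                             amplitude = 0, sign = 1, fa_gain = 1),
      movement = list(prob = list(a = 0, b = 900, c = 100, floor = 0.15),
                      lick_coupled = TRUE, lick_prob = 1, coupling = 0.2,
                      burst_duration_s = 1.5, onset_mean_s = 0.6,
                      onset_sd_s = 0.1),
      seed = seed),
    tuned_away = sim_config(
      behavior = beh(b),
      choice_response = list(onset_s = 0.2, duration_s = 2.8,
                             amplitude = 0.05, sign = -1, fa_gain = 1),
      tuning = list(best_freq_hz = 25000, bandwidth_oct = 1.0,
                    amplitude = 0.08),
      seed = seed))
  if (!is.null(n_trials)) {
    cfg$n_trials <- as.integer(n_trials)
    cfg <- validate_sim_config(cfg)
  }
  cfg
}

# acquisition-sigmoid rate schedule over trial numbers (1-based)
schedule_rate <- function(par, t) {
  par$floor + par$a * stats::plogis((t - par$b) / par$c)
}
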