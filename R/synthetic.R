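# IPFM beat-time simulator: integrate an instantaneous heart-rate signal on a
# fixed time grid and emit a beat each time the integral crosses an integer.

# Integration grid step (s). 4 ms gives sub-0.01 ms beat-time accuracy for the
# smooth rate signals used here.
IPFM_GRID_DT <- 0.004

#' Autonomic configuration for the IPFM simulator
#'
#' Parameterizes the instantaneous-rate signal
#' \deqn{r(t) = (1000/\bar{RR}) [1 + a_{LF} \sin(2\pi f_{LF} t + \phi_{LF})
#'   + a_{HF} \sin(2\pi f_{HF} t + \phi_{HF}) + \eta(t)]}
#' (beats/s), where \eqn{\eta} is smoothed Gaussian noise of standard
#' deviation `noise_sd`. The HF term emulates respiratory sinus arrhythmia,
#' the LF term slower sympathetic/baroreflex modulation.
#'
#' The `sympatho_shift` parameter \eqn{\rho \in [0, 1]} models a
#' doxorubicin-like shift toward sympathetic predominance by rescaling, before
#' simulation: mean RR by \eqn{(1 - 0.08\rho)} (faster heart rate), HF
#' amplitude by \eqn{(1 - 0.6\rho)} (vagal withdrawal) and LF amplitude by
#' \eqn{(1 + 0.4\rho)}. The coefficients are package constants chosen to give
#' the direction and rough magnitude of the Pre/Post contrast the simulator is
#' meant to emulate; they are configuration, not physiological claims.
#'
#' Defaults are the canine nocturnal preset: mean RR 560 ms (about 107 bpm),
#' respiratory frequency 0.30 Hz with amplitude 0.12, LF at 0.09 Hz with
#' amplitude 0.05, broadband noise SD 0.02, 8-h duration.
#'
#' @param mean_rr Mean RR interval, ms.
#' @param a_hf,f_hf HF (respiratory) modulation amplitude (dimensionless) and
#'   frequency (Hz); `f_hf` must lie in (0.15, 0.4).
#' @param a_lf,f_lf LF modulation amplitude and frequency (Hz); `f_lf` must
#'   lie in (0.04, 0.15).
#' @param noise_sd Standard deviation of the smoothed broadband modulation.
#' @param duration Record duration, seconds.
#' @param sympatho_shift Sympathovagal shift \eqn{\rho} in \[0, 1\].
#' @param phase_hf,phase_lf Modulation phases in radians, or `NULL` to draw
#'   them uniformly from the seed passed to [generate_beats()].
#' @param record_start_clock Wall clock `"HH:MM"` of the first grid sample.
#'
#' @return An object of class `autonomic_config`.
#' @export
autonomic_config <- function(mean_rr = 560, a_hf = 0.12, f_hf = 0.30,
                             a_lf = 0.05, f_lf = 0.09, noise_sd = 0.02,
                             duration = 28800, sympatho_shift = 0,
                             phase_hf = NULL, phase_lf = NULL,
                             record_start_clock = "00:00") {
  stopifnot(mean_rr > 0, duration > 0,
            a_hf >= 0, a_lf >= 0, noise_sd >= 0)
  if (a_hf + a_lf + 3 * noise_sd >= 1) {
    stop("a_hf + a_lf + 3*noise_sd must be < 1 so the rate stays positive")
  }
  if (!(f_hf > 0.15 && f_hf < 0.4)) stop("f_hf must lie in (0.15, 0.4) Hz")
  if (!(f_lf > 0.04 && f_lf < 0.15)) stop("f_lf must lie in (0.04, 0.15) Hz")
  if (sympatho_shift < 0 || sympatho_shift > 1) {
    stop("sympatho_shift must lie in [0, 1]")
  }
  parse_clock(record_start_clock)
  structure(list(mean_rr = mean_rr, a_hf = a_hf, f_hf = f_hf,
                 a_lf = a_lf, f_lf = f_lf, noise_sd = noise_sd,
                 duration = duration, sympatho_shift = sympatho_shift,
                 phase_hf = phase_hf, phase_lf = phase_lf,
                 record_start_clock = record_start_clock),
            class = "autonomic_config")
}

# Apply the sympathovagal-shift rescaling and return the effective parameters.
apply_sympatho_shift <- function(cfg) {
  rho <- cfg$sympatho_shift
  cfg$mean_rr <- cfg$mean_rr * (1 - 0.08 * rho)
  cfg$a_hf <- cfg$a_hf * (1 - 0.6 * rho)
  cfg$a_lf <- cfg$a_lf * (1 + 0.4 * rho)
  cfg$sympatho_shift <- 0
  cfg
}

#' Simulate beat times with the IPFM model
#'
#' Integrates the instantaneous-rate signal of an [autonomic_config()] on a
#' fixed 4 ms grid (trapezoidal rule) and emits beat `k` at the
#' linearly-interpolated time where the running integral crosses `k`. With all
#' modulation and noise at zero this reproduces a metronome: beats at exact
#' multiples of the mean RR.
#'
#' The broadband term is Gaussian white noise on the grid, smoothed by a 2-s
#' moving average and rescaled to standard deviation `noise_sd` (a moving
#' average over \eqn{n} samples divides the SD of white noise by
#' \eqn{\sqrt{n}}, so the rescaling is deterministic), giving a finite-variance
#' noise floor without high-frequency aliasing into the HRV bands.
#'
#' @param config An [autonomic_config()].
#' @param seed Integer seed fixing all randomness (noise path and, when the
#'   config leaves them `NULL`, the modulation phases).
#' @return A [beat_series()] with all beats labeled `"N"`.
#' @examples
#' cfg <- autonomic_config(mean_rr = 500, a_hf = 0, a_lf = 0, noise_sd = 0,
#'                         duration = 10)
#' generate_beats(cfg, seed = 1)$times  # 0.5, 1.0, ..., 10.0
#' @export
generate_beats <- function(config, seed) {
  stopifnot(inherits(config, "autonomic_config"))
  eff <- apply_sympatho_shift(config)
  rng <- local_rng(seed)
  phase_lf <- if (is.null(eff$phase_lf)) rng(stats::runif(1, 0, 2 * pi)) else eff$phase_lf
  phase_hf <- if (is.null(eff$phase_hf)) rng(stats::runif(1, 0, 2 * pi)) else eff$phase_hf

  dt <- IPFM_GRID_DT
  tg <- seq(0, eff$duration, by = dt)
  mod <- 1 +
    eff$a_lf * sin(2 * pi * eff$f_lf * tg + phase_lf) +
    eff$a_hf * sin(2 * pi * eff$f_hf * tg + phase_hf)
  if (eff$noise_sd > 0) {
    nwin <- round(2 / dt) + 1L  # 2-s moving-average window
    white <- rng(stats::rnorm(length(tg) + nwin - 1L))
    # O(n) moving average via cumulative sums
    cs <- c(0, cumsum(white))
    eta <- (cs[(nwin + 1L):length(cs)] - cs[seq_len(length(cs) - nwin)]) / nwin
    mod <- mod + eff$noise_sd * sqrt(nwin) * eta[seq_along(tg)]
  }
  rate <- (1000 / eff$mean_rr) * mod  # beats per second
  if (any(rate <= 0)) {
    stop("rejected configuration: instantaneous rate nonpositive on the grid")
  }
  # running integral (trapezoid); I[j] = integral of rate over [0, tg[j]]
  integral <- c(0, cumsum((rate[-length(rate)] + rate[-1L]) / 2 * dt))
  n_beats <- floor(integral[length(integral)])
  if (n_beats < 1) stop("duration too short: no beat emitted")
  beat_times <- stats::approx(x = integral, y = tg, xout = seq_len(n_beats),
                              ties = "ordered")$y
  beat_series(beat_times, record_start_clock = eff$record_start_clock)
}

# Run an expression under a locally seeded RNG, restoring global state after.
# Returns a function so callers can interleave seeded draws with other code.
local_rng <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  state <- get(".Random.seed", envir = globalenv())
  if (has_old) assign(".Random.seed", old, envir = globalenv())
  function(expr) {
    restore <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (!is.null(restore)) assign(".Random.seed", restore, envir = globalenv())
    })
    expr
  }
}

#' Artifact injection configuration
#'
#' @param ectopic_rate Per-beat probability of turning a beat ectopic
#'   (shifting it earlier). In \[0, 0.2\].
#' @param missed_rate Per-beat probability of deleting a beat (missed
#'   detection). In \[0, 0.2\].
#' @param prematurity Fraction of the local RR interval by which an ectopic
#'   fires early, in (0, 0.9).
#' @return An object of class `artifact_config`.
#' @export
artifact_config <- function(ectopic_rate = 0.01, missed_rate = 0,
                            prematurity = 0.4) {
  stopifnot(ectopic_rate >= 0, ectopic_rate <= 0.2,
            missed_rate >= 0, missed_rate <= 0.2,
            prematurity > 0, prematurity < 0.9)
  structure(list(ectopic_rate = ectopic_rate, missed_rate = missed_rate,
                 prematurity = prematurity),
            class = "artifact_config")
}

#' Inject ectopic beats and missed detections into a beat series
#'
#' Each beat independently becomes ectopic with probability `ectopic_rate`
#' (shifted earlier by `prematurity` times the preceding RR interval and
#' relabeled `"E"`) or is deleted with probability `missed_rate`. Ground-truth
#' labels are retained so filtering performance can be scored against the
#' injection record. Perturbations that would break strict time ordering are
#' skipped.
#'
#' @param beats A [beat_series()].
#' @param cfg An [artifact_config()].
#' @param seed Integer seed.
#' @return A [beat_series()] with perturbed times/labels.
#' @export
inject_artifacts <- function(beats, cfg, seed) {
  stopifnot(inherits(beats, "beat_series"), inherits(cfg, "artifact_config"))
  rng <- local_rng(seed)
  n <- length(beats$times)
  u_ect <- rng(stats::runif(n))
  u_mis <- rng(stats::runif(n))
  times <- beats$times
  labels <- beats$labels

  # ectopic shifts (first beat has no preceding RR, never shifted)
  for (i in which(u_ect < cfg$ectopic_rate)) {
    if (i == 1L) next
    new_t <- times[i] - cfg$prematurity * (times[i] - times[i - 1L])
    if (new_t > times[i - 1L] && (i == n || new_t < times[i + 1L])) {
      times[i] <- new_t
      labels[i] <- "E"
    }
  }
  keep <- u_mis >= cfg$missed_rate
  if (sum(keep) < 2L) stop("artifact injection removed nearly all beats")
  beat_series(times[keep], labels[keep],
              record_start_clock = beats$record_start_clock,
              window = beats$window)
}

#' Simulate a paired Pre/Post cohort
#'
#' Draws mild inter-individual variation (independent Gaussian factors with
#' 5\% relative SD on mean RR and the two modulation amplitudes) around a base
#' configuration, then simulates each subject once with `sympatho_shift = 0`
#' (Pre) and once with `sympatho_shift = shift` (Post), using distinct
#' sub-seeds so noise paths differ between subjects and conditions.
#'
#' @param pre_cfg Base [autonomic_config()] for the Pre condition.
#' @param shift Sympathovagal shift applied in the Post condition.
#' @param n_subjects Number of subjects (at least 2).
#' @param seed Integer seed.
#' @param artifact_cfg Optional [artifact_config()] applied to both conditions.
#' @return A list of length `n_subjects`; each element is a list with
#'   components `pre` and `post` (both [beat_series()]) and `config` (the
#'   subject's jittered Pre configuration).
#' @export
generate_cohort <- function(pre_cfg, shift, n_subjects, seed,
                            artifact_cfg = NULL) {
  stopifnot(inherits(pre_cfg, "autonomic_config"), n_subjects >= 2)
  rng <- local_rng(seed)
  jit <- rng(matrix(stats::rnorm(3L * n_subjects, mean = 1, sd = 0.05),
                    nrow = n_subjects))
  sub_seeds <- rng(matrix(sample.int(2^30, 4L * n_subjects),
                          nrow = n_subjects))
  lapply(seq_len(n_subjects), function(s) {
    cfg_s <- pre_cfg
    cfg_s$mean_rr <- pre_cfg$mean_rr * jit[s, 1L]
    cfg_s$a_hf <- pre_cfg$a_hf * jit[s, 2L]
    cfg_s$a_lf <- pre_cfg$a_lf * jit[s, 3L]
    cfg_post <- cfg_s
    cfg_post$sympatho_shift <- shift
    pre <- generate_beats(cfg_s, seed = sub_seeds[s, 1L])
    post <- generate_beats(cfg_post, seed = sub_seeds[s, 2L])
    if (!is.null(artifact_cfg)) {
      pre <- inject_artifacts(pre, artifact_cfg, seed = sub_seeds[s, 3L])
      post <- inject_artifacts(post, artifact_cfg, seed = sub_seeds[s, 4L])
    }
    list(pre = pre, post = post, config = cfg_s)
  })
}

#' Write a beat series to CSV (or plain RR text)
#'
#' `write_beats()` writes the `time_s,label` CSV dialect consumed by
#' [read_beats()]; `write_rr()` writes the derived RR intervals, one ms value
#' per line.
#'
#' @param beats A [beat_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  utils::write.csv(data.frame(time_s = beats$times, label = beats$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beats
#' @export
write_rr <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  writeLines(format(diff(beats$times) * 1000, trim = TRUE,
                    scientific = FALSE, digits = 12),
             path)
  invisible(path)
}
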