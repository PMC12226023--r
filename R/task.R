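#' Configuration of the pulse-based context-dependent decision-making task
#'
#' The task presents a train of brief auditory pulses. At every time step of
#' the stimulus period the number of pulses is Poisson distributed; each pulse
#' is independently assigned a location (right with per-trial probability
#' `p`) and a frequency (high with per-trial probability `p_high`). The two
#' stimulus channels carry the signed pulse-count differences, scaled by
#' `input_gain`; two binary context channels indicate whether location or
#' frequency is the relevant modality.
#'
#' @param dt Integration/time-bin step in ms.
#' @param tau Single-neuron time constant in ms.
#' @param T_fix,T_sti,T_dec Durations (ms) of the fixation, stimulus and
#'   decision periods. All must be divisible by `dt`.
#' @param pulse_rate Mean number of pulses per time step during the stimulus
#'   period (40 Hz at a 20 ms step gives 0.8).
#' @param strength_probs Admissible per-trial values for the right / high
#'   probabilities. Each must lie strictly in (0, 1); the default set excludes
#'   1/2 so the correct choice is always defined.
#' @param input_gain Scale from a pulse-count difference to input amplitude.
#' @return An object of class `cdm_task_config`.
#' @export
task_config <- function(dt = 20, tau = 100, T_fix = 200, T_sti = 800,
                        T_dec = 20, pulse_rate = 0.8,
                        strength_probs = c(39, 35, 25, 15, 5, 1) / 40,
                        input_gain = 0.1) {
  if (dt <= 0) stop("invalid task config: dt must be positive")
  for (nm in c("T_fix", "T_sti", "T_dec")) {
    v <- get(nm)
    if (v < 0 || abs(v / dt - round(v / dt)) > 1e-9)
      stop("invalid task config: ", nm, " must be a non-negative multiple of dt")
  }
  if (pulse_rate < 0) stop("invalid task config: pulse_rate must be >= 0")
  if (any(strength_probs <= 0 | strength_probs >= 1))
    stop("invalid task config: every strength probability must lie in (0, 1)")
  if (any(abs(strength_probs - 0.5) < 1e-12))
    stop("invalid task config: strength probability 1/2 would leave the target undefined")
  structure(list(dt = dt, tau = tau, T_fix = T_fix, T_sti = T_sti,
                 T_dec = T_dec, pulse_rate = pulse_rate,
                 strength_probs = strength_probs, input_gain = input_gain,
                 n_fix = as.integer(round(T_fix / dt)),
                 n_sti = as.integer(round(T_sti / dt)),
                 n_dec = as.integer(round(T_dec / dt))),
            class = "cdm_task_config")
}

#' Signed stimulus strength of a per-trial probability
#'
#' The strength of a modality on a trial is `2 * p - 1`, where `p` is the
#' per-pulse probability of the "positive" feature value (right location or
#' high frequency).
#'
#' @param p Probability in (0, 1) (vectorised).
#' @return `2 * p - 1`.
#' @export
stimulus_strength <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  2 * p - 1
}

#' Sample a batch of task trials
#'
#' Generates `n_trials` trials under `config`. Per trial, the right / high
#' probabilities are drawn uniformly from `config$strength_probs` and the
#' context is chosen uniformly. Pulses occur only during the stimulus period;
#' the context channels are on from trial start. The target is the sign of the
#' relevant modality's strength and the decision mask marks the decision
#' period.
#'
#' Randomness comes from R's global RNG; use [set.seed()] for reproducibility.
#'
#' @param config A [task_config()].
#' @param n_trials Number of trials (positive).
#' @return An object of class `cdm_trials`: matrices `u1`, `u2`, `u_ctx1`,
#'   `u_ctx2` (trials x steps), vector `target`, logical `decision_mask`
#'   (per step), `n_pulses` (trials x steps raw pulse counts), and a `meta`
#'   data frame with per-trial context label, probabilities, and signed
#'   strengths.
#' @export
sample_trials <- function(config, n_trials) {
  stopifnot(inherits(config, "cdm_task_config"))
  if (n_trials <= 0) stop("n_trials must be positive")
  raw <- .sample_trials_cpp(as.integer(n_trials), config$n_fix, config$n_sti,
                            config$n_dec, config$pulse_rate,
                            config$input_gain, config$strength_probs)
  n_steps <- config$n_fix + config$n_sti + config$n_dec
  uc1 <- matrix(as.numeric(raw$context == 1L), n_trials, n_steps)
  uc2 <- matrix(as.numeric(raw$context == 2L), n_trials, n_steps)
  mask <- rep(FALSE, n_steps)
  if (config$n_dec > 0) mask[(n_steps - config$n_dec + 1L):n_steps] <- TRUE
  meta <- data.frame(
    context = raw$context,
    context_label = ifelse(raw$context == 1L, "LOC", "FRQ"),
    p_loc = raw$p_loc, p_frq = raw$p_frq,
    strength_loc = stimulus_strength(raw$p_loc),
    strength_frq = stimulus_strength(raw$p_frq)
  )
  structure(list(u1 = raw$u1, u2 = raw$u2, u_ctx1 = uc1, u_ctx2 = uc2,
                 target = raw$target, decision_mask = mask, meta = meta,
                 n_pulses = raw$n_pulses, config = config),
            class = "cdm_trials")
}

#' @export
print.cdm_trials <- function(x, ...) {
  cat(sprintf("CDM trial batch: %d trials x %d steps (%d stimulus steps)\n",
              nrow(x$u1), ncol(x$u1), x$config$n_sti))
  cat(sprintf("  contexts: %d LOC / %d FRQ\n",
              sum(x$meta$context == 1), sum(x$meta$context == 2)))
  invisible(x)
}

#' Serialise a trial batch to a JSON container
#'
#' Writes the input channels, targets, masks, pulse counts and per-trial
#' metadata to a versioned JSON file; [load_trials()] restores every field
#' at full double precision.
#'
#' @param trials A `cdm_trials` batch.
#' @param path Output file path.
#' @export
save_trials <- function(trials, path) {
  stopifnot(inherits(trials, "cdm_trials"))
  cfg <- trials$config
  payload <- list(container = "lowrankCDM-trials", version = 1L,
                  u1 = trials$u1, u2 = trials$u2,
                  u_ctx1 = trials$u_ctx1, u_ctx2 = trials$u_ctx2,
                  target = trials$target, decision_mask = trials$decision_mask,
                  n_pulses = trials$n_pulses, meta = trials$meta,
                  config = unclass(cfg))
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a trial batch from its JSON container
#' @param path File written by [save_trials()].
#' @export
load_trials <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$container) || x$container != "lowrankCDM-trials")
    stop("not a lowrankCDM trial container")
  if (is.null(x$version) || x$version != 1L)
    stop("unsupported trial container version: ", x$version)
  cfg <- do.call(task_config, x$config[c("dt", "tau", "T_fix", "T_sti",
                                         "T_dec", "pulse_rate",
                                         "strength_probs", "input_gain")])
  structure(list(u1 = as.matrix(x$u1), u2 = as.matrix(x$u2),
                 u_ctx1 = as.matrix(x$u_ctx1), u_ctx2 = as.matrix(x$u_ctx2),
                 target = x$target, decision_mask = x$decision_mask,
                 meta = as.data.frame(x$meta),
                 n_pulses = as.matrix(x$n_pulses), config = cfg),
            class = "cdm_trials")
}

#' Export per-trial metadata to CSV
#' @param trials A `cdm_trials` batch.
#' @param path Output file path.
#' @export
export_trial_meta <- function(trials, path) {
  stopifnot(inherits(trials, "cdm_trials"))
  utils::write.csv(cbind(trial = seq_len(nrow(trials$meta)),
                         trials$meta, target = trials$target),
                   path, row.names = FALSE)
  invisible(path)
}
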