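#' Run a trial with simulated-optogenetics inhibition
#'
#' Repeats the base protocol with a strong excitatory current (`I_inh`,
#' default 5 nA) injected into the inhibitory population of each target
#' area. Stimulus-phase inhibition shares the stimulus window
#' `[T_on, T_off)`; delay-phase inhibition starts 2 s after stimulus offset
#' (letting the network settle) and lasts to the end of the trial.
#' Deterministic (noise-free) runs are the default so classifications are
#' not noise-flipped.
#'
#' @param conn a `connectome`.
#' @param params a [model_params()] object.
#' @param base_protocol the control [wm_protocol()].
#' @param targets character vector of inhibited areas (nonempty).
#' @param phase `"stimulus"` or `"delay"`.
#' @param deterministic noise off (default `TRUE`).
#' @param I_inh inhibition amplitude (nA).
#' @return a `wm_trajectory`.
#' @export
run_inhibition <- function(conn, params, base_protocol, targets,
                           phase = c("delay", "stimulus"),
                           deterministic = TRUE, I_inh = params$I_inh) {
  phase <- match.arg(phase)
  if (!length(targets)) stop("targets must be nonempty")
  proto <- base_protocol
  proto$inhibition <- c(proto$inhibition,
                        list(list(areas = targets, phase = phase,
                                  current = I_inh, pop = "C")))
  simulate_network(conn, params, proto, deterministic = deterministic)
}

#' Inhibition-effect ratio
#'
#' Mean delay rate under inhibition divided by the same mean in control,
#' averaged over the eligible areas: those persistent in control
#' (`control > theta`) and not themselves inhibited (the inactivated areas
#' are always excluded from the average).
#'
#' @param control_rates,inhibited_rates named delay-rate vectors (Hz).
#' @param targets inhibited area names (excluded from the average).
#' @param theta persistence threshold (Hz).
#' @return scalar ratio (1 = no effect; < 1 = activity decrement).
#' @export
inhibition_effect <- function(control_rates, inhibited_rates, targets,
                              theta = 5) {
  stopifnot(length(control_rates) == length(inhibited_rates))
  eligible <- control_rates > theta & !(names(control_rates) %in% targets)
  if (!any(eligible))
    stop("no eligible area: none is persistent in control and uninhibited")
  mean(inhibited_rates[eligible]) / mean(control_rates[eligible])
}

#' Classify areas into input / core / readout / nonessential
#'
#' Functional four-way classification from phase-specific inhibition:
#' an effect is "strong" when the activity decrement `1 - ratio` exceeds
#' `theta_effect` (default 10%). Input areas have a strong stimulus-phase
#' effect (assigned first); among the rest, core areas combine a strong
#' delay-phase effect with their own persistent delay activity
#' (`> theta_rate`), readout areas are persistent but with weak delay-phase
#' effect, and the remaining areas are nonessential. An area with a strong
#' delay effect but no persistent activity of its own does not meet the core
#' definition and falls into nonessential.
#'
#' @param stim_effects,delay_effects named per-area effect ratios from
#'   inhibiting that area during the stimulus / delay phase.
#' @param control_delay_rates named control delay rates (Hz).
#' @param theta_effect strong-effect cutoff on the decrement `1 - ratio`.
#' @param theta_rate persistence cutoff (Hz).
#' @return named character vector of labels.
#' @export
classify_areas <- function(stim_effects, delay_effects, control_delay_rates,
                           theta_effect = 0.10, theta_rate = 5) {
  areas <- names(control_delay_rates)
  stopifnot(!is.null(areas),
            length(stim_effects) == length(areas),
            length(delay_effects) == length(areas))
  strong_stim <- (1 - stim_effects) > theta_effect
  strong_delay <- (1 - delay_effects) > theta_effect
  high <- control_delay_rates > theta_rate
  lab <- rep("nonessential", length(areas))
  lab[strong_delay & high] <- "core"
  lab[!strong_delay & high] <- "readout"
  lab[strong_stim] <- "input"   # input precedence
  stats::setNames(lab, areas)
}

#' Single-area inhibition survey
#'
#' Runs the control trial plus one inhibition trial per area and phase, and
#' returns the per-area effect ratios and the classification. This is the
#' driver behind the four-way functional map of the network.
#'
#' @param conn a `connectome`.
#' @param params a [model_params()] object.
#' @param base_protocol control [wm_protocol()].
#' @param areas areas to perturb (default: all).
#' @param theta_effect,theta_rate classification thresholds.
#' @param deterministic noise off (default `TRUE`).
#' @return list with `control_rates`, `stim_effects`, `delay_effects`,
#'   `labels`.
#' @export
inhibition_survey <- function(conn, params, base_protocol,
                              areas = conn$atlas$name,
                              theta_effect = 0.10, theta_rate = 5,
                              deterministic = TRUE) {
  ctrl <- simulate_network(conn, params, base_protocol,
                           deterministic = deterministic)
  ctrl_rates <- delay_rates(ctrl)
  eff <- function(phase) {
    vapply(areas, function(a) {
      tr <- run_inhibition(conn, params, base_protocol, a, phase,
                           deterministic = deterministic)
      inhibition_effect(ctrl_rates, delay_rates(tr), a, theta_rate)
    }, numeric(1))
  }
  stim_eff <- eff("stimulus")
  delay_eff <- eff("delay")
  list(control_rates = ctrl_rates[areas],
       stim_effects = stim_eff, delay_effects = delay_eff,
       labels = classify_areas(stim_eff, delay_eff, ctrl_rates[areas],
                               theta_effect, theta_rate))
}

#' Multi-area delay-phase inhibition sweep
#'
#' Inhibits every size-`group_size` combination from a pool of areas during
#' the delay and summarizes, for each area, the mean effect ratio over all
#' groups containing it (second-/higher-order core detection). Exhaustive by
#' default; `n_sample` switches to seeded random sampling of combinations
#' when the combinatorial budget is too large.
#'
#' @param conn a `connectome`.
#' @param params a [model_params()] object.
#' @param base_protocol control [wm_protocol()].
#' @param pool character vector of candidate areas.
#' @param group_size combination size (1 reduces to the single-area survey).
#' @param theta persistence threshold (Hz).
#' @param n_sample optional number of sampled combinations.
#' @param seed RNG seed for sampling.
#' @param max_groups guard on the exhaustive budget.
#' @return list with `per_group` (data frame of group -> ratio) and
#'   `per_area` (named mean effect over groups containing the area).
#' @export
multi_area_sweep <- function(conn, params, base_protocol, pool,
                             group_size = 2, theta = 5,
                             n_sample = NULL, seed = 1L,
                             max_groups = 200L) {
  stopifnot(length(pool) >= group_size, group_size >= 1)
  pool <- sort(pool)   # lexicographic enumeration order
  groups <- utils::combn(pool, group_size, simplify = FALSE)
  if (length(groups) > max_groups && is.null(n_sample))
    stop(length(groups), " combinations exceed the budget (", max_groups,
         "); pass n_sample to sample them")
  if (!is.null(n_sample) && n_sample < length(groups))
    groups <- with_seed(seed, sample(groups, n_sample))
  ctrl <- simulate_network(conn, params, base_protocol, deterministic = TRUE)
  ctrl_rates <- delay_rates(ctrl)
  ratios <- vapply(groups, function(g) {
    tr <- run_inhibition(conn, params, base_protocol, g, "delay")
    inhibition_effect(ctrl_rates, delay_rates(tr), g, theta)
  }, numeric(1))
  per_area <- vapply(pool, function(a) {
    hit <- vapply(groups, function(g) a %in% g, logical(1))
    if (!any(hit)) NA_real_ else mean(ratios[hit])
  }, numeric(1))
  list(per_group = data.frame(
         group = vapply(groups, paste, character(1), collapse = "+"),
         ratio = ratios),
       per_area = per_area)
}
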