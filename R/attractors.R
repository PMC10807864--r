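#' Enumerate attractor states by exhaustive subset stimulation
#'
#' For every subset of the candidate areas, stimulates all subset members
#' simultaneously (population A, standard stimulus window), integrates the
#' trial noise-free, and thresholds the delay rates of *all* areas at
#' `theta` into a binary pattern. Patterns are deduplicated exactly; the
#' all-low pattern is recorded as the baseline and not counted as an
#' attractor.
#'
#' @param conn a `connectome`.
#' @param params a [model_params()] object.
#' @param candidates character vector of stimulated candidate areas (size k;
#'   `2^k` simulations are run unless `n_sample` is given).
#' @param theta firing threshold (Hz) defining "active in the attractor".
#' @param budget maximum number of simulations without sampling.
#' @param n_sample optional number of sampled subsets (seeded), for large k.
#' @param seed sampling seed.
#' @param protocol optional base [wm_protocol()] override (timing/step).
#' @return object of class `attractor_set`: `patterns` (logical matrix,
#'   attractors x areas), `rates` (matching delay-rate matrix), `stimuli`
#'   (list of discovery subsets), `baseline_seen` (flag), `theta`,
#'   `candidates`, `params_used` (`mu_EE`, `g_E_self`).
#' @export
enumerate_attractors <- function(conn, params, candidates, theta = 5,
                                 budget = 2^16, n_sample = NULL, seed = 1L,
                                 protocol = NULL) {
  areas <- conn$atlas$name
  stopifnot(all(candidates %in% areas))
  k <- length(candidates)
  subsets <- NULL
  if (!is.null(n_sample)) {
    subsets <- with_seed(seed, lapply(seq_len(n_sample), function(i) {
      candidates[stats::runif(k) < 0.5]
    }))
  } else {
    if (2^k > budget)
      stop("2^", k, " subsets exceed the budget; pass n_sample to sample")
    subsets <- lapply(0:(2^k - 1), function(code) {
      candidates[bitwAnd(code, bitwShiftL(1, seq_len(k) - 1)) > 0]
    })
  }
  pat_keys <- character(0)
  patterns <- list(); rates <- list(); stimuli <- list()
  baseline_seen <- FALSE
  for (ss in subsets) {
    proto <- if (is.null(protocol)) wm_protocol(ss, params = params)
             else { p <- protocol; p$stim_areas <- ss; p }
    tr <- simulate_network(conn, params, proto, deterministic = TRUE)
    dr <- delay_rates(tr)
    pat <- persistent_areas(dr, theta)
    if (!any(pat)) { baseline_seen <- TRUE; next }
    key <- paste(as.integer(pat), collapse = "")
    if (!(key %in% pat_keys)) {
      pat_keys <- c(pat_keys, key)
      patterns[[key]] <- pat
      rates[[key]] <- dr
      stimuli[[key]] <- ss
    }
  }
  P <- if (length(patterns))
    do.call(rbind, patterns) else
    matrix(logical(0), 0, length(areas), dimnames = list(NULL, areas))
  R <- if (length(rates))
    do.call(rbind, rates) else
    matrix(numeric(0), 0, length(areas), dimnames = list(NULL, areas))
  structure(list(patterns = P, rates = R, stimuli = stimuli,
                 baseline_seen = baseline_seen, theta = theta,
                 candidates = candidates,
                 params_used = c(mu_EE = params$mu_EE,
                                 g_E_self = params$g_E_self)),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat("<attractor_set>", nrow(x$patterns), "distinct attractors over",
      ncol(x$patterns), "areas (theta =", x$theta, "Hz)\n")
  invisible(x)
}

#' Attractor fractions and size distribution
#'
#' The attractor fraction of an area is the share of identified attractors
#' in which it is active; the size of an attractor is its number of active
#' areas. An empty set yields empty outputs, not an error.
#'
#' @param aset an `attractor_set`.
#' @return list with `fraction` (named vector) and `size_histogram` (table
#'   over sizes).
#' @export
attractor_stats <- function(aset) {
  P <- aset$patterns
  if (nrow(P) == 0)
    return(list(fraction = stats::setNames(numeric(ncol(P)), colnames(P)),
                size_histogram = table(integer(0))))
  list(fraction = colMeans(P),
       size_histogram = table(rowSums(P)))
}

#' Attractor counts across coupling parameters
#'
#' Re-runs the census over a grid of long-range (`mu_EE`) and local
#' (`g_E_self`) excitatory strengths. `mu_IE` is co-scaled with `mu_EE` at
#' the standard ratio 0.167/0.1 = 1.67.
#'
#' @param conn a `connectome`.
#' @param mu_EE_list,g_E_self_list parameter grids (nA).
#' @param candidates stimulated candidate areas.
#' @param params base [model_params()] object.
#' @param theta firing threshold (Hz).
#' @param ... passed to [enumerate_attractors()] (budget, sampling,
#'   protocol).
#' @return matrix of attractor counts, `mu_EE_list` x `g_E_self_list`.
#' @export
sweep_attractors <- function(conn, mu_EE_list, g_E_self_list, candidates,
                             params = model_params(), theta = 5, ...) {
  counts <- matrix(NA_integer_, length(mu_EE_list), length(g_E_self_list),
                   dimnames = list(mu_EE_list, g_E_self_list))
  for (i in seq_along(mu_EE_list)) for (j in seq_along(g_E_self_list)) {
    p <- params
    p$mu_EE <- mu_EE_list[i]
    p$mu_IE <- mu_EE_list[i] * 1.67
    p$g_E_self <- g_E_self_list[j]
    aset <- enumerate_attractors(conn, p, candidates, theta = theta, ...)
    counts[i, j] <- nrow(aset$patterns)
  }
  counts
}

#' Rank candidate areas for the census
#'
#' Scores each cortical area by the rank sum of (hierarchy, -PV): areas high
#' in the hierarchy and poor in PV interneurons are the most likely to carry
#' persistent activity and are stimulated first.
#'
#' @param conn a `connectome`.
#' @param k number of candidates to return.
#' @return character vector of area names.
#' @export
rank_candidates <- function(conn, k = 18) {
  score <- rank(conn$h) + rank(-conn$PV)
  conn$atlas$name[order(score, decreasing = TRUE)][seq_len(min(k, n_areas(conn)))]
}

#' Per-attractor core analysis
#'
#' For one identified attractor: inhibits each of its active areas singly
#' during the delay (re-running the discovery stimulus), computes the effect
#' ratio over the remaining active areas, flags cores at ratio < 0.95, and
#' reports the cell type-specific loop strength restricted to the active
#' subnetwork.
#'
#' @param aset an `attractor_set`.
#' @param pattern_index row of `aset$patterns` to analyse (>= 2 active
#'   areas).
#' @param conn a `connectome`.
#' @param params a [model_params()] object.
#' @param core_cutoff strong-effect ratio cutoff (default 0.95).
#' @param loop_length loop length for the restricted measure.
#' @return data frame with one row per active area: `area`, `effect_ratio`,
#'   `core`, `loop_strength_celltype`.
#' @export
attractor_core_analysis <- function(aset, pattern_index, conn, params,
                                    core_cutoff = 0.95, loop_length = 2) {
  stopifnot(pattern_index >= 1, pattern_index <= nrow(aset$patterns))
  pat <- aset$patterns[pattern_index, ]
  high <- names(pat)[pat]
  if (length(high) < 2) stop("pattern must have at least 2 active areas")
  stim <- aset$stimuli[[pattern_index]]
  proto <- wm_protocol(stim, params = params)
  ctrl <- simulate_network(conn, params, proto, deterministic = TRUE)
  ctrl_rates <- delay_rates(ctrl)
  ratios <- vapply(high, function(a) {
    tr <- run_inhibition(conn, params, proto, a, "delay")
    inhibition_effect(ctrl_rates, delay_rates(tr), a, aset$theta)
  }, numeric(1))
  ls <- loop_strength(conn$W_variant$celltype, loop_length, restrict = high)
  data.frame(area = high, effect_ratio = unname(ratios),
             core = unname(ratios < core_cutoff),
             loop_strength_celltype = unname(ls[high]))
}
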