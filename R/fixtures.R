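#' Specification of a synthetic anatomical fixture
#'
#' Describes the statistical structure of a generated atlas/connectome:
#' number of cortical and thalamic areas, the target Pearson correlation
#' between PV cell fraction and hierarchy (negative: association areas carry
#' fewer PV interneurons), the dynamic range of connection weights in log10
#' decades, and the fraction of nonzero off-diagonal connections. Defaults
#' mirror the anatomy the model was built for: 43 cortical areas, a PV-vs-
#' hierarchy correlation of -0.35, weights spanning five orders of magnitude,
#' and near-complete (97%) interareal connectivity.
#'
#' @param n_areas number of cortical areas (>= 2).
#' @param n_thalamic number of thalamic areas.
#' @param seed integer seed; every generator is a pure function of the spec.
#' @param pv_hierarchy_corr target Pearson r in (-1, 0].
#' @param weight_decades log10 dynamic range of nonzero weights (> 0).
#' @param connection_density fraction of nonzero off-diagonal entries.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_areas = 43, n_thalamic = 0, seed = 1,
                         pv_hierarchy_corr = -0.35, weight_decades = 5,
                         connection_density = 0.97) {
  stopifnot(n_areas >= 2, n_thalamic >= 0,
            pv_hierarchy_corr > -1, pv_hierarchy_corr <= 0,
            weight_decades > 0,
            connection_density > 0, connection_density <= 1)
  structure(list(n_areas = as.integer(n_areas),
                 n_thalamic = as.integer(n_thalamic),
                 seed = as.integer(seed),
                 pv_hierarchy_corr = pv_hierarchy_corr,
                 weight_decades = weight_decades,
                 connection_density = connection_density),
            class = "fixture_spec")
}

# Standardized vector with exactly the requested sample correlation to h:
# rho * std(h) + sqrt(1-rho^2) * (noise orthogonalized against h).
correlated_noise <- function(h, rho) {
  n <- length(h)
  u <- as.vector(scale(h))
  eps <- stats::rnorm(n)
  e <- eps - mean(eps) - u * sum((eps - mean(eps)) * u) / sum(u * u)
  e <- e / sqrt(sum(e^2) / (n - 1))
  rho * u + sqrt(1 - rho^2) * e
}

#' Generate a synthetic area atlas
#'
#' Hierarchy scores are uniform on `[0, 1]`; the PV cell fraction is an
#' affine-plus-orthogonalized-noise construction whose *sample* correlation
#' with hierarchy equals the requested target exactly; volumes and neuron
#' densities are log-normal and strictly positive. Thalamic areas (if any)
#' get hierarchy scores on the same raw scale and zero PV density (the model
#' has no thalamic inhibitory population).
#'
#' @param spec a [fixture_spec()].
#' @return an `area_atlas` with `n_areas + n_thalamic` rows.
#' @export
synthetic_atlas <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_areas
    h <- stats::runif(n)
    z <- correlated_noise(h, spec$pv_hierarchy_corr)
    pv_frac <- 0.3 + 0.05 * z
    if (any(pv_frac <= 0))
      stop("PV fraction construction produced nonpositive values; reseed")
    vol <- stats::rlnorm(n, meanlog = log(2), sdlog = 0.5)
    dens <- stats::rlnorm(n, meanlog = log(1e5), sdlog = 0.3)
    modules <- paste0("M", 1 + (rank(h, ties.method = "first") - 1) %/%
                        ceiling(n / 5))
    at <- area_atlas(
      name = sprintf("C%02d", seq_len(n)),
      volume_mm3 = vol, neuron_density = dens,
      pv_density = pv_frac * dens,
      hierarchy_raw = h, module = modules, is_thalamic = FALSE
    )
    if (spec$n_thalamic > 0) {
      nt <- spec$n_thalamic
      th <- area_atlas(
        name = sprintf("T%02d", seq_len(nt)),
        volume_mm3 = stats::rlnorm(nt, log(0.5), 0.5),
        neuron_density = stats::rlnorm(nt, log(8e4), 0.3),
        pv_density = 0,
        hierarchy_raw = stats::runif(nt), module = "thalamus",
        is_thalamic = TRUE
      )
      at <- rbind(at, th)
      class(at) <- c("area_atlas", "data.frame")
    }
    at
  })
}

#' Generate a synthetic weight matrix
#'
#' Nonnegative, zero-diagonal, with log-uniform magnitudes spanning
#' `weight_decades` decades and a `connection_density` fraction of nonzero
#' off-diagonal entries. Dimensions may be rectangular (targets x sources)
#' for thalamocortical blocks.
#'
#' @param spec a [fixture_spec()].
#' @param n_target,n_source matrix dimensions (default: cortical, square).
#' @param seed_offset added to `spec$seed` so different blocks of the same
#'   fixture draw independent streams.
#' @return weight matrix.
#' @export
synthetic_weights <- function(spec, n_target = spec$n_areas,
                              n_source = spec$n_areas, seed_offset = 1000L) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + seed_offset, {
    W <- matrix(10^stats::runif(n_target * n_source,
                                -spec$weight_decades, 0),
                n_target, n_source)
    if (spec$connection_density < 1) {
      keep <- matrix(stats::runif(n_target * n_source) <
                       spec$connection_density, n_target, n_source)
      W <- W * keep
    }
    if (n_target == n_source) diag(W) <- 0
    W
  })
}

#' Deterministic two-area instance for exact tests
#'
#' Two cortical areas with unit volumes and densities, hierarchy `[0, 1]`,
#' PV fraction `[1, 0]` (sensory-like low area, association-like high area)
#' and `W_raw = rbind(c(0, 0.5), c(0.2, 0))`. Every closed-form example in
#' the package documentation is computed on this instance.
#'
#' @return list with elements `atlas` and `W_raw`.
#' @export
toy_two_area_fixture <- function() {
  atlas <- area_atlas(
    name = c("low", "high"),
    volume_mm3 = c(1, 1), neuron_density = c(1, 1),
    pv_density = c(1, 0),            # PV fraction 1 and 0
    hierarchy_raw = c(0, 1),
    module = c("sensory", "frontal"), is_thalamic = FALSE
  )
  W_raw <- matrix(c(0, 0.2, 0.5, 0), 2, 2,
                  dimnames = list(atlas$name, atlas$name))
  # orientation: W_raw["low","high"] = 0.5 (high -> low feedback),
  #              W_raw["high","low"] = 0.2 (low -> high feedforward)
  W_raw["low", "high"] <- 0.5
  W_raw["high", "low"] <- 0.2
  list(atlas = atlas, W_raw = W_raw)
}

#' Build a complete synthetic connectome
#'
#' Convenience wrapper: generates the atlas and weights from one spec and
#' runs the full preprocessing chain. Thalamic rows of the atlas are split
#' off; use [tc_matrices()] with the returned pieces for the thalamocortical
#' extension.
#'
#' @param spec a [fixture_spec()].
#' @param beta,k_scale connectivity-shaping parameters.
#' @return a `connectome` (cortical); if `spec$n_thalamic > 0` the result
#'   carries the thalamic atlas and raw blocks in attributes
#'   `thalamus`, `W_ct_raw` (thalamus x cortex), `W_tc_raw`
#'   (cortex x thalamus).
#' @export
synthetic_connectome <- function(spec, beta = 2.42, k_scale = 0.3) {
  at <- synthetic_atlas(spec)
  ctx <- at[!at$is_thalamic, , drop = FALSE]
  class(ctx) <- c("area_atlas", "data.frame")
  W_raw <- synthetic_weights(spec)
  dimnames(W_raw) <- list(ctx$name, ctx$name)
  conn <- build_connectome(ctx, W_raw, beta = beta, k_scale = k_scale)
  if (spec$n_thalamic > 0) {
    th <- at[at$is_thalamic, , drop = FALSE]
    class(th) <- c("area_atlas", "data.frame")
    attr(conn, "thalamus") <- th
    attr(conn, "W_ct_raw") <- synthetic_weights(
      spec, n_target = spec$n_thalamic, n_source = spec$n_areas,
      seed_offset = 2000L)
    attr(conn, "W_tc_raw") <- synthetic_weights(
      spec, n_target = spec$n_areas, n_source = spec$n_thalamic,
      seed_offset = 3000L)
  }
  conn
}

#' Write a synthetic fixture to disk
#'
#' Emits the CSV dialects used by the readers plus a JSON manifest echoing
#' the spec, the seed and the achieved PV-hierarchy correlation.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  at <- synthetic_atlas(spec)
  ctx <- at[!at$is_thalamic, , drop = FALSE]
  write_area_table(at, file.path(dir, "areas.csv"))
  W <- synthetic_weights(spec)
  dimnames(W) <- list(ctx$name, ctx$name)
  write_weight_matrix(W, file.path(dir, "W_raw.csv"), stage = "raw")
  pvf <- ctx$pv_density / ctx$neuron_density
  manifest <- c(unclass(spec),
                list(achieved_pv_hierarchy_corr =
                       stats::cor(pvf, ctx$hierarchy_raw)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Constructed census fixture: coupled bistable candidates
#'
#' A hand-built 8-area cortical connectome for attractor-census studies:
#' four low-PV association-like areas strongly and reciprocally coupled
#' (weight 1 among themselves), four high-PV sensory-like areas weakly
#' coupled (0.05). With `g_E_self` around 0.44 nA the low-PV areas are
#' independently bistable, so weak long-range coupling yields a near-product
#' attractor landscape that progressively merges as `mu_EE` grows.
#'
#' @return list with `conn` (a `connectome`) and `candidates` (the four
#'   low-PV area names).
#' @export
census_fixture <- function() {
  atlas <- area_atlas(paste0("A", 1:8), 1, 1,
                      pv_density = c(1, 0.9, 0.8, 0.85, 0.1, 0, 0.05, 0.12),
                      hierarchy_raw = c(0, 0.1, 0.2, 0.15, 0.8, 1, 0.9, 0.85))
  W <- matrix(0.05, 8, 8, dimnames = list(atlas$name, atlas$name))
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  list(conn = build_connectome(atlas, W), candidates = paste0("A", 5:8))
}

#' Constructed thalamocortical loop fixture
#'
#' A hand-built five-cortical-area, three-thalamic-area network whose delay
#' activity is maintained by the thalamocortical loop: with the weakened
#' cortical coupling of the thalamocortical regime no cortical area sustains
#' activity on its own, but convergent cortex -> thalamus -> cortex
#' excitation keeps the association areas persistent; inhibiting the
#' thalamus during the delay collapses the activity.
#'
#' @return list with `conn`, `tc` (from [tc_matrices()]), `thalamic_areas`,
#'   and `stim_area` (the association area to stimulate).
#' @export
tc_loop_fixture <- function() {
  atlas <- area_atlas(c("S1", "A1", "A2", "A3", "A4"), 1, 1,
                      pv_density = c(1, 0.1, 0.05, 0, 0.08),
                      hierarchy_raw = c(0, 0.8, 0.9, 1, 0.85))
  Wr <- matrix(0.2, 5, 5, dimnames = list(atlas$name, atlas$name))
  diag(Wr) <- 0
  conn <- build_connectome(atlas, Wr)
  th_names <- c("TH1", "TH2", "TH3")
  W_ct <- matrix(1, 3, 5, dimnames = list(th_names, atlas$name))
  W_ct[, 1] <- 0.1
  W_tc <- matrix(1, 5, 3, dimnames = list(atlas$name, th_names))
  W_tc[1, ] <- 0.1
  tc <- tc_matrices(W_ct, W_tc, conn$h, h_th = c(0.7, 0.72, 0.68))
  list(conn = conn, tc = tc, thalamic_areas = th_names, stim_area = "A3")
}
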