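#' Volume/density normalization of raw connectivity
#'
#' Converts raw anterograde projection densities (per unit volume of source
#' and target) into input per "average neuron" of the target area:
#' `W_norm[i, j] = W_raw[i, j] * Vol_j / d_i`, where `Vol_j` is the volume of
#' source area `j` and `d_i` the neuron density of target area `i`. Rows are
#' targets, columns are sources, here and everywhere in the package.
#'
#' @param W_raw nonnegative square matrix, target-by-source.
#' @param atlas matching `area_atlas` (row/column order must agree).
#' @return the normalized matrix, same dimnames, zero diagonal preserved.
#' @export
normalize_connectivity <- function(W_raw, atlas) {
  stopifnot(is.matrix(W_raw), nrow(W_raw) == ncol(W_raw),
            nrow(W_raw) == nrow(atlas))
  bad <- atlas$name[!is.finite(atlas$volume_mm3) | atlas$volume_mm3 <= 0]
  if (length(bad)) stop("zero/missing volume for area(s): ",
                        paste(bad, collapse = ", "))
  bad <- atlas$name[!is.finite(atlas$neuron_density) | atlas$neuron_density <= 0]
  if (length(bad)) stop("zero/missing neuron density for area(s): ",
                        paste(bad, collapse = ", "))
  if (any(W_raw < 0)) stop("W_raw must be nonnegative")
  W <- sweep(W_raw, 2, atlas$volume_mm3, `*`)     # multiply by source volume
  W <- sweep(W, 1, atlas$neuron_density, `/`)     # divide by target density
  dimnames(W) <- dimnames(W_raw)
  W
}

#' Min-max normalization with pass-through gaps
#'
#' Rescales values to `[0, 1]` by the range of the observed entries
#' (`NA` gaps are preserved). When `bounds` is supplied the min/max come from
#' it instead of from `values`; this is how thalamic hierarchy scores are
#' normalized by the *cortical* range, so they may legitimately fall outside
#' `[0, 1]`.
#'
#' @param values numeric vector, possibly with `NA` gaps.
#' @param bounds optional numeric vector whose finite range supplies min/max.
#' @return numeric vector, same length and names.
#' @export
minmax_normalize <- function(values, bounds = NULL) {
  ref <- if (is.null(bounds)) values else bounds
  ref <- ref[is.finite(ref)]
  if (length(ref) < 2) stop("need at least two observed values to normalize")
  lo <- min(ref); hi <- max(ref)
  if (hi <= lo) stop("zero range: all observed values are equal")
  (values - lo) / (hi - lo)
}

#' Hierarchy imputation by connectivity-weighted mean
#'
#' Areas lacking a measured hierarchy score receive
#' `h_i = alpha_h * (sum_j W_raw[i, j] h_j / sum_j W_raw[i, j]) + beta_h`,
#' where the sums run over areas with known hierarchy. Known entries are
#' returned untouched. The affine coefficients default to the standard fit
#' (`alpha_h = 1.33`, `beta_h = -0.22`).
#'
#' @param W_raw raw weight matrix, target-by-source.
#' @param h_known numeric vector with `NA` at the unknown areas.
#' @param alpha_h,beta_h affine coefficients of the imputation fit.
#' @param refit if `TRUE`, `alpha_h`/`beta_h` are re-estimated by least
#'   squares of the weighted means against the known values before imputing.
#' @return completed hierarchy vector.
#' @export
impute_hierarchy <- function(W_raw, h_known, alpha_h = 1.33, beta_h = -0.22,
                             refit = FALSE) {
  stopifnot(is.matrix(W_raw), length(h_known) == nrow(W_raw))
  known <- is.finite(h_known)
  if (!any(known)) stop("no known hierarchy values to impute from")
  if (all(known)) return(h_known)
  wmean <- function(i) {
    w <- W_raw[i, known]
    tot <- sum(w)
    if (tot <= 0) {
      nm <- rownames(W_raw)[i]
      stop("area ", if (is.null(nm)) i else nm,
           " receives zero weight from areas with known hierarchy")
    }
    sum(w * h_known[known]) / tot
  }
  if (refit) {
    wm_known <- vapply(which(known), wmean, numeric(1))
    fit <- stats::lm.fit(cbind(1, wm_known), h_known[known])
    beta_h <- fit$coefficients[1]
    alpha_h <- fit$coefficients[2]
  }
  h <- h_known
  for (i in which(!known)) h[i] <- alpha_h * wmean(i) + beta_h
  h
}

#' Fill missing thalamic hierarchy from an adjacent nucleus
#'
#' Thalamic areas without a measured hierarchy take the value of the nearest
#' area (by position in a user-declared ordered list) that has one.
#'
#' @param h_th numeric vector with `NA` gaps, in the declared adjacency order.
#' @return completed vector.
#' @export
fill_thalamic_hierarchy <- function(h_th) {
  known <- which(is.finite(h_th))
  if (!length(known)) stop("no thalamic area has a known hierarchy value")
  for (i in which(!is.finite(h_th))) {
    h_th[i] <- h_th[known[which.min(abs(known - i))]]
  }
  h_th
}

#' Power-law rescaling and max-normalization of connectivity
#'
#' Compresses the dynamic range of the normalized weights by an exponent
#' `k_scale` in (0, 1], then divides by the maximum so the strongest
#' connection is exactly 1. The transform is monotone, hence rank-preserving.
#'
#' @param W_norm nonnegative matrix.
#' @param k_scale exponent in (0, 1].
#' @return rescaled matrix with `max(W) == 1`.
#' @export
rescale_connectivity <- function(W_norm, k_scale = 0.3) {
  stopifnot(k_scale > 0, k_scale <= 1)
  if (any(W_norm < 0)) stop("W_norm must be nonnegative")
  W <- W_norm^k_scale
  m <- max(W)
  if (m <= 0) stop("all-zero connectivity matrix cannot be rescaled")
  W / m
}

#' Counterstream-inhibitory-bias coefficient matrix
#'
#' `m[i, j] = 1 / (1 + exp(-beta * (h_i - h_j)))` measures the
#' "feedforwardness" of the projection from source `j` to target `i`:
#' above 0.5 for feedforward (target higher in the hierarchy), below 0.5 for
#' feedback. Complementarity `m[i, j] + m[j, i] = 1` holds exactly, and `m`
#' is invariant to adding a constant to all hierarchy values.
#'
#' @param h normalized hierarchy vector (targets and sources share it).
#' @param beta sigmoid steepness.
#' @return matrix in (0, 1), `0.5` on the diagonal.
#' @export
cib_matrix <- function(h, beta = 2.42) {
  stopifnot(all(is.finite(h)))
  d <- outer(h, h, `-`)            # h_target - h_source
  m <- 1 / (1 + exp(-beta * d))
  if (!is.null(names(h))) dimnames(m) <- list(names(h), names(h))
  m
}

#' Split connectivity into excitatory- and inhibitory-targeting parts
#'
#' Feedforward weight goes preferentially to excitatory targets
#' (`W_E = m * W`) and feedback weight to inhibitory targets
#' (`W_I = (1 - m) * W`); the two parts sum back to `W` exactly.
#'
#' @param W rescaled weight matrix.
#' @param m CIB coefficient matrix from [cib_matrix()].
#' @return list with elements `W_E` and `W_I`.
#' @export
split_by_target <- function(W, m) {
  stopifnot(all(dim(W) == dim(m)))
  list(W_E = m * W, W_I = (1 - m) * W)
}

#' Cell type-specific and control connectivity variants
#'
#' The `celltype` variant weighs each projection by the cell type projection
#' coefficient `m[i, j] - PV_i * (1 - m[i, j])` (excitatory targeting minus
#' PV-weighted inhibitory targeting) and is max-normalized; `sign_only` keeps
#' only the sign of the excitatory-inhibitory balance, `sgn(2m - 1) * W`;
#' `noPV` keeps its magnitude but ignores the local PV gradient,
#' `(2m - 1) * W`. Entries may be negative in every mode; the two control
#' variants are deliberately not max-normalized.
#'
#' @param W rescaled weight matrix.
#' @param m CIB coefficient matrix.
#' @param PV normalized PV fraction per (target) area, in `[0, 1]`.
#' @param mode one of `"celltype"`, `"sign_only"`, `"noPV"`.
#' @return signed matrix.
#' @export
celltype_matrix <- function(W, m, PV,
                            mode = c("celltype", "sign_only", "noPV")) {
  mode <- match.arg(mode)
  stopifnot(all(dim(W) == dim(m)), length(PV) == nrow(W))
  if (any(PV < 0 | PV > 1)) stop("PV must lie in [0, 1]")
  out <- switch(mode,
    celltype = {
      k_cell <- m - PV * (1 - m)   # PV_i recycles down columns: row = target i
      Wc <- k_cell * W
      mx <- max(Wc)
      if (mx <= 0) stop("degenerate celltype normalization: max(W_cell) <= 0")
      Wc / mx
    },
    sign_only = sign(2 * m - 1) * W,
    noPV = (2 * m - 1) * W
  )
  dimnames(out) <- dimnames(W)
  out
}

#' Assemble a model-ready connectome from atlas and raw weights
#'
#' Runs the full preprocessing chain: diagonal removal, volume/density
#' normalization, PV-fraction and hierarchy min-max normalization (cortical
#' areas only), hierarchy imputation for unmeasured areas, power-law
#' rescaling, CIB split, and the cell type-specific variants.
#'
#' @param atlas an `area_atlas` of cortical areas.
#' @param W_raw raw target-by-source weight matrix matching the atlas.
#' @param beta CIB sigmoid steepness.
#' @param k_scale rescaling exponent.
#' @param alpha_h,beta_h hierarchy-imputation coefficients.
#' @return an object of class `connectome`: a list carrying the atlas, every
#'   staged matrix (`W_raw`, `W_norm`, `W_scale`, `W`), the normalized
#'   vectors `h` and `PV`, the CIB matrix `m`, the split `W_E`/`W_I`, and
#'   `W_variant` (named list `celltype`, `sign_only`, `noPV`).
#' @export
build_connectome <- function(atlas, W_raw, beta = 2.42, k_scale = 0.3,
                             alpha_h = 1.33, beta_h = -0.22) {
  validate_atlas(atlas)
  stopifnot(is.matrix(W_raw), nrow(W_raw) == nrow(atlas))
  if (any(atlas$is_thalamic))
    stop("build_connectome() takes cortical areas only; see tc_matrices()")
  diag(W_raw) <- 0   # self-projections are not modelled
  if (is.null(rownames(W_raw)))
    dimnames(W_raw) <- list(atlas$name, atlas$name)

  W_norm <- normalize_connectivity(W_raw, atlas)
  W <- rescale_connectivity(W_norm, k_scale)
  W_scale <- W_norm^k_scale

  PV <- minmax_normalize(pv_fraction(atlas))
  # normalize the measured hierarchy scores first (gaps pass through), then
  # impute on the normalized scale, where the affine coefficients were fit
  h_known <- minmax_normalize(atlas$hierarchy_raw)
  h <- impute_hierarchy(W_raw, h_known, alpha_h, beta_h)
  names(h) <- names(PV) <- atlas$name

  m <- cib_matrix(h, beta)
  sp <- split_by_target(W, m)
  variants <- list(
    celltype = celltype_matrix(W, m, PV, "celltype"),
    sign_only = celltype_matrix(W, m, PV, "sign_only"),
    noPV = celltype_matrix(W, m, PV, "noPV")
  )
  structure(list(atlas = atlas, W_raw = W_raw, W_norm = W_norm,
                 W_scale = W_scale, W = W, h = h, PV = PV, m = m,
                 W_E = sp$W_E, W_I = sp$W_I, W_variant = variants,
                 beta = beta, k_scale = k_scale),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome>", nrow(x$atlas), "areas; max(W) =", max(x$W), "\n")
  cat("  hierarchy range:", paste(signif(range(x$h), 3), collapse = " .. "),
      " PV range:", paste(signif(range(x$PV), 3), collapse = " .. "), "\n")
  invisible(x)
}

#' Number of areas in a connectome
#' @param conn a `connectome`.
#' @return integer.
#' @export
n_areas <- function(conn) nrow(conn$atlas)

#' Export every staged matrix of a connectome to CSV
#'
#' Writes `W_raw`, `W_norm`, `W_scale`, `W`, `W_E`, `W_I` and the variants to
#' `<dir>/<stage>.csv` with sidecar metadata, plus the area table.
#'
#' @param conn a `connectome`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_connectome <- function(conn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_area_table(conn$atlas, file.path(dir, "areas.csv"))
  stages <- list(W_raw = conn$W_raw, W_norm = conn$W_norm,
                 W_scale = conn$W_scale, W = conn$W,
                 W_E = conn$W_E, W_I = conn$W_I)
  for (nm in names(stages))
    write_weight_matrix(stages[[nm]], file.path(dir, paste0(nm, ".csv")),
                        stage = nm)
  for (nm in names(conn$W_variant))
    write_weight_matrix(conn$W_variant[[nm]],
                        file.path(dir, paste0("W_", nm, ".csv")), stage = nm)
  invisible(dir)
}
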