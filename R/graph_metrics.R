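#' Input strength
#'
#' Total incoming connection weight per target area: the row sums of a
#' target-by-source matrix. Works on the raw, rescaled or cell type-specific
#' matrices alike.
#'
#' @param W square matrix, target-by-source.
#' @return named numeric vector.
#' @export
input_strength <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  rowSums(W)
}

#' Eigenvector centrality
#'
#' The entry of each area in the leading eigenvector of the connectivity
#' matrix. For nonnegative matrices this is the Perron vector, returned
#' nonnegative with unit sum. Signed matrices (the cell type-specific
#' variants) have no Perron guarantee, so a deterministic convention is
#' applied: the eigenvalue of largest real part is taken, the real part of
#' its eigenvector is used, the sign is fixed so the largest-magnitude entry
#' is positive, and the vector has unit Euclidean norm. A leading eigenvalue
#' that is ambiguous (another eigenvalue within `tol` of the same real part
#' but not its conjugate) raises an error.
#'
#' @param W square matrix.
#' @param tol tie tolerance on the leading real part.
#' @return named numeric vector.
#' @export
eigenvector_centrality <- function(W, tol = 1e-8) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (all(W == 0)) stop("all-zero matrix has no leading eigenvector")
  e <- eigen(W)
  re <- Re(e$values)
  lead <- which.max(re)
  ties <- which(abs(re - re[lead]) < tol * max(1, abs(re[lead])))
  ties <- ties[ties != lead]
  # a complex-conjugate partner shares the real part; exclude it from the tie
  conj_partner <- abs(Im(e$values[lead])) > tol &
    abs(e$values[ties] - Conj(e$values[lead])) < tol * max(1, Mod(e$values[lead]))
  if (any(!conj_partner))
    stop("ambiguous leading eigenvalue (multiplicity > 1 within tolerance)")
  v <- Re(e$vectors[, lead])
  if (all(W >= 0)) {
    v <- abs(v)
    v <- v / sum(v)
  } else {
    if (v[which.max(abs(v))] < 0) v <- -v
    v <- v / sqrt(sum(v^2))
  }
  stats::setNames(v, rownames(W))
}

# diag of W %*% W ... %*% W without forming unneeded products
mat_power_diag <- function(W, L) {
  P <- W
  for (k in seq_len(L - 1)) P <- P %*% W
  diag(P)
}

#' Loop strength
#'
#' For each area, the sum over all directed simple cycles of exactly `L`
#' distinct areas passing through it of the product of the cycle's edge
#' weights. Rotations of a cycle are counted once; for `L >= 3` the two
#' orientations are distinct cycles. Implemented by closed-form corrections
#' of the diagonal of the matrix power (valid for the supported lengths
#' `L = 2, 3, 4` with a zero diagonal):
#' \itemize{
#'   \item `L = 2`: `diag(W^2)` (each reciprocal pair once);
#'   \item `L = 3`: `diag(W^3)` (no non-simple closed 3-walk survives a zero
#'     diagonal);
#'   \item `L = 4`: `diag(W^4)` minus closed walks revisiting the base area
#'     or folding back on an intermediate area.
#' }
#'
#' @param W square matrix with zero diagonal, target-by-source.
#' @param L loop length, 2, 3 or 4.
#' @param restrict optional character or index subset of areas; cycles are
#'   enumerated on the induced submatrix (per-attractor analysis) and values
#'   reported for those areas only.
#' @return named numeric vector (over `restrict` if given).
#' @export
loop_strength <- function(W, L = 2, restrict = NULL) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (!is.null(restrict)) {
    W <- W[restrict, restrict, drop = FALSE]
  }
  n <- nrow(W)
  if (!(L %in% 2:4)) stop("supported loop lengths are 2, 3 and 4")
  if (L > n) stop("loop length exceeds the number of areas")
  if (any(diag(W) != 0)) stop("loop_strength requires a zero diagonal")
  out <- switch(as.character(L),
    "2" = diag(W %*% W),
    "3" = mat_power_diag(W, 3),
    "4" = {
      P <- W * t(W)                      # P[i, j] = W_ij * W_ji
      p <- rowSums(P)
      d4 <- mat_power_diag(W, 4)
      # walks i -> j -> i -> k -> i and i -> j -> k -> j -> i (k != i)
      d4 - p^2 - (as.vector(P %*% p) - rowSums(P * t(P)))
    })
  stats::setNames(out, rownames(W))
}

#' Correlate a structural measure with delay rates
#'
#' Pearson correlation of a per-area graph measure against delay-period
#' firing rates, restricted to a subset (typically the persistent areas).
#'
#' @param measure numeric vector.
#' @param rates numeric vector, same length.
#' @param subset optional logical subset.
#' @return list with `r`, `p`, `n` (see [correlate_measure()]).
#' @export
predict_rate <- function(measure, rates, subset = NULL) {
  correlate_measure(rates, measure, subset)
}

#' Predict a binary area label from one structural measure
#'
#' Univariate logistic regression (intercept + slope, unregularized);
#' classification at posterior 0.5 and in-sample accuracy, matching how
#' prediction accuracies are usually reported for these measures. Perfect
#' separation is caught and reported as accuracy 1 with `separated = TRUE`;
#' a constant measure degenerates to the majority class.
#'
#' @param measure numeric vector.
#' @param labels logical vector (both classes should be present).
#' @return list with `accuracy`, `separated`, `fit` (the `glm` object or
#'   `NULL` in the degenerate case).
#' @export
predict_binary <- function(measure, labels) {
  stopifnot(length(measure) == length(labels))
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present in labels")
  if (stats::sd(measure) == 0) {
    maj <- mean(labels) >= 0.5
    return(list(accuracy = mean(labels == maj), separated = FALSE,
                fit = NULL))
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(labels ~ measure, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  pred <- stats::predict(fit, type = "response") > 0.5
  acc <- mean(pred == labels)
  if (sep && acc == 1) return(list(accuracy = 1, separated = TRUE, fit = fit))
  list(accuracy = acc, separated = sep, fit = fit)
}

#' Table of graph measures across variants
#'
#' Computes input strength, eigenvector centrality and loop strength (for
#' the requested lengths) on the rescaled matrix and on each connectivity
#' variant of a connectome.
#'
#' @param conn a `connectome`.
#' @param variants character subset of
#'   `c("raw", "celltype", "sign_only", "noPV")` (`"raw"` = the rescaled
#'   max-normalized `W`).
#' @param loop_lengths integer vector within 2:4.
#' @return long-format data frame with columns `area`, `variant`, `measure`,
#'   `loop_length` (NA for non-loop measures), `value`.
#' @export
graph_measure_table <- function(conn,
                                variants = c("raw", "celltype",
                                             "sign_only", "noPV"),
                                loop_lengths = c(2, 3)) {
  variants <- match.arg(variants, several.ok = TRUE)
  rows <- list()
  for (v in variants) {
    W <- if (v == "raw") conn$W else conn$W_variant[[v]]
    add <- function(measure, loop_length, values) {
      rows[[length(rows) + 1]] <<- data.frame(
        area = conn$atlas$name, variant = v, measure = measure,
        loop_length = loop_length, value = unname(values))
    }
    add("input_strength", NA_integer_, input_strength(W))
    ec <- tryCatch(eigenvector_centrality(W), error = function(e) NULL)
    if (!is.null(ec)) add("eigenvector_centrality", NA_integer_, ec)
    for (L in loop_lengths) add("loop_strength", L, loop_strength(W, L))
  }
  do.call(rbind, rows)
}
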