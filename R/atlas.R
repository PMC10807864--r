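#' Per-area anatomical attribute table
#'
#' Constructs and validates the static biology of each modelled area: volume,
#' total neuron density, PV-interneuron density, raw hierarchy score and an
#' optional module label. These quantities feed every connectivity
#' normalization downstream.
#'
#' @param name character vector of unique area names.
#' @param volume_mm3 positive numeric, area volume in mm^3.
#' @param neuron_density positive numeric, neurons per mm^3.
#' @param pv_density nonnegative numeric, PV cells per mm^3.
#' @param hierarchy_raw numeric, raw (unnormalized) hierarchy score; `NA`
#'   marks areas whose hierarchy was not measured.
#' @param module optional character module label per area.
#' @param is_thalamic logical flag per area.
#' @return a data frame of class `area_atlas`.
#' @export
area_atlas <- function(name, volume_mm3, neuron_density, pv_density,
                       hierarchy_raw = NA_real_, module = NA_character_,
                       is_thalamic = FALSE) {
  n <- length(name)
  at <- data.frame(
    name = as.character(name),
    volume_mm3 = as.numeric(volume_mm3),
    neuron_density = as.numeric(neuron_density),
    pv_density = as.numeric(pv_density),
    hierarchy_raw = rep_len(as.numeric(hierarchy_raw), n),
    module = rep_len(as.character(module), n),
    is_thalamic = rep_len(as.logical(is_thalamic), n),
    stringsAsFactors = FALSE
  )
  class(at) <- c("area_atlas", "data.frame")
  validate_atlas(at)
  at
}

#' Validate an area atlas
#'
#' Checks the invariants every atlas must satisfy: unique names, positive
#' volumes, nonnegative densities, and at least one measured hierarchy value.
#'
#' @param atlas an `area_atlas`.
#' @return the atlas, invisibly; errors name the offending area.
#' @export
validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas))
  req <- c("name", "volume_mm3", "neuron_density", "pv_density",
           "hierarchy_raw", "module", "is_thalamic")
  miss <- setdiff(req, names(atlas))
  if (length(miss)) stop("atlas lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(atlas$name))
    stop("duplicated area name(s): ",
         paste(unique(atlas$name[duplicated(atlas$name)]), collapse = ", "))
  bad <- atlas$name[!is.finite(atlas$volume_mm3) | atlas$volume_mm3 <= 0]
  if (length(bad)) stop("nonpositive or missing volume for area(s): ",
                        paste(bad, collapse = ", "))
  bad <- atlas$name[!is.finite(atlas$neuron_density) | atlas$neuron_density < 0]
  if (length(bad)) stop("invalid neuron density for area(s): ",
                        paste(bad, collapse = ", "))
  bad <- atlas$name[!is.finite(atlas$pv_density) | atlas$pv_density < 0]
  if (length(bad)) stop("invalid PV density for area(s): ",
                        paste(bad, collapse = ", "))
  if (!any(is.finite(atlas$hierarchy_raw)))
    stop("at least one area must have a measured hierarchy value")
  invisible(atlas)
}

#' PV cell fraction of each area
#'
#' PV density divided by total neuron density; the quantity the model uses to
#' scale local inhibition (before min-max normalization across the cortex).
#'
#' @param atlas an `area_atlas`.
#' @return numeric vector named by area.
#' @export
pv_fraction <- function(atlas) {
  zero <- atlas$neuron_density <= 0
  if (any(zero)) stop("zero neuron density for area(s): ",
                      paste(atlas$name[zero], collapse = ", "))
  stats::setNames(atlas$pv_density / atlas$neuron_density, atlas$name)
}

#' Read / write area tables and weight matrices
#'
#' CSV dialects used throughout the package. Area tables carry the columns
#' `name,volume_mm3,neuron_density,pv_density,hierarchy_raw,module,is_thalamic`
#' with empty cells meaning missing. Weight matrices are written with area
#' names as first row and first column, in target-by-source orientation
#' (`W[i, j]` = projection from source column `j` onto target row `i`); the
#' orientation, units and processing stage are recorded in a sidecar JSON
#' file `<path>.meta.json`.
#'
#' @param path file path of the CSV.
#' @param atlas an `area_atlas` (for writing).
#' @return `read_area_table` returns an `area_atlas`; `read_weight_matrix`
#'   returns a named numeric matrix.
#' @name connectome_io
NULL

#' @rdname connectome_io
#' @export
read_area_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(name = "character"))
  if (is.null(df$module)) df$module <- NA_character_
  if (is.null(df$is_thalamic)) df$is_thalamic <- FALSE
  area_atlas(df$name, df$volume_mm3, df$neuron_density, df$pv_density,
             df$hierarchy_raw, df$module, df$is_thalamic)
}

#' @rdname connectome_io
#' @export
write_area_table <- function(atlas, path) {
  utils::write.csv(as.data.frame(atlas), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname connectome_io
#' @param W named square matrix (for writing).
#' @param stage character label for the processing stage (metadata only).
#' @param units character units label (metadata only).
#' @export
write_weight_matrix <- function(W, path, stage = "raw", units = "arbitrary") {
  stopifnot(is.matrix(W))
  utils::write.csv(as.data.frame(W), path, row.names = TRUE)
  meta <- list(orientation = "target-by-source (rows = target, cols = source)",
               stage = stage, units = units,
               dim = dim(W))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname connectome_io
#' @export
read_weight_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  W <- as.matrix(df)
  if (nrow(W) != ncol(W)) {
    # rectangular matrices (e.g. thalamus x cortex) are allowed
    storage.mode(W) <- "double"
    return(W)
  }
  storage.mode(W) <- "double"
  W
}
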