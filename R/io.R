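# NIfTI-1 map IO (via RNifti) and grid-consistency checks. Coordinates are
# voxel-space and 0-based at the CLI surface; world coordinates live only
# in the affine carried by the NIfTI header.

#' Read a quantitative map from a NIfTI-1 file
#'
#' @param path Path to a .nii or .nii.gz file.
#' @return A list of class \code{"qmap"}: \code{values} (numeric array),
#'   \code{dim}, \code{pixdim} (voxel spacing), and \code{image}, the
#'   underlying \code{RNifti} image carrying the full header/affine.
#' @export
read_qmap <- function(path) {
  img <- RNifti::readNifti(path)
  structure(list(values = array(as.numeric(img), dim = dim(img)),
                 dim = dim(img), pixdim = RNifti::pixdim(img),
                 image = img),
            class = "qmap")
}

#' Write a quantitative map to a NIfTI-1 file
#'
#' @param values Numeric array, or a \code{qmap}.
#' @param path Output path (.nii or .nii.gz).
#' @param template Optional \code{qmap} or RNifti image supplying the
#'   header/affine; defaults to an identity-affine header.
#' @return The path, invisibly.
#' @export
write_qmap <- function(values, path, template = NULL) {
  if (inherits(values, "qmap")) values <- values$values
  if (inherits(template, "qmap")) template <- template$image
  img <- if (is.null(template)) RNifti::asNifti(values)
         else RNifti::asNifti(values, reference = template)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that two maps share a voxel grid
#'
#' @param a,b \code{qmap}s or arrays.
#' @param what Names used in the error message.
#' @return Invisibly \code{TRUE}; errors descriptively on mismatch.
#' @export
check_same_grid <- function(a, b, what = c("a", "b")) {
  da <- if (inherits(a, "qmap")) a$dim else dim(a)
  db <- if (inherits(b, "qmap")) b$dim else dim(b)
  if (!identical(da, db))
    stop(sprintf("grid mismatch between %s [%s] and %s [%s]",
                 what[1], paste(da, collapse = "x"),
                 what[2], paste(db, collapse = "x")))
  invisible(TRUE)
}

#' Read an integer label volume, coercing integral float storage
#'
#' Label volumes are sometimes stored as floats; values are coerced to
#' integer with a warning when they are integral, and rejected otherwise.
#'
#' @param path Path to a NIfTI-1 label volume.
#' @return Integer array of labels.
#' @export
read_labels <- function(path) {
  q <- read_qmap(path)
  v <- q$values
  if (any(is.na(v))) stop("label volume contains missing values")
  if (any(v != round(v)))
    stop("label volume contains non-integral values")
  dtype <- RNifti::niftiHeader(q$image)$datatype
  if (dtype %in% c(16L, 64L))  # FLOAT32 / FLOAT64 on disk
    warning("label volume stored as float; coercing integral values to integer")
  array(as.integer(round(v)), dim = q$dim)
}

#' Read a simulation/run configuration from YAML
#'
#' Every tunable of the ROI and voxel-wise estimators defaults to the
#' standard analysis values (36 bins over 0-50 1/s, 4% bin retention,
#' 5x5x5 window, 10 in-mask voxels minimum); the YAML file overrides
#' individual fields and must carry an explicit \code{rng_seed} when any
#' simulation noise is requested.
#'
#' @param path YAML file path.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(n_bins = 36, rate_range = c(0, 50), min_bin_frac = 0.04,
                   box = 5, min_in_mask = 10, rng_seed = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}
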