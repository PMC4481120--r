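#' Landmark configuration
#'
#' One digitization event: the full side-expanded coordinate block recorded
#' for one individual, by one method, in one replicate. Rows follow the
#' canonical order of [expand_sides()].
#'
#' @param individual character id of the specimen.
#' @param method character label of the acquisition method (e.g. `"DIG"`,
#'   `"MED"`, `"HIGH"`).
#' @param replicate integer replicate number (>= 1).
#' @param coords numeric K x 3 matrix of landmark coordinates (columns
#'   x, y, z) in the canonical side-expanded order.
#' @param units `"mm"` or `"voxel"`.
#' @param missing logical vector of length K marking landmarks that could
#'   not be placed; masked rows may hold `NA` coordinates.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(individual, method, replicate, coords,
                            units = c("mm", "voxel"), missing = NULL) {
  units <- match.arg(units)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be a K x 3 matrix")
  K <- nrow(coords)
  if (is.null(missing)) missing <- rep(FALSE, K)
  if (length(missing) != K) stop("missing mask length must equal nrow(coords)")
  if (any(!is.finite(coords[!missing, , drop = FALSE])))
    stop("non-finite coordinates at unmasked landmarks for individual ",
         individual)
  replicate <- as.integer(replicate)
  if (replicate < 1L) stop("replicate must be >= 1")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(individual = as.character(individual), method = as.character(method),
         replicate = replicate, coords = coords, units = units,
         missing = unname(as.logical(missing))),
    class = "landmark_config"
  )
}

#' Replicated landmark dataset
#'
#' The full study table: every configuration of every individual, method and
#' replicate, together with the landmark scheme, the distance scheme and the
#' per-method mm-per-unit factors for methods digitized in voxel units.
#'
#' @param configurations list of [landmark_config()] objects, all with the
#'   same number of side-expanded landmarks.
#' @param scheme a [landmark_scheme()]; its side expansion must match the
#'   configurations' row count.
#' @param distance_scheme a [distance_scheme()].
#' @param unit_factor named numeric vector, mm per coordinate unit for each
#'   method recorded in voxel units.
#' @return An object of class `landmark_dataset`. Configurations are stored
#'   in canonical (individual, method, replicate) order so that downstream
#'   results never depend on input row order.
#' @export
landmark_dataset <- function(configurations, scheme,
                             distance_scheme = default_distance_scheme(),
                             unit_factor = numeric()) {
  if (!inherits(scheme, "landmark_scheme")) stop("scheme must be a landmark_scheme")
  if (!inherits(distance_scheme, "distance_scheme"))
    stop("distance_scheme must be a distance_scheme")
  if (length(configurations)) {
    Ks <- vapply(configurations, function(cf) nrow(cf$coords), integer(1))
    if (length(unique(Ks)) > 1L) {
      off <- configurations[[which(Ks != Ks[1])[1]]]
      stop("ragged landmark counts across configurations; offender: ",
           off$individual, "/", off$method, "/", off$replicate)
    }
    if (Ks[1] != n_expanded(scheme))
      stop("configurations have ", Ks[1], " landmarks but the scheme expands to ",
           n_expanded(scheme))
    key <- vapply(configurations, function(cf)
      paste(cf$individual, cf$method, cf$replicate, sep = "\r"), character(1))
    if (anyDuplicated(key))
      stop("duplicated (individual, method, replicate) configuration")
    ind <- vapply(configurations, `[[`, character(1), "individual")
    met <- vapply(configurations, `[[`, character(1), "method")
    rep_ <- vapply(configurations, `[[`, integer(1), "replicate")
    configurations <- unname(configurations[order(ind, met, rep_)])
    voxm <- unique(vapply(configurations, `[[`, character(1), "method")[
      vapply(configurations, `[[`, character(1), "units") == "voxel"])
    lacking <- setdiff(voxm, names(unit_factor))
    if (length(lacking))
      warning("voxel-unit method(s) without a unit factor: ",
              paste(lacking, collapse = ", "))
  }
  if (length(unit_factor) && any(unit_factor <= 0))
    stop("unit factors must be > 0")
  structure(
    list(configurations = configurations, scheme = scheme,
         distance_scheme = distance_scheme, unit_factor = unit_factor),
    class = "landmark_dataset"
  )
}

#' @export
print.landmark_dataset <- function(x, ...) {
  n <- length(x$configurations)
  cat("Replicated landmark dataset\n")
  cat("  configurations:", n, "\n")
  if (n) {
    met <- vapply(x$configurations, `[[`, character(1), "method")
    ind <- vapply(x$configurations, `[[`, character(1), "individual")
    cat("  individuals:", length(unique(ind)),
        " methods:", paste(unique(met), collapse = ", "), "\n")
    cat("  landmarks (side-expanded):", nrow(x$configurations[[1]]$coords), "\n")
  }
  invisible(x)
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration", x$individual, "/", x$method,
      "/ replicate", x$replicate, "-", nrow(x$coords), "landmarks [",
      x$units, "]\n")
  invisible(x)
}

#' Methods present in a dataset
#' @param dataset a [landmark_dataset()].
#' @return Character vector of unique method labels, in canonical order.
#' @export
dataset_methods <- function(dataset) {
  unique(vapply(dataset$configurations, `[[`, character(1), "method"))
}

#' Subset a dataset by method
#' @param dataset a [landmark_dataset()].
#' @param method character label.
#' @return A [landmark_dataset()] containing only that method's configurations.
#' @export
subset_method <- function(dataset, method) {
  keep <- vapply(dataset$configurations, function(cf) cf$method == method,
                 logical(1))
  if (!any(keep)) stop("method not present: ", method)
  landmark_dataset(dataset$configurations[keep], dataset$scheme,
                   dataset$distance_scheme, dataset$unit_factor)
}
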