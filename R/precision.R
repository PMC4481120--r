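#' Leave-one-landmark-out deviation of a landmark
#'
#' Estimates the spread of one landmark without letting its variation leak
#' into the superimposition. The landmark of interest is deleted and a GPA
#' is run on the remaining landmarks; each configuration's fitted similarity
#' transform (centering by the reduced centroid, scaling by the reduced
#' centroid size, and its rotation matrix) is then applied to the held-out
#' landmark, carrying it into the shared shape space. The mean landmark is
#' the arithmetic average of the transformed held-out points, and each
#' configuration's deviation is its Euclidean distance from that mean
#' landmark (shape-space units, i.e. scale-free).
#'
#' Were the landmark left in the superimposition, a highly variable landmark
#' would drag the fit and spread its variance across the other landmarks;
#' see [naive_landmark_deviation()] for that (deliberately naive) contrast.
#'
#' @param configs list of K x 3 matrices (K >= 4 so the reduced fit keeps at
#'   least 3 landmarks).
#' @param landmark_k row index of the landmark to hold out.
#' @param tol,max_iter passed to [gpa()].
#' @return A list with `deviations` (one per configuration), `transformed`
#'   (n x 3 matrix of held-out points in shape space), `mean_landmark`
#'   (3-vector) and `fit` (the reduced `gpa_fit`).
#' @export
loo_landmark_deviation <- function(configs, landmark_k, tol = 1e-10,
                                   max_iter = 100L) {
  configs <- lapply(configs, as.matrix)
  K <- nrow(configs[[1]])
  if (K < 4L) stop("leave-one-out deviation needs K >= 4 landmarks")
  if (landmark_k < 1L || landmark_k > K) stop("invalid landmark index")
  reduced <- lapply(configs, function(x) x[-landmark_k, , drop = FALSE])
  fit <- gpa(reduced, tol = tol, max_iter = max_iter)
  held <- t(mapply(function(x, tr) apply_transform(x[landmark_k, ], tr),
                   configs, fit$transforms))
  mean_lm <- colMeans(held)
  dev <- sqrt(rowSums(sweep(held, 2L, mean_lm)^2))
  list(deviations = unname(dev), transformed = unname(held),
       mean_landmark = mean_lm, fit = fit)
}

#' Per-landmark deviation from a single all-landmark GPA
#'
#' The contrast to [loo_landmark_deviation()]: the same deviation statistic
#' (distance of each configuration's landmark from the mean landmark) but
#' computed from one ordinary GPA that includes every landmark. A landmark
#' with inflated variance then pulls the superimposition and its variance is
#' partly redistributed to the other landmarks, biasing per-landmark
#' precision estimates.
#'
#' @inheritParams loo_landmark_deviation
#' @param fit optionally, a precomputed all-landmark `gpa_fit` of `configs`
#'   (the same fit serves every landmark).
#' @return A list with `deviations` (n x 1 per configuration) for the chosen
#'   landmark and `fit` (the full `gpa_fit`).
#' @export
naive_landmark_deviation <- function(configs, landmark_k, tol = 1e-10,
                                     max_iter = 100L, fit = NULL) {
  configs <- lapply(configs, as.matrix)
  K <- nrow(configs[[1]])
  if (landmark_k < 1L || landmark_k > K) stop("invalid landmark index")
  if (is.null(fit)) fit <- gpa(configs, tol = tol, max_iter = max_iter)
  pts <- t(vapply(fit$aligned, function(x) x[landmark_k, ], numeric(3)))
  mean_lm <- colMeans(pts)
  dev <- sqrt(rowSums(sweep(pts, 2L, mean_lm)^2))
  list(deviations = unname(dev), fit = fit)
}

#' Per-landmark precision report for one method
#'
#' Runs the leave-one-landmark-out analysis for every analyzed landmark of
#' one method and reports the mean and SD of the deviations across that
#' method's configurations (every replicate enters as its own
#' configuration), both in scale-free shape-space units and rescaled to mm
#' by the method's mean centroid size. With a bilaterally symmetric scheme,
#' using the midline and left-side landmarks only (the default) avoids
#' duplicating information from the two sides.
#'
#' @param dataset a [landmark_dataset()] in mm units.
#' @param method method label to analyze.
#' @param use_sides `"midline_and_left"` (default) or `"all"`.
#' @param tol,max_iter passed to [gpa()].
#' @return An object of class `precision_report`: a list with
#'   `per_landmark` (data frame: landmark, side, mean/sd deviation in shape
#'   space and in mm, n_configs), `mean_centroid_size_mm`, `method` and
#'   `use_sides`. The mm columns equal the shape-space columns times
#'   `mean_centroid_size_mm` exactly.
#' @export
landmark_precision_report <- function(dataset, method,
                                      use_sides = c("midline_and_left", "all"),
                                      tol = 1e-10, max_iter = 100L) {
  use_sides <- match.arg(use_sides)
  .assert_mm(dataset, method)
  cfs <- Filter(function(cf) cf$method == method, dataset$configurations)
  if (length(cfs) < 2L) stop("need at least 2 configurations for method ",
                             method)
  map <- expand_sides(dataset$scheme)
  sel <- if (use_sides == "midline_and_left")
    map$index[map$side %in% c("M", "L")] else map$index
  masked <- vapply(cfs, function(cf) any(cf$missing[sel]), logical(1))
  if (any(masked))
    stop("masked landmark(s) in the analyzed subset; exclude configuration(s) ",
         paste(which(masked), collapse = ", "))
  configs <- lapply(cfs, function(cf) cf$coords[sel, , drop = FALSE])
  mcs <- mean(vapply(configs, centroid_size, numeric(1)))
  rows <- lapply(seq_along(sel), function(j) {
    dev <- loo_landmark_deviation(configs, j, tol = tol,
                                  max_iter = max_iter)$deviations
    data.frame(landmark = map$landmark[sel[j]], side = map$side[sel[j]],
               mean_deviation_shape = mean(dev),
               sd_deviation_shape = stats::sd(dev),
               n_configs = length(dev), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  per$mean_deviation_mm <- per$mean_deviation_shape * mcs
  per$sd_deviation_mm <- per$sd_deviation_shape * mcs
  per <- per[, c("landmark", "side", "mean_deviation_shape",
                 "sd_deviation_shape", "mean_deviation_mm",
                 "sd_deviation_mm", "n_configs")]
  structure(list(method = method, per_landmark = per,
                 mean_centroid_size_mm = mcs, use_sides = use_sides),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, digits = 3, ...) {
  cat("Landmark precision report - method", x$method,
      "(", x$use_sides, ")\n")
  cat("  mean centroid size:", format(x$mean_centroid_size_mm, digits = 6),
      "mm\n")
  print(format(x$per_landmark, digits = digits), row.names = FALSE)
  invisible(x)
}
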