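#' Centroid size of a landmark configuration
#'
#' The standard size measure of geometric morphometrics: the square root of
#' the summed squared distances of the landmarks from their centroid. It is
#' invariant to rotation and translation and scales linearly under uniform
#' scaling.
#'
#' @param config numeric K x 3 matrix, K >= 2.
#' @return Non-negative scalar; zero iff all landmarks coincide.
#' @examples
#' centroid_size(rbind(c(0, 0, 0), c(2, 0, 0)))  # sqrt(2)
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2L) stop("centroid size needs at least 2 landmarks")
  centered <- sweep(config, 2L, colMeans(config))
  sqrt(sum(centered^2))
}

#' Least-squares optimal rotation between two centered configurations
#'
#' Solves the orthogonal Procrustes problem for a proper rotation: the 3 x 3
#' matrix `R` with `det(R) = +1` minimizing `||source %*% R - target||^2`
#' (both configurations centered at the origin). Reflections are excluded by
#' flipping the sign of the axis belonging to the smallest singular value of
#' the cross-covariance, so anatomical configurations are never mirrored.
#'
#' @param source,target numeric K x 3 matrices centered at the origin.
#' @param allow_rank2 keep `TRUE` (default) to accept planar (rank 2)
#'   configurations, whose rotation is still unique up to the reflection
#'   constraint; rank below 2 always errors.
#' @return A 3 x 3 proper rotation matrix.
#' @export
optimal_rotation <- function(source, target, allow_rank2 = TRUE) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!identical(dim(source), dim(target)))
    stop("source and target must have identical dimensions")
  M <- crossprod(source, target)  # 3 x 3 cross-covariance
  sv <- svd(M)
  rank <- sum(sv$d > max(sv$d[1], 1e-300) * 1e-12)
  if (rank < 2L || (!allow_rank2 && rank < 3L))
    stop("degenerate cross-covariance: rotation not identifiable")
  s <- c(1, 1, sign(det(sv$v %*% t(sv$u))))
  if (s[3] == 0) s[3] <- 1
  R <- sv$u %*% diag(s) %*% t(sv$v)
  R
}

#' Generalized Procrustes analysis
#'
#' Iterative least-squares superimposition of several configurations into a
#' common shape space: each configuration is centered, scaled to unit
#' centroid size, and rotated to the current mean shape; the mean is then
#' re-estimated as the normalized average of the rotated configurations.
#' Iteration stops when the root-mean-square change of the mean shape falls
#' below `tol` or after `max_iter` sweeps. The summed squared Procrustes
#' distance of the configurations to the mean is non-increasing across
#' iterations. The first configuration's orientation seeds the initial mean,
#' making the result deterministic; up to a global rotation the fit is
#' invariant to any rigid motion and positive scaling applied independently
#' to each input.
#'
#' @param configs list of numeric K x 3 matrices (>= 2, identical K, no
#'   masked landmarks).
#' @param tol convergence tolerance on the RMS coordinate change of the
#'   mean shape (default `1e-10`).
#' @param max_iter maximum number of iterations (default 100).
#' @return An object of class `gpa_fit` with elements
#'   \describe{
#'     \item{mean_shape}{K x 3 matrix, centered at the origin with unit
#'       centroid size.}
#'     \item{aligned}{list of K x 3 matrices in shape space.}
#'     \item{transforms}{per configuration: `translation` (its original
#'       centroid), `scale` (its original centroid size) and `rotation`
#'       (3 x 3 proper rotation), such that
#'       `((X - translation)/scale) %*% rotation` reproduces the aligned
#'       coordinates.}
#'     \item{mean_centroid_size}{mean of the input centroid sizes, in the
#'       input units.}
#'     \item{iterations, converged}{iteration count and convergence flag.}
#'     \item{objective}{summed squared Procrustes distance to the mean at
#'       each iteration (non-increasing).}
#'   }
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (length(configs) < 2L) stop("GPA needs at least 2 configurations")
  configs <- lapply(configs, as.matrix)
  K <- nrow(configs[[1]])
  if (any(vapply(configs, nrow, integer(1)) != K))
    stop("all configurations must have the same number of landmarks")
  if (any(vapply(configs, function(x) any(!is.finite(x)), logical(1))))
    stop("GPA requires complete configurations (no masked landmarks)")

  centroids <- lapply(configs, colMeans)
  sizes <- vapply(configs, centroid_size, numeric(1))
  if (any(sizes <= 0)) stop("degenerate configuration with zero centroid size")
  unit <- Map(function(x, c0, s) sweep(x, 2L, c0) / s, configs, centroids,
              sizes)

  mean_shape <- unit[[1]]  # seeds orientation deterministically
  rotations <- rep(list(diag(3)), length(unit))
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    rotations <- lapply(unit, optimal_rotation, target = mean_shape)
    rotated <- Map(`%*%`, unit, rotations)
    objective <- c(objective,
                   sum(vapply(rotated, function(x) sum((x - mean_shape)^2),
                              numeric(1))))
    avg <- Reduce(`+`, rotated) / length(rotated)
    avg <- sweep(avg, 2L, colMeans(avg))
    new_mean <- avg / sqrt(sum(avg^2))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  rotations <- lapply(unit, optimal_rotation, target = mean_shape)
  aligned <- Map(`%*%`, unit, rotations)
  transforms <- Map(function(c0, s, R)
    list(translation = c0, scale = s, rotation = R),
    centroids, sizes, rotations)
  structure(
    list(mean_shape = mean_shape, aligned = aligned, transforms = transforms,
         mean_centroid_size = mean(sizes), iterations = iter,
         converged = converged, objective = objective),
    class = "gpa_fit"
  )
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("GPA fit:", length(x$aligned), "configurations,",
      nrow(x$mean_shape), "landmarks;",
      x$iterations, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  mean centroid size:", format(x$mean_centroid_size), "\n")
  invisible(x)
}

#' Apply a fitted similarity transform to coordinates
#'
#' Applies a configuration's fitted Procrustes transform — centering by its
#' centroid, division by its centroid size, then rotation — to arbitrary
#' points. Applying a fit's own transform to its source configuration
#' reproduces the stored aligned coordinates; a point at the configuration's
#' centroid maps to the origin. This is how a landmark excluded from the
#' superimposition is carried into the shared shape space.
#'
#' @param x numeric matrix of points (n x 3) or a single 3-vector.
#' @param transform one element of a `gpa_fit`'s `transforms` list.
#' @return Transformed coordinates with the shape of `x`.
#' @export
apply_transform <- function(x, transform) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  out <- sweep(m, 2L, transform$translation) / transform$scale
  out <- out %*% transform$rotation
  if (vec) drop(out) else out
}

#' Total Procrustes distance of a fit
#'
#' Summed squared distances of the aligned configurations from the mean
#' shape — the objective GPA minimizes.
#'
#' @param fit a `gpa_fit`.
#' @return Non-negative scalar.
#' @export
procrustes_ss <- function(fit) {
  sum(vapply(fit$aligned, function(x) sum((x - fit$mean_shape)^2),
             numeric(1)))
}
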