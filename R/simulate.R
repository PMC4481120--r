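#' Template mean shapes for simulation
#'
#' `toad_like` returns a fixed, bilaterally symmetric 35-point configuration
#' approximating a ~20 mm anuran skull with the bundled scheme's structure
#' (5 midline landmarks, 15 bilateral pairs mirrored exactly about the
#' midsagittal plane); its inter-landmark distances span roughly 2-17 mm,
#' with the small-distance subset (< 3 mm) mimicking the study design.
#' `random` draws a well-conditioned configuration (coordinates uniform in a
#' 20 mm box, redrawn until no three landmarks are nearly collinear).
#'
#' @param style `"toad_like"` or `"random"`.
#' @param K number of landmarks for `random` (ignored for `toad_like`,
#'   which is always 35 and follows [default_landmark_scheme()]).
#' @param seed integer seed for `random` (same seed, same template).
#' @return A K x 3 matrix in mm; rows in canonical side-expanded order for
#'   `toad_like`.
#' @export
make_template <- function(style = c("toad_like", "random"), K = 35L,
                          seed = 1L) {
  style <- match.arg(style)
  if (style == "toad_like") {
    if (K != 35L) stop("toad_like template is fixed at 35 side-expanded landmarks")
    # per-landmark positions (x anterior->posterior, y lateral, z ventral->dorsal)
    base <- matrix(c(
      1.0, 0.0, 3.5,   # 1  anterior tip of nasal
      8.0, 0.0, 4.5,   # 2  nasal-frontoparietal suture
      15.5, 0.0, 4.8,  # 3  posterior tip of frontoparietal suture
      3.0, 4.0, 3.2,   # 4  nasal-maxillary suture
      8.2, 2.3, 4.2,   # 5  nasal-frontoparietal lateral suture
      13.0, 5.5, 4.6,  # 6  frontoparietal-squamosal suture
      16.0, 4.8, 4.2,  # 7  frontoparietal-squamosal-occipital suture
      15.4, 6.4, 3.6,  # 8  squamosal-occipital suture
      16.3, 1.6, 4.4,  # 9  frontoparietal-occipital suture
      0.9, 2.4, 2.0,   # 10 prenasal-maxillary lateral suture
      3.0, 4.3, 2.2,   # 11 nasal-maxillary lateral suture
      13.2, 8.4, 0.9,  # 12 squamosal-maxillary suture
      9.5, 0.0, 0.8,   # 13 sphenethmoid-parasphenoid suture
      16.6, 0.0, 0.6,  # 14 posterior tip of parasphenoid corpus
      0.3, 1.2, 0.9,   # 15 anterior tip of premaxillary bone
      2.6, 3.6, 0.8,   # 16 premaxillary-maxillary suture
      12.4, 7.0, 0.7,  # 17 pterygoid-maxillary suture
      7.8, 2.4, 0.7,   # 18 neopalatine-sphenethmoid suture
      16.6, 4.2, 0.5,  # 19 tip of pterygoid process
      14.6, 1.6, 0.7   # 20 pterygoid-parasphenoid suture
    ), ncol = 3L, byrow = TRUE)
    scheme <- default_landmark_scheme()
    map <- expand_sides(scheme)
    out <- base[map$landmark, , drop = FALSE]
    # left keeps +y, right is the exact mirror image about the midline plane
    out[map$side == "R", 2L] <- -out[map$side == "R", 2L]
    dimnames(out) <- list(NULL, c("x", "y", "z"))
    return(out)
  }
  if (K < 4L) stop("need K >= 4 landmarks")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  repeat {
    tpl <- matrix(stats::runif(K * 3L, 0, 20), ncol = 3L,
                  dimnames = list(NULL, c("x", "y", "z")))
    if (!.any_collinear(tpl)) break
  }
  tpl
}

.any_collinear <- function(x, tol = 1e-2) {
  K <- nrow(x)
  for (i in seq_len(K - 2L)) for (j in (i + 1L):(K - 1L)) for (k in (j + 1L):K) {
    u <- x[j, ] - x[i, ]; v <- x[k, ] - x[i, ]
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    if (sqrt(sum(cr^2)) < tol * sqrt(sum(u^2)) * sqrt(sum(v^2))) return(TRUE)
  }
  FALSE
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Method definition for simulation
#'
#' Describes one measurement method of a simulated study: its digitizing
#' error scale per landmark, an optional systematic per-landmark bias (fixed
#' across individuals and replicates — a method that sees a suture
#' differently sees it differently every time), and its coordinate units.
#'
#' @param label method label (e.g. `"DIG"`).
#' @param error_sd per-coordinate digitizing error SD in mm; scalar or
#'   length-K vector (K side-expanded landmarks).
#' @param bias_sd SD (mm, per coordinate) of the method's systematic
#'   per-landmark bias vectors, drawn once per simulated dataset; 0 = no
#'   bias.
#' @param bias optional explicit K x 3 bias matrix in mm (overrides
#'   `bias_sd`).
#' @param units `"mm"` or `"voxel"`; voxel-unit methods are emitted divided
#'   by `mm_per_unit` so the pipeline must convert them back.
#' @param mm_per_unit pixel size in mm for voxel-unit methods (e.g. 0.01742
#'   for a medium-resolution scan, 0.00871 for high resolution).
#' @return A list of class `sim_method`.
#' @export
sim_method <- function(label, error_sd, bias_sd = 0, bias = NULL,
                       units = c("mm", "voxel"), mm_per_unit = 1) {
  units <- match.arg(units)
  if (any(error_sd < 0) || any(bias_sd < 0)) stop("SDs must be >= 0")
  if (units == "voxel" && mm_per_unit <= 0) stop("mm_per_unit must be > 0")
  structure(list(label = label, error_sd = error_sd, bias_sd = bias_sd,
                 bias = bias, units = units, mm_per_unit = mm_per_unit),
            class = "sim_method")
}

#' Simulation parameters for a replicated multi-method landmark study
#'
#' The defaults emulate the study design the package targets: 20
#' individuals, 2 replicates per individual per method, three methods — a 3D
#' digitizer (`DIG`, larger digitizing error and a systematic per-landmark
#' bias relative to the image-based methods) and two micro-CT resolutions
#' (`MED`, `HIGH`, emitted in voxel units with pixel sizes 0.01742 and
#' 0.00871 mm). Individual shape variation has two components: iid
#' per-coordinate jitter (localized shape differences) and a per-individual
#' lognormal size factor (overall scale differences, CV 4%), so that
#' among-individual distance variance grows with distance length as in real
#' organisms while digitizing error does not. Each configuration optionally
#' lives in its own random rigid frame with a nuisance scale in [0.9, 1.1]
#' (a digitizer arm defines an arbitrary coordinate system per session).
#'
#' @param n_individuals number of individuals (default 20).
#' @param n_replicates replicates per individual per method (default 2).
#' @param methods list of [sim_method()] definitions.
#' @param individual_sd SD (mm, per coordinate) of iid individual shape
#'   jitter (default 0.12).
#' @param individual_size_cv coefficient of variation of the per-individual
#'   size factor (default 0.04; 0 disables size variation).
#' @param template K x 3 mean shape in mm (default [make_template()]
#'   `"toad_like"`).
#' @param rigid_nuisance apply a random rotation and translation to every
#'   configuration (default `TRUE`).
#' @param nuisance_scale_range range of the per-configuration nuisance
#'   scale factor drawn when `rigid_nuisance` is on. Default `c(1, 1)` (no
#'   scale noise): a digitizer arm or a calibrated CT reports true
#'   millimetres, and a per-digitization scale would corrupt the distance
#'   analyses. Set e.g. `c(0.9, 1.1)` to exercise the full similarity
#'   invariance of the Procrustes stages.
#' @param seed integer seed; identical (params, seed) give byte-identical
#'   datasets.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_individuals = 20L, n_replicates = 2L,
                       methods = list(
                         sim_method("DIG", error_sd = 0.06, bias_sd = 0.30),
                         sim_method("MED", error_sd = 0.035, bias_sd = 0.07,
                                    units = "voxel", mm_per_unit = 0.01742),
                         sim_method("HIGH", error_sd = 0.03, bias_sd = 0.07,
                                    units = "voxel", mm_per_unit = 0.00871)
                       ),
                       individual_sd = 0.12, individual_size_cv = 0.04,
                       template = make_template("toad_like"),
                       rigid_nuisance = TRUE,
                       nuisance_scale_range = c(1, 1), seed = 1L) {
  if (n_individuals < 1L || n_replicates < 1L) stop("need >= 1 individuals and replicates")
  if (!length(methods)) stop("need at least one method")
  if (individual_sd < 0 || individual_size_cv < 0) stop("SDs must be >= 0")
  if (centroid_size(template) <= 0) stop("degenerate template")
  if (length(nuisance_scale_range) != 2L || any(nuisance_scale_range <= 0) ||
      nuisance_scale_range[1] > nuisance_scale_range[2])
    stop("nuisance_scale_range must be an increasing positive pair")
  labels <- vapply(methods, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate method labels")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_replicates = as.integer(n_replicates), methods = methods,
                 individual_sd = individual_sd,
                 individual_size_cv = individual_size_cv,
                 template = as.matrix(template),
                 rigid_nuisance = isTRUE(rigid_nuisance),
                 nuisance_scale_range = nuisance_scale_range,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Uniform random proper rotation
#' @keywords internal
.random_rotation <- function() {
  # QR of a Gaussian matrix with sign-fixed diagonal gives a Haar rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Simulate a replicated multi-method landmark dataset
#'
#' Generates data under the error model of [sim_params()]: individual shape
#' = size-scaled template + iid jitter; configuration = individual shape +
#' the method's fixed per-landmark bias + iid digitizing error with the
#' method's per-landmark SD; optionally a random rigid motion and nuisance
#' scale per configuration; voxel-unit methods divided by their pixel size
#' before output. The realized ground truth (individual shapes, biases,
#' error SDs) is returned alongside the dataset.
#'
#' @param params a [sim_params()].
#' @param scheme,distance_scheme schemes attached to the dataset (defaults
#'   match the `toad_like` template).
#' @return A list with `dataset` (a [landmark_dataset()]) and `truth` (list:
#'   `individual_shapes`, `individual_scales`, `biases`, `error_sd`,
#'   `params`, `seed`).
#' @export
simulate_dataset <- function(params = sim_params(),
                             scheme = default_landmark_scheme(),
                             distance_scheme = default_distance_scheme()) {
  K <- nrow(params$template)
  if (K != n_expanded(scheme))
    stop("template size does not match the scheme's side expansion")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  inds <- sprintf("ind%02d", seq_len(params$n_individuals))
  scales <- if (params$individual_size_cv > 0)
    exp(stats::rnorm(params$n_individuals, 0,
                     sqrt(log(1 + params$individual_size_cv^2)))) else
    rep(1, params$n_individuals)
  shapes <- lapply(seq_len(params$n_individuals), function(i)
    params$template * scales[i] +
      matrix(stats::rnorm(K * 3L, 0, params$individual_sd), K, 3L))
  names(shapes) <- inds

  biases <- lapply(params$methods, function(m) {
    if (!is.null(m$bias)) return(as.matrix(m$bias))
    matrix(stats::rnorm(K * 3L, 0, m$bias_sd), K, 3L)
  })
  names(biases) <- vapply(params$methods, `[[`, character(1), "label")
  error_sd <- lapply(params$methods, function(m) rep_len(m$error_sd, K))
  names(error_sd) <- names(biases)

  configs <- list()
  unit_factor <- numeric()
  for (m in params$methods) {
    if (m$units == "voxel") unit_factor[m$label] <- m$mm_per_unit
    for (i in seq_len(params$n_individuals)) {
      for (t in seq_len(params$n_replicates)) {
        X <- shapes[[i]] + biases[[m$label]] +
          matrix(stats::rnorm(K * 3L, 0, 1), K, 3L) * error_sd[[m$label]]
        if (params$rigid_nuisance) {
          R <- .random_rotation()
          s <- stats::runif(1, params$nuisance_scale_range[1],
                            params$nuisance_scale_range[2])
          tr <- stats::rnorm(3L, 0, 10)
          X <- s * X %*% R + matrix(tr, K, 3L, byrow = TRUE)
        }
        if (m$units == "voxel") X <- X / m$mm_per_unit
        configs[[length(configs) + 1L]] <-
          landmark_config(inds[i], m$label, t, X, units = m$units)
      }
    }
  }
  dataset <- landmark_dataset(configs, scheme, distance_scheme, unit_factor)
  truth <- list(individual_shapes = shapes, individual_scales = scales,
                biases = biases, error_sd = error_sd, params = params,
                seed = params$seed)
  list(dataset = dataset, truth = truth)
}

#' Analytic distance repeatability expected under the generator
#'
#' Delta-method prediction of the per-distance repeatability implied by the
#' simulation parameters, valid for isotropic error and no method bias:
#' along a distance's inter-landmark direction, among-individual variance is
#' `2 * individual_sd^2 + (individual_size_cv * L)^2` (jitter at both
#' endpoints plus size scaling of the length `L`) and digitizing-error
#' variance is `sd_a^2 + sd_b^2`. Bilateral averaging halves the independent
#' jitter and error components but not the shared size component.
#'
#' @param params a [sim_params()].
#' @param method method label whose error SDs to use.
#' @param scheme,distance_scheme schemes defining the distances.
#' @return Data frame with columns `distance`, `length_mm`, `var_ind`,
#'   `var_err` and `expected_r`.
#' @export
expected_repeatability <- function(params, method,
                                   scheme = default_landmark_scheme(),
                                   distance_scheme = default_distance_scheme()) {
  idx <- match(method, vapply(params$methods, `[[`, character(1), "label"))
  if (is.na(idx)) stop("method not present: ", method)
  m <- params$methods[[idx]]
  has_bias <- if (!is.null(m$bias)) any(m$bias != 0) else any(m$bias_sd > 0)
  if (has_bias)
    stop("analytic repeatability is only valid without method bias")
  K <- nrow(params$template)
  err <- rep_len(m$error_sd, K)
  map <- expand_sides(scheme)
  tpl <- params$template
  rows <- lapply(seq_len(nrow(distance_scheme)), function(i) {
    a <- distance_scheme$landmark_a[i]; b <- distance_scheme$landmark_b[i]
    both_mid <- all(scheme$position[scheme$landmark %in% c(a, b)] == "midline")
    side <- if (both_mid) "M" else "L"
    ia <- map$index[map$landmark == a & map$side ==
                      if (scheme$position[scheme$landmark == a] == "midline")
                        "M" else side]
    ib <- map$index[map$landmark == b & map$side ==
                      if (scheme$position[scheme$landmark == b] == "midline")
                        "M" else side]
    L <- sqrt(sum((tpl[ia, ] - tpl[ib, ])^2))
    half <- if (both_mid) 1 else 0.5  # bilateral averaging of independent parts
    var_ind <- half * 2 * params$individual_sd^2 +
      (params$individual_size_cv * L)^2
    var_err <- half * (err[ia]^2 + err[ib]^2)
    data.frame(distance = distance_scheme$distance[i], length_mm = L,
               var_ind = var_ind, var_err = var_err,
               expected_r = if (var_ind + var_err == 0) 1 else
                 var_ind / (var_ind + var_err))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
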