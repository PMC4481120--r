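#' Inter-landmark distances of one configuration
#'
#' Euclidean distances between the landmark pairs of a [distance_scheme()],
#' before bilateral averaging. A distance with at least one bilateral
#' endpoint exists on both sides and is computed separately for the left and
#' right side (midline endpoints are shared); a distance between two midline
#' landmarks has a single `"M"` value. Distances touching a masked landmark
#' are returned as `NA`, never as zero.
#'
#' @param config a [landmark_config()] in mm units.
#' @param scheme the [landmark_scheme()] the configuration follows.
#' @param distance_scheme a [distance_scheme()].
#' @return Data frame with columns `distance`, `side` (`"M"`, `"L"`, `"R"`)
#'   and `value` (mm; `NA` when masked). Coincident landmarks yield 0 with a
#'   degeneracy warning.
#' @export
compute_distances <- function(config, scheme,
                              distance_scheme = default_distance_scheme()) {
  if (config$units != "mm")
    stop("configuration is in voxel units; run convert_units() first")
  idx <- .distance_index(scheme, distance_scheme)
  vals <- .distance_values(config, idx)
  out <- data.frame(distance = idx$distance, side = idx$side, value = vals,
                    stringsAsFactors = FALSE)
  if (any(!is.na(out$value) & out$value == 0))
    warning("coincident landmarks: zero-length distance(s) ",
            paste(unique(out$distance[!is.na(out$value) & out$value == 0]),
                  collapse = ", "))
  out
}

# endpoint row indices for every (distance, side) pair; pure function of the
# schemes, computed once per call chain
.distance_index <- function(scheme, distance_scheme) {
  map <- expand_sides(scheme)
  pos <- stats::setNames(scheme$position, scheme$landmark)
  rowidx <- function(id, side) {
    s <- ifelse(pos[as.character(id)] == "midline", "M", side)
    match(paste(id, s), paste(map$landmark, map$side))
  }
  a <- distance_scheme$landmark_a
  b <- distance_scheme$landmark_b
  both_mid <- pos[as.character(a)] == "midline" &
    pos[as.character(b)] == "midline"
  sides <- lapply(both_mid, function(bm) if (bm) "M" else c("L", "R"))
  nrep <- lengths(sides)
  dist_rep <- rep(distance_scheme$distance, nrep)
  side <- unlist(sides, use.names = FALSE)
  a_rep <- rep(a, nrep)
  b_rep <- rep(b, nrep)
  data.frame(distance = dist_rep, side = side,
             ia = rowidx(a_rep, side), ib = rowidx(b_rep, side))
}

.distance_values <- function(config, idx) {
  d <- config$coords[idx$ia, , drop = FALSE] -
    config$coords[idx$ib, , drop = FALSE]
  vals <- sqrt(rowSums(d^2))
  vals[config$missing[idx$ia] | config$missing[idx$ib]] <- NA_real_
  unname(vals)
}

#' Average bilateral distances into one value per distance
#'
#' Replaces the left and right values of each bilateral distance by their
#' mean; midline-only distances pass through unchanged. If one side is
#' masked, the present side is used and the row is flagged `single_side`.
#'
#' @param raw data frame of per-side distances with columns `individual`,
#'   `method`, `replicate`, `distance`, `side`, `value` (as produced by
#'   [distance_table()] internals or by stacking [compute_distances()]
#'   output with its configuration metadata).
#' @return A distance table: data frame with columns `individual`, `method`,
#'   `replicate`, `distance`, `value_mm` and `single_side` (logical), one
#'   row per (individual, method, replicate, distance).
#' @export
average_bilateral <- function(raw) {
  key <- paste(raw$individual, raw$method, raw$replicate, raw$distance,
               sep = "\r")
  g <- match(key, unique(key))
  ok <- !is.na(raw$value)
  sums <- rowsum(ifelse(ok, raw$value, 0), g)[, 1]
  cnt <- rowsum(as.numeric(ok), g)[, 1]
  tot <- rowsum(rep(1, nrow(raw)), g)[, 1]
  first <- which(!duplicated(g))
  out <- data.frame(
    individual = raw$individual[first], method = raw$method[first],
    replicate = raw$replicate[first], distance = raw$distance[first],
    value_mm = ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_),
    single_side = cnt == 1 & tot > 1, stringsAsFactors = FALSE)
  out <- out[order(out$individual, out$method, out$replicate, out$distance), ]
  rownames(out) <- NULL
  out
}

#' Distance table for a whole dataset
#'
#' Convenience wrapper: computes every configuration's inter-landmark
#' distances and averages bilateral pairs, yielding one row per
#' (individual, method, replicate, distance).
#'
#' @param dataset a [landmark_dataset()] in mm units.
#' @return A distance table (see [average_bilateral()]).
#' @export
distance_table <- function(dataset) {
  .assert_mm(dataset)
  idx <- .distance_index(dataset$scheme, dataset$distance_scheme)
  n <- length(dataset$configurations)
  m <- nrow(idx)
  vals <- unlist(lapply(dataset$configurations, .distance_values, idx = idx),
                 use.names = FALSE)
  raw <- data.frame(
    individual = rep(vapply(dataset$configurations, `[[`, character(1),
                            "individual"), each = m),
    method = rep(vapply(dataset$configurations, `[[`, character(1),
                        "method"), each = m),
    replicate = rep(vapply(dataset$configurations, `[[`, integer(1),
                           "replicate"), each = m),
    distance = rep(idx$distance, n), side = rep(idx$side, n),
    value = vals, stringsAsFactors = FALSE)
  average_bilateral(raw)
}

#' Gross-error screening configuration
#'
#' Replicate-to-replicate differences above 0.5 mm are treated as gross
#' digitizing errors for most distances; distances whose method-wise mean is
#' below 3.0 mm are screened at 0.3 mm instead (small distances carry
#' proportionally more error, so a tighter absolute rule applies). An
#' explicit id list can override the mean-driven rule.
#'
#' @param default_threshold mm, flag threshold for ordinary distances (0.5).
#' @param small_threshold mm, flag threshold for small distances (0.3).
#' @param small_mean_cutoff mm, method-wise mean below which a distance is
#'   treated as small (3.0).
#' @param small_distance_ids optional integer vector of distance ids always
#'   screened at `small_threshold`, regardless of the observed mean.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(default_threshold = 0.5, small_threshold = 0.3,
                      small_mean_cutoff = 3.0, small_distance_ids = NULL) {
  if (default_threshold <= 0 || small_threshold <= 0)
    stop("thresholds must be > 0")
  if (small_threshold > default_threshold)
    stop("small_threshold must not exceed default_threshold")
  structure(list(default_threshold = default_threshold,
                 small_threshold = small_threshold,
                 small_mean_cutoff = small_mean_cutoff,
                 small_distance_ids = as.integer(small_distance_ids)),
            class = "qc_config")
}

#' Screen replicate pairs for gross measurement error
#'
#' Compares the absolute difference between every within-method replicate
#' pair of each distance against its threshold (see [qc_config()]) and
#' lists all violations. Nothing is corrected automatically: a flagged pair
#' signals that the underlying landmarks should be re-placed and the
#' distance re-measured.
#'
#' @param table a distance table (see [distance_table()]).
#' @param qc a [qc_config()].
#' @return An object of class `qc_report`: a data frame of flags with
#'   columns `individual`, `method`, `distance`, `replicate_a`,
#'   `replicate_b`, `abs_difference` and `threshold_used`. Zero rows means
#'   no violation.
#' @export
flag_gross_errors <- function(table, qc = qc_config()) {
  meankey <- paste(table$method, table$distance, sep = "\r")
  method_means <- tapply(table$value_mm, meankey, mean, na.rm = TRUE)
  flags <- list()
  grp <- split(table, paste(table$individual, table$method, table$distance,
                            sep = "\r"))
  single_only <- TRUE
  for (g in grp) {
    g <- g[order(g$replicate), , drop = FALSE]
    if (nrow(g) < 2L) next
    single_only <- FALSE
    m <- method_means[[paste(g$method[1], g$distance[1], sep = "\r")]]
    small <- (is.finite(m) && m < qc$small_mean_cutoff) ||
      g$distance[1] %in% qc$small_distance_ids
    thr <- if (small) qc$small_threshold else qc$default_threshold
    pairs <- utils::combn(seq_len(nrow(g)), 2L)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      d <- abs(g$value_mm[i] - g$value_mm[j])
      if (is.finite(d) && d > thr)
        flags[[length(flags) + 1L]] <- data.frame(
          individual = g$individual[1], method = g$method[1],
          distance = g$distance[1], replicate_a = g$replicate[i],
          replicate_b = g$replicate[j], abs_difference = d,
          threshold_used = thr, stringsAsFactors = FALSE)
    }
  }
  if (single_only)
    warning("no (individual, method, distance) group has 2+ replicates; ",
            "gross-error screening needs replicated measurements")
  out <- if (length(flags)) do.call(rbind, flags) else
    data.frame(individual = character(), method = character(),
               distance = integer(), replicate_a = integer(),
               replicate_b = integer(), abs_difference = numeric(),
               threshold_used = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("qc_report", "data.frame")
  out
}

#' @export
print.qc_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("Gross-error screen: no violations\n")
  } else {
    cat("Gross-error screen:", nrow(x), "violation(s)\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}
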