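#' One-way ANOVA variance components
#'
#' Decomposes replicated measurements into among-group and residual variance
#' via one-way ANOVA mean squares: `s2 = MS_within` and
#' `s2_A = (MS_among - MS_within) / k0`, where `k0` is the replicate count
#' for balanced designs and Sokal & Rohlf's effective group size
#' `(N - sum(n_i^2)/N) / (a - 1)` otherwise. A negative among-group estimate
#' is clipped to zero (flagged, raw value retained) so that the
#' repeatability `r = s2_A / (s2 + s2_A)` stays in `[0, 1]`.
#'
#' @param group vector of group ids (one group per individual).
#' @param value numeric measurements.
#' @param permissive drop groups with a single value (with a warning)
#'   instead of erroring.
#' @return An object of class `variance_components`: list with `s2_A`, `s2`,
#'   `s2_A_raw`, `ms_among`, `ms_within`, `n_groups`, `k` (the effective
#'   replicate count used), `balanced`, `clipped` and `r`. When both
#'   components are zero, `r` is defined as 0.
#' @examples
#' vc <- variance_components(c("A", "A", "B", "B"), c(1, 3, 5, 7))
#' vc$r  # 7/9
#' @export
variance_components <- function(group, value, permissive = FALSE) {
  keep <- is.finite(value)
  group <- factor(group[keep])
  value <- value[keep]
  sizes <- table(group)
  if (any(sizes < 2L)) {
    if (!permissive)
      stop("group(s) with a single value: ",
           paste(names(sizes)[sizes < 2L], collapse = ", "),
           " (use permissive = TRUE to drop them)")
    warning("dropping group(s) with a single value: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
    ok <- group %in% names(sizes)[sizes >= 2L]
    group <- droplevels(group[ok]); value <- value[ok]
    sizes <- table(group)
  }
  a <- nlevels(group)
  if (a < 2L) stop("need at least 2 groups")
  N <- length(value)
  if (stats::var(value) == 0) {
    vc <- list(s2_A = 0, s2 = 0, s2_A_raw = 0, ms_among = 0, ms_within = 0,
               n_groups = a, k = N / a, balanced = length(unique(sizes)) == 1L,
               clipped = FALSE, r = 0)
    class(vc) <- "variance_components"
    return(vc)
  }
  aov_tab <- withCallingHandlers(
    stats::anova(stats::lm(value ~ group)),
    warning = function(w) {
      # zero residual variance is a legitimate degenerate case here
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ms_among <- aov_tab[["Mean Sq"]][1]
  ms_within <- aov_tab[["Mean Sq"]][2]
  balanced <- length(unique(as.integer(sizes))) == 1L
  k0 <- if (balanced) as.integer(sizes[1]) else
    (N - sum(sizes^2) / N) / (a - 1)
  s2_A_raw <- (ms_among - ms_within) / k0
  clipped <- s2_A_raw < 0
  s2_A <- max(s2_A_raw, 0)
  s2 <- ms_within
  r <- if (s2 + s2_A == 0) 0 else s2_A / (s2 + s2_A)
  vc <- list(s2_A = s2_A, s2 = s2, s2_A_raw = s2_A_raw, ms_among = ms_among,
             ms_within = ms_within, n_groups = a, k = k0,
             balanced = balanced, clipped = clipped, r = r)
  class(vc) <- "variance_components"
  vc
}

#' @export
print.variance_components <- function(x, ...) {
  cat("One-way variance components:", x$n_groups, "groups, k =", x$k,
      if (!x$balanced) "(unbalanced)" else "", "\n")
  cat("  s2_A =", format(x$s2_A), " s2 =", format(x$s2),
      if (x$clipped) " [among-group estimate clipped at 0]" else "", "\n")
  cat("  repeatability r =", format(x$r), "\n")
  invisible(x)
}

.repeatability_report <- function(table, label, methods) {
  per <- lapply(split(table, table$distance), function(g) {
    vc <- variance_components(g$individual, g$value_mm)
    data.frame(distance = g$distance[1], r = vc$r, s2_A = vc$s2_A,
               s2 = vc$s2, n_groups = vc$n_groups, k = vc$k,
               clipped = vc$clipped, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  per <- per[order(per$distance), , drop = FALSE]
  rownames(per) <- NULL
  structure(list(label = label, methods = methods, per_distance = per,
                 mean_r = mean(per$r), sd_r = stats::sd(per$r)),
            class = "repeatability_report")
}

#' Within-method distance repeatability
#'
#' Per-distance repeatability treating each individual as a group and its
#' replicate measurements under one method as the group's values:
#' `r = s2_A / (s2 + s2_A)` from one-way ANOVA variance components. High
#' `r` means differences among individuals dominate digitizing noise, i.e.
#' the measuring protocol is reliable.
#'
#' @param table a distance table (see [distance_table()]).
#' @param method method label.
#' @return An object of class `repeatability_report`: `per_distance` data
#'   frame (distance, r, variance components), `mean_r`, `sd_r` and `label`.
#' @export
within_method_repeatability <- function(table, method) {
  tab <- table[table$method == method, , drop = FALSE]
  if (!nrow(tab)) stop("method not present: ", method)
  .repeatability_report(tab, label = method, methods = method)
}

#' Between-method distance repeatability
#'
#' Pools the replicates of two methods for every individual measured by
#' both (e.g. 2 + 2 = 4 values per individual) and computes the same
#' ANOVA-based repeatability. A drop relative to the within-method values
#' quantifies the disagreement between the two measuring protocols beyond
#' their internal noise.
#'
#' @param table a distance table.
#' @param method_a,method_b the two method labels to join.
#' @return A `repeatability_report` labeled `"A + B"`.
#' @export
between_method_repeatability <- function(table, method_a, method_b) {
  ta <- table[table$method == method_a, , drop = FALSE]
  tb <- table[table$method == method_b, , drop = FALSE]
  if (!nrow(ta)) stop("method not present: ", method_a)
  if (!nrow(tb)) stop("method not present: ", method_b)
  shared <- intersect(unique(ta$individual), unique(tb$individual))
  if (!length(shared)) stop("no shared individuals between ", method_a,
                            " and ", method_b)
  tab <- rbind(ta[ta$individual %in% shared, ],
               tb[tb$individual %in% shared, ])
  .repeatability_report(tab, label = paste(method_a, "+", method_b),
                        methods = c(method_a, method_b))
}

#' @export
print.repeatability_report <- function(x, digits = 3, ...) {
  cat("Distance repeatability -", x$label, "\n")
  cat("  mean r =", format(round(x$mean_r, digits)), "+/-",
      format(round(x$sd_r, digits)), "(SD across distances)\n")
  print(format(x$per_distance, digits = digits), row.names = FALSE)
  invisible(x)
}
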