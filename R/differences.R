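#' Raw and absolute differences between replicates within one method
#'
#' For each distance, subtracts replicate 2 from replicate 1 of every
#' individual (replicate order as numbered) and averages the raw and the
#' absolute differences across individuals. Raw means near zero indicate no
#' systematic drift between replicates; the absolute mean measures the
#' magnitude of digitizing noise irrespective of direction. With more than
#' two replicates, consecutive pairs are used (flagged in the report).
#' Individuals missing a replicate are skipped with a warning.
#'
#' @param table a distance table (see [distance_table()]).
#' @param method method label.
#' @return An object of class `difference_report`: `per_distance` data
#'   frame (distance, mean_raw, sd_raw, mean_abs, sd_abs, n,
#'   pct_of_mean = `NA` until [percentage_error()] fills it), `summary`
#'   (mean and SD across distances of each column) and `label`. The sign
#'   convention (first minus second) is recorded in `label`.
#' @export
within_method_differences <- function(table, method) {
  tab <- table[table$method == method, , drop = FALSE]
  if (!nrow(tab)) stop("method not present: ", method)
  diffs <- lapply(split(tab, tab$distance), function(g) {
    per_ind <- vapply(split(g, g$individual), function(h) {
      h <- h[order(h$replicate), , drop = FALSE]
      if (nrow(h) < 2L) return(NA_real_)
      # consecutive-pair convention; a 2-replicate design gives rep1 - rep2
      mean(h$value_mm[-nrow(h)] - h$value_mm[-1L])
    }, numeric(1))
    if (anyNA(per_ind))
      warning("individual(s) without a replicate pair skipped for distance ",
              g$distance[1])
    per_ind <- per_ind[!is.na(per_ind)]
    data.frame(distance = g$distance[1], mean_raw = mean(per_ind),
               sd_raw = stats::sd(per_ind), mean_abs = mean(abs(per_ind)),
               sd_abs = stats::sd(abs(per_ind)), n = length(per_ind),
               stringsAsFactors = FALSE)
  })
  .difference_report(do.call(rbind, diffs),
                     label = paste0(method, " (replicate 1 - replicate 2)"),
                     methods = method)
}

#' Raw and absolute differences between two methods
#'
#' For every individual measured by both methods, each distance is reduced
#' to the mean over that method's replicates and the difference
#' `method_a - method_b` is taken; raw and absolute differences are averaged
#' across the shared individuals. Raw means near zero show the methods share
#' no consistent bias; the absolute mean is the magnitude of between-method
#' disagreement.
#'
#' @param table a distance table.
#' @param method_a,method_b method labels; the difference is
#'   `method_a - method_b`.
#' @param use_replicate_means use the mean over replicates per individual
#'   (default); `FALSE` uses replicate 1 only.
#' @return A `difference_report` (see [within_method_differences()]).
#' @export
between_method_differences <- function(table, method_a, method_b,
                                       use_replicate_means = TRUE) {
  ta <- table[table$method == method_a, , drop = FALSE]
  tb <- table[table$method == method_b, , drop = FALSE]
  if (!nrow(ta)) stop("method not present: ", method_a)
  if (!nrow(tb)) stop("method not present: ", method_b)
  shared <- intersect(unique(ta$individual), unique(tb$individual))
  if (!length(shared)) stop("no shared individuals between ", method_a,
                            " and ", method_b)
  reduce <- function(t) {
    t <- t[t$individual %in% shared, , drop = FALSE]
    if (!use_replicate_means)
      t <- t[t$replicate == min(t$replicate), , drop = FALSE]
    key <- paste(t$individual, t$distance, sep = "\r")
    agg <- tapply(t$value_mm, key, mean)
    data.frame(key = names(agg), value = as.numeric(agg),
               stringsAsFactors = FALSE)
  }
  va <- reduce(ta); vb <- reduce(tb)
  m <- merge(va, vb, by = "key", suffixes = c("_a", "_b"))
  parts <- strsplit(m$key, "\r", fixed = TRUE)
  m$distance <- as.integer(vapply(parts, `[`, character(1), 2L))
  m$diff <- m$value_a - m$value_b
  diffs <- lapply(split(m, m$distance), function(g)
    data.frame(distance = g$distance[1], mean_raw = mean(g$diff),
               sd_raw = stats::sd(g$diff), mean_abs = mean(abs(g$diff)),
               sd_abs = stats::sd(abs(g$diff)), n = nrow(g),
               stringsAsFactors = FALSE))
  .difference_report(do.call(rbind, diffs),
                     label = paste(method_a, "-", method_b),
                     methods = c(method_a, method_b))
}

.difference_report <- function(per, label, methods) {
  per <- per[order(per$distance), , drop = FALSE]
  per$pct_of_mean <- NA_real_
  rownames(per) <- NULL
  structure(list(label = label, methods = methods, per_distance = per,
                 summary = .diff_summary(per)),
            class = "difference_report")
}

.diff_summary <- function(per) {
  cols <- c("mean_raw", "mean_abs", "pct_of_mean")
  data.frame(
    statistic = cols,
    mean = vapply(cols, function(cl) mean(per[[cl]]), numeric(1)),
    sd = vapply(cols, function(cl) stats::sd(per[[cl]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Percentage error relative to distance means
#'
#' Expresses each distance's mean absolute difference as a percentage of
#' that distance's mean length: `100 * mean_abs / mean`. The report-level
#' "% of mean" is the mean and SD of the per-distance percentages (not the
#' ratio of summary means). The distance mean is taken over all rows of
#' `table` belonging to the methods involved in the report.
#'
#' @param report a `difference_report`.
#' @param table the distance table the report was computed from.
#' @return The report with `pct_of_mean` filled (masked `NA` where a
#'   distance mean is zero) and its summary updated.
#' @export
percentage_error <- function(report, table) {
  tab <- table[table$method %in% report$methods, , drop = FALSE]
  if (!nrow(tab)) tab <- table
  dmeans <- tapply(tab$value_mm, tab$distance, mean, na.rm = TRUE)
  per <- report$per_distance
  m <- as.numeric(dmeans[as.character(per$distance)])
  per$pct_of_mean <- ifelse(is.finite(m) & m > 0,
                            100 * per$mean_abs / m, NA_real_)
  report$per_distance <- per
  report$summary <- .diff_summary(per)
  report
}

#' @export
print.difference_report <- function(x, digits = 3, ...) {
  cat("Distance differences -", x$label, "\n")
  print(format(x$per_distance, digits = digits), row.names = FALSE)
  cat("Across distances:\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Correlation between distance repeatability and distance length
#'
#' Pearson correlation (two-sided t-test, df = n - 2, alpha 0.05) between
#' per-distance repeatability and per-distance mean length. When landmark
#' error is homogeneous in mm, small distances carry proportionally more
#' error and lower repeatability, producing a positive association.
#'
#' @param rep_report a `repeatability_report`.
#' @param table the distance table the repeatabilities came from (mean
#'   lengths are computed from the methods in the report label).
#' @param alpha significance level recorded in the result (default 0.05).
#' @return A list of class `correlation_result`: `r`, `df`, `t_statistic`,
#'   `p_value`, `alpha`, `significant`, `n`.
#' @export
repeatability_length_correlation <- function(rep_report, table,
                                             alpha = 0.05) {
  methods <- rep_report$methods
  if (is.null(methods)) methods <- unique(table$method)
  tab <- table[table$method %in% methods, , drop = FALSE]
  if (!nrow(tab)) tab <- table
  dmeans <- tapply(tab$value_mm, tab$distance, mean, na.rm = TRUE)
  per <- rep_report$per_distance
  len <- as.numeric(dmeans[as.character(per$distance)])
  if (length(len) < 3L) stop("need at least 3 distances")
  if (stats::sd(per$r) == 0 || stats::sd(len) == 0)
    stop("zero variance in repeatability or length: correlation undefined")
  ct <- stats::cor.test(per$r, len, method = "pearson",
                        alternative = "two.sided")
  structure(list(r = unname(ct$estimate), df = unname(ct$parameter),
                 t_statistic = unname(ct$statistic),
                 p_value = ct$p.value, alpha = alpha,
                 significant = ct$p.value < alpha, n = length(len)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f, d.f. = %d, P = %.4g%s\n",
              x$r, x$df, x$p_value,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}
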