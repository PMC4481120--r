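#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the input data (either an
#' in-memory [landmark_dataset()] or a file path + dialect), unit factors
#' for voxel-unit methods, QC thresholds, GPA tolerances, which analyses to
#' run, which method pairs to join for the between-method analyses, and an
#' output directory.
#'
#' @param dataset a [landmark_dataset()] (alternative to `input`).
#' @param input path readable by [read_landmark_table()].
#' @param dialect dialect for `input`.
#' @param unit_factors named vector of mm-per-unit factors applied with
#'   [convert_units()] to any method still in voxel units.
#' @param qc a [qc_config()].
#' @param gpa_tol,gpa_max_iter GPA convergence controls.
#' @param use_sides landmark subset for the precision analysis.
#' @param analyses character subset of
#'   `c("qc", "precision", "repeatability", "differences", "correlation")`.
#' @param between_pairs list of character 2-vectors naming method pairs to
#'   join; `NULL` means all pairs of observed methods.
#' @param output_dir directory for the CSV/JSON reports.
#' @param strict_qc abort when the gross-error screen finds violations
#'   (default `FALSE`: violations are reported but non-fatal).
#' @param seed integer recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters when the caller simulates the input).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = NULL, input = NULL,
                            dialect = "long_csv", unit_factors = numeric(),
                            qc = qc_config(), gpa_tol = 1e-10,
                            gpa_max_iter = 100L,
                            use_sides = "midline_and_left",
                            analyses = c("qc", "precision", "repeatability",
                                         "differences", "correlation"),
                            between_pairs = NULL, output_dir = NULL,
                            strict_qc = FALSE, seed = 1L) {
  if (is.null(dataset) && is.null(input))
    stop("provide either a dataset or an input path")
  if (!is.null(input) && !file.exists(input) && !dir.exists(input))
    stop("input path does not exist: ", input)
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(dataset = dataset, input = input, dialect = dialect,
                 unit_factors = unit_factors, qc = qc, gpa_tol = gpa_tol,
                 gpa_max_iter = as.integer(gpa_max_iter),
                 use_sides = use_sides, analyses = analyses,
                 between_pairs = between_pairs, output_dir = output_dir,
                 strict_qc = isTRUE(strict_qc), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full measurement-error pipeline
#'
#' Stage order: read (or take) the dataset, convert voxel-unit methods to
#' mm, extract bilateral-averaged distances and screen replicate pairs for
#' gross errors, run the leave-one-landmark-out precision analysis per
#' method, compute within-method and between-method distance
#' repeatabilities, the raw/absolute/percentage difference reports, and the
#' repeatability-versus-length correlations. Each stage failure aborts with
#' a stage-named message; QC violations are listed but non-fatal unless
#' `strict_qc`. When `output_dir` is set, CSV tables, a JSON summary and a
#' plain-text run log are written; reruns with the same config and inputs
#' are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `dataset`,
#'   `distance_table`, `qc`, `precision`, `repeatability_within`,
#'   `repeatability_between`, `differences_within`, `differences_between`,
#'   `correlations` and `summary`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_lines <- c(
    paste0("landmarkprec ",
           as.character(utils::packageVersion("landmarkprec")),
           " | R ", getRversion()),
    paste0("seed: ", config$seed),
    paste0("use_sides: ", config$use_sides),
    paste0("analyses: ", paste(config$analyses, collapse = ", ")))

  dataset <- stage("read", {
    if (!is.null(config$dataset)) config$dataset else
      read_landmark_table(config$input, config$dialect)
  })

  dataset <- stage("convert_units", {
    for (m in dataset_methods(dataset)) {
      units <- vapply(Filter(function(cf) cf$method == m,
                             dataset$configurations),
                      `[[`, character(1), "units")
      if (any(units == "voxel")) {
        fac <- if (m %in% names(config$unit_factors))
          config$unit_factors[[m]] else dataset$unit_factor[[m]]
        dataset <- convert_units(dataset, m, fac)
        log_lines <- c(log_lines,
                       sprintf("converted %s from voxel units (x %g mm)",
                               m, fac))
      }
    }
    dataset
  })

  methods <- dataset_methods(dataset)
  dtab <- stage("distances", distance_table(dataset))

  qc_rep <- NULL
  if ("qc" %in% config$analyses) {
    qc_rep <- stage("qc", flag_gross_errors(dtab, config$qc))
    log_lines <- c(log_lines, sprintf("qc: %d violation(s)", nrow(qc_rep)))
    if (config$strict_qc && nrow(qc_rep))
      stop("pipeline stage 'qc' failed: ", nrow(qc_rep),
           " gross-error violation(s) under --strict-qc", call. = FALSE)
  }

  precision <- NULL
  if ("precision" %in% config$analyses)
    precision <- stage("precision",
      lapply(stats::setNames(methods, methods), function(m)
        landmark_precision_report(dataset, m, use_sides = config$use_sides,
                                  tol = config$gpa_tol,
                                  max_iter = config$gpa_max_iter)))

  pairs <- config$between_pairs
  if (is.null(pairs) && length(methods) > 1L) {
    cmb <- utils::combn(methods, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  pair_label <- function(p) paste(p[1], "+", p[2])

  rep_within <- rep_between <- NULL
  if ("repeatability" %in% config$analyses) {
    rep_within <- stage("repeatability",
      lapply(stats::setNames(methods, methods), function(m)
        within_method_repeatability(dtab, m)))
    if (length(pairs))
      rep_between <- stage("repeatability", {
        out <- lapply(pairs, function(p)
          between_method_repeatability(dtab, p[1], p[2]))
        stats::setNames(out, vapply(pairs, pair_label, character(1)))
      })
  }

  diff_within <- diff_between <- NULL
  if ("differences" %in% config$analyses) {
    diff_within <- stage("differences",
      lapply(stats::setNames(methods, methods), function(m)
        percentage_error(within_method_differences(dtab, m), dtab)))
    if (length(pairs))
      diff_between <- stage("differences", {
        out <- lapply(pairs, function(p)
          percentage_error(between_method_differences(dtab, p[1], p[2]),
                           dtab))
        stats::setNames(out, vapply(pairs, function(p)
          paste(p[1], "-", p[2]), character(1)))
      })
  }

  correlations <- NULL
  if ("correlation" %in% config$analyses && !is.null(rep_between))
    correlations <- stage("correlation",
      lapply(rep_between, repeatability_length_correlation, table = dtab))

  summarize <- function() {
    s <- list(n_configurations = length(dataset$configurations),
              methods = methods,
              n_distances = nrow(dataset$distance_scheme),
              qc_violations = if (is.null(qc_rep)) NA_integer_ else
                nrow(qc_rep))
    if (!is.null(rep_within))
      s$mean_r_within <- vapply(rep_within, `[[`, numeric(1), "mean_r")
    if (!is.null(rep_between))
      s$mean_r_between <- vapply(rep_between, `[[`, numeric(1), "mean_r")
    if (!is.null(precision))
      s$mean_deviation_mm <- vapply(precision, function(p)
        mean(p$per_landmark$mean_deviation_mm), numeric(1))
    if (!is.null(correlations))
      s$repeatability_length_r <- vapply(correlations, `[[`, numeric(1), "r")
    s
  }
  result <- structure(
    list(dataset = dataset, distance_table = dtab, qc = qc_rep,
         precision = precision, repeatability_within = rep_within,
         repeatability_between = rep_between,
         differences_within = diff_within,
         differences_between = diff_between, correlations = correlations,
         summary = summarize(), log = log_lines),
    class = "pipeline_result")

  if (!is.null(config$output_dir))
    .write_pipeline_reports(result, config$output_dir)
  result
}

.write_pipeline_reports <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wcsv(result$distance_table, "distances.csv")
  if (!is.null(result$qc)) wcsv(as.data.frame(result$qc), "qc_flags.csv")
  if (!is.null(result$precision)) {
    prec <- do.call(rbind, lapply(result$precision, function(p)
      cbind(method = p$method, p$per_landmark,
            mean_centroid_size_mm = p$mean_centroid_size_mm)))
    wcsv(prec, "precision.csv")
  }
  bindrep <- function(reps) do.call(rbind, lapply(reps, function(r)
    cbind(dataset_label = r$label, r$per_distance)))
  if (!is.null(result$repeatability_within) ||
      !is.null(result$repeatability_between)) {
    rep_all <- rbind(
      if (!is.null(result$repeatability_within))
        bindrep(result$repeatability_within),
      if (!is.null(result$repeatability_between))
        bindrep(result$repeatability_between))
    wcsv(rep_all, "repeatability.csv")
  }
  binddiff <- function(reps) do.call(rbind, lapply(reps, function(r)
    cbind(pairing = r$label, r$per_distance)))
  if (!is.null(result$differences_within))
    wcsv(binddiff(result$differences_within), "differences_within.csv")
  if (!is.null(result$differences_between))
    wcsv(binddiff(result$differences_between), "differences_between.csv")
  if (!is.null(result$correlations)) {
    cors <- do.call(rbind, lapply(names(result$correlations), function(nm) {
      ct <- result$correlations[[nm]]
      data.frame(pairing = nm, r = ct$r, df = ct$df,
                 t_statistic = ct$t_statistic, p_value = ct$p_value,
                 significant = ct$significant, stringsAsFactors = FALSE)
    }))
    wcsv(cors, "correlations.csv")
  }
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", x$summary$n_configurations, "configurations,",
      length(x$summary$methods), "methods\n")
  if (!is.null(x$summary$mean_r_within)) {
    cat("  mean within-method r: ",
        paste(sprintf("%s=%.3f", names(x$summary$mean_r_within),
                      x$summary$mean_r_within), collapse = ", "), "\n")
  }
  if (!is.null(x$summary$mean_r_between)) {
    cat("  mean between-method r:",
        paste(sprintf("%s=%.3f", names(x$summary$mean_r_between),
                      x$summary$mean_r_between), collapse = ", "), "\n")
  }
  invisible(x)
}
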