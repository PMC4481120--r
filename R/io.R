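#' Read replicated landmark data
#'
#' Reads a replicated landmark study table in one of three dialects and
#' returns a [landmark_dataset()] in canonical order. The reference dialect
#' is `long_csv`: a UTF-8 CSV with header
#' `individual,method,replicate,landmark,side,x,y,z` and `side` in
#' `{M, L, R}`. `txt_block` reads one whitespace-separated `x y z` file per
#' configuration (the canonical side-expanded row order), taking individual,
#' method and replicate from the filename pattern
#' `<individual>_<method>_<replicate>.txt`. `tps` reads standard `LM3`
#' records (import-only); the `ID =` line supplies the individual while
#' method and replicate are supplied by the caller.
#'
#' Row order in the file never affects the result: rows are mapped to the
#' canonical side-expanded order defined by the scheme. `NA` coordinates are
#' read back as masked landmarks.
#'
#' @param path file path (`long_csv`, `tps`) or directory / vector of file
#'   paths (`txt_block`).
#' @param dialect one of `"long_csv"`, `"txt_block"`, `"tps"`.
#' @param scheme a [landmark_scheme()]; default the bundled 20-landmark
#'   scheme.
#' @param distance_scheme a [distance_scheme()] attached to the result.
#' @param units coordinate units of the file(s), `"mm"` or `"voxel"`
#'   (`txt_block` and `tps` only; `long_csv` is always written in the units
#'   the dataset carried, recorded per method via `unit_factor`).
#' @param method,replicate method label(s) and replicate number(s) for
#'   `tps` records, recycled along records.
#' @param unit_factor named numeric vector of mm-per-unit factors attached
#'   to the dataset.
#' @return A [landmark_dataset()].
#' @export
read_landmark_table <- function(path,
                                dialect = c("long_csv", "txt_block", "tps"),
                                scheme = default_landmark_scheme(),
                                distance_scheme = default_distance_scheme(),
                                units = "mm", method = NULL, replicate = NULL,
                                unit_factor = numeric()) {
  dialect <- match.arg(dialect)
  configs <- switch(dialect,
    long_csv = .read_long_csv(path, scheme),
    txt_block = .read_txt_block(path, scheme, units),
    tps = .read_tps(path, scheme, units, method, replicate)
  )
  landmark_dataset(configs, scheme, distance_scheme, unit_factor)
}

.read_long_csv <- function(path, scheme) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(individual = "character",
                                       method = "character"))
  required <- c("individual", "method", "replicate", "landmark", "side",
                "x", "y", "z")
  if (!all(required %in% names(df)))
    stop("long_csv needs columns: ", paste(required, collapse = ","))
  if (nrow(df) == 0L) return(list())
  if (!all(df$side %in% c("M", "L", "R")))
    stop("side must be one of M, L, R")
  keyrow <- paste(df$individual, df$method, df$replicate, df$landmark,
                  df$side, sep = "\r")
  if (anyDuplicated(keyrow))
    stop("duplicate (individual, method, replicate, landmark, side) row: ",
         gsub("\r", "/", keyrow[duplicated(keyrow)][1]))
  map <- expand_sides(scheme)
  mapkey <- paste(map$landmark, map$side)
  cfgkey <- paste(df$individual, df$method, df$replicate, sep = "\r")
  lapply(split(seq_len(nrow(df)), cfgkey), function(idx) {
    block <- df[idx, , drop = FALSE]
    pos <- match(mapkey, paste(block$landmark, block$side))
    if (anyNA(pos))
      stop("ragged landmark counts across configurations; offender: ",
           gsub("\r", "/", cfgkey[idx[1]]))
    coords <- as.matrix(block[pos, c("x", "y", "z")])
    miss <- apply(coords, 1L, function(r) anyNA(r))
    landmark_config(block$individual[1], block$method[1], block$replicate[1],
                    coords, units = "mm", missing = miss)
  })
}

.read_txt_block <- function(path, scheme, units) {
  files <- path
  if (length(path) == 1L && dir.exists(path))
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
  if (!length(files)) stop("no txt files found under ", path)
  lapply(files, function(f) {
    if (!file.exists(f)) stop("file not found: ", f)
    stem <- sub("\\.txt$", "", basename(f))
    parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("txt_block filename must be <individual>_<method>_<replicate>.txt: ",
           basename(f))
    repl <- suppressWarnings(as.integer(parts[length(parts)]))
    if (is.na(repl)) stop("non-integer replicate in filename: ", basename(f))
    method <- parts[length(parts) - 1L]
    individual <- paste(parts[seq_len(length(parts) - 2L)], collapse = "_")
    coords <- as.matrix(utils::read.table(f, header = FALSE,
                                          col.names = c("x", "y", "z"),
                                          na.strings = "NA"))
    miss <- apply(coords, 1L, function(r) anyNA(r))
    landmark_config(individual, method, repl, coords, units = units,
                    missing = miss)
  })
}

.read_tps <- function(path, scheme, units, method, replicate) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LM3\\s*=", lines)
  if (!length(starts)) stop("no LM3 records found in ", path)
  if (is.null(method)) stop("tps dialect requires a method label")
  method <- rep_len(as.character(method), length(starts))
  replicate <- rep_len(if (is.null(replicate)) 1L else as.integer(replicate),
                       length(starts))
  lapply(seq_along(starts), function(j) {
    s <- starts[j]
    K <- as.integer(sub("^LM3\\s*=\\s*", "", lines[s]))
    block <- lines[(s + 1L):(s + K)]
    coords <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"),
                                    function(v) as.numeric(v[1:3])))
    idline <- grep("^ID\\s*=", lines[(s + K + 1L):min(s + K + 3L, length(lines))],
                   value = TRUE)
    individual <- if (length(idline)) sub("^ID\\s*=\\s*", "", idline[1]) else
      as.character(j)
    miss <- apply(coords, 1L, function(r) anyNA(r))
    landmark_config(individual, method[j], replicate[j], coords,
                    units = units, missing = miss)
  })
}

#' Write replicated landmark data
#'
#' Serializes a [landmark_dataset()] so that reading the file(s) back
#' reproduces the dataset exactly (round trip). Masked landmarks are written
#' as `NA` and recovered as masked. Coordinates are written with 17
#' significant digits so doubles survive the round trip bit-identically.
#'
#' @param dataset a [landmark_dataset()].
#' @param path output file (`long_csv`) or directory (`txt_block`).
#' @param dialect `"long_csv"` or `"txt_block"`.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(dataset, path,
                                 dialect = c("long_csv", "txt_block")) {
  dialect <- match.arg(dialect)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  if (dialect == "long_csv") {
    map <- expand_sides(dataset$scheme)
    rows <- lapply(dataset$configurations, function(cf) {
      coords <- cf$coords
      coords[cf$missing, ] <- NA_real_
      data.frame(individual = cf$individual, method = cf$method,
                 replicate = cf$replicate, landmark = map$landmark,
                 side = map$side,
                 x = fmt(coords[, 1]), y = fmt(coords[, 2]),
                 z = fmt(coords[, 3]), stringsAsFactors = FALSE)
    })
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(individual = character(), method = character(),
                 replicate = integer(), landmark = integer(),
                 side = character(), x = character(), y = character(),
                 z = character(), stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (cf in dataset$configurations) {
      coords <- cf$coords
      coords[cf$missing, ] <- NA_real_
      f <- file.path(path, paste0(cf$individual, "_", cf$method, "_",
                                  cf$replicate, ".txt"))
      writeLines(paste(fmt(coords[, 1]), fmt(coords[, 2]), fmt(coords[, 3])),
                 f)
    }
  }
  invisible(path)
}

#' Convert a method's coordinates from voxel units to mm
#'
#' Coordinates digitized on CT cross-sections are in pixel/voxel units until
#' multiplied by the scan resolution's pixel size in mm (e.g. 0.01742 mm for
#' a medium-resolution scan, 0.00871 mm for high resolution). Conversion is
#' linear, so inter-landmark distances computed after conversion equal
#' `factor` times the distances computed before. Converting a method already
#' in mm is refused.
#'
#' @param dataset a [landmark_dataset()].
#' @param method method label whose configurations are in voxel units.
#' @param factor mm per coordinate unit (> 0); defaults to the factor stored
#'   in the dataset's `unit_factor` for that method.
#' @return The dataset with that method's coordinates in mm.
#' @export
convert_units <- function(dataset, method, factor = NULL) {
  if (is.null(factor)) factor <- dataset$unit_factor[[method]]
  if (is.null(factor) || !is.finite(factor) || factor <= 0)
    stop("unit factor must be a positive number")
  sel <- vapply(dataset$configurations, function(cf) cf$method == method,
                logical(1))
  if (!any(sel)) stop("method not present: ", method)
  units <- vapply(dataset$configurations[sel], `[[`, character(1), "units")
  if (any(units == "mm"))
    stop("method ", method, " is already in mm; refusing to convert twice")
  dataset$configurations[sel] <- lapply(dataset$configurations[sel],
    function(cf) {
      cf$coords <- cf$coords * factor
      cf$units <- "mm"
      cf
    })
  uf <- dataset$unit_factor
  uf[method] <- factor
  dataset$unit_factor <- uf
  dataset
}

#' Require a dataset (or one method) to be in mm
#' @keywords internal
.assert_mm <- function(dataset, method = NULL) {
  cfs <- dataset$configurations
  if (!is.null(method))
    cfs <- Filter(function(cf) cf$method == method, cfs)
  units <- vapply(cfs, `[[`, character(1), "units")
  if (any(units == "voxel"))
    stop("configurations are still in voxel units; run convert_units() first")
  invisible(TRUE)
}
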