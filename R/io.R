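# Shared CSV dialect: '#' comment lines, '.' decimal separator, full double
# precision on write. Matrix files carry the column axis in the header row
# ("r_cm" or "z_cm" followed by the axis values) and the row axis in the
# first column.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (!is.finite(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

read_dialect_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], numbers = which(keep))
}

parse_numeric_fields <- function(line, lineno, path) {
  fields <- strsplit(line, ",", fixed = TRUE)[[1]]
  out <- suppressWarnings(as.numeric(trimws(fields)))
  bad <- which(is.na(out) & trimws(fields) != "NA")
  if (length(bad))
    stop(sprintf("%s, line %d: field %d ('%s') is not numeric",
                 path, lineno, bad[1], trimws(fields)[bad[1]]))
  out
}

read_matrix_dialect <- function(path, header_key) {
  d <- read_dialect_lines(path)
  if (length(d$lines) < 2L)
    stop(sprintf("%s: needs a header row and at least one data row", path))
  hdr <- strsplit(d$lines[1], ",", fixed = TRUE)[[1]]
  if (trimws(hdr[1]) != header_key)
    stop(sprintf("%s, line %d: header must start with '%s' (got '%s')",
                 path, d$numbers[1], header_key, trimws(hdr[1])))
  col_axis <- suppressWarnings(as.numeric(trimws(hdr[-1])))
  if (any(is.na(col_axis)))
    stop(sprintf("%s, line %d: non-numeric axis value in header",
                 path, d$numbers[1]))
  if (any(diff(col_axis) <= 0))
    stop(sprintf("%s, line %d: header axis must be strictly ascending",
                 path, d$numbers[1]))
  rows <- lapply(seq_along(d$lines[-1]) + 1L, function(k)
    parse_numeric_fields(d$lines[k], d$numbers[k], path))
  nfield <- lengths(rows)
  if (any(nfield != length(col_axis) + 1L)) {
    k <- which(nfield != length(col_axis) + 1L)[1]
    stop(sprintf("%s, line %d: expected %d fields, found %d",
                 path, d$numbers[k + 1L], length(col_axis) + 1L, nfield[k]))
  }
  row_axis <- vapply(rows, `[`, numeric(1), 1L)
  if (any(diff(row_axis) <= 0))
    stop(sprintf("%s: row axis must be strictly ascending", path))
  values <- do.call(rbind, lapply(rows, `[`, -1L))
  list(row_axis = row_axis, col_axis = col_axis, values = values)
}

write_matrix_dialect <- function(path, header_key, row_axis, col_axis,
                                 values, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(c(header_key, fmt_num(col_axis)), collapse = ","), con)
  for (i in seq_along(row_axis))
    writeLines(paste(c(fmt_num(row_axis[i]), fmt_num(values[i, ])),
                     collapse = ","), con)
  invisible(path)
}

#' Read / write anisotropy tables in the TG-43 CSV dialect
#'
#' Layout: optional `#` comment lines; header row `r_cm` followed by the
#' ascending angle values in degrees; each subsequent row a radius followed
#' by the F values. Write and read round-trip to full double precision.
#'
#' @param path file path.
#' @return [read_anisotropy_csv()] returns an [anisotropy_table()].
#' @export
read_anisotropy_csv <- function(path) {
  m <- read_matrix_dialect(path, "r_cm")
  anisotropy_table(m$row_axis, m$col_axis, m$values,
                   provenance = basename(path))
}

#' @param table an [anisotropy_table()].
#' @rdname read_anisotropy_csv
#' @export
write_anisotropy_csv <- function(table, path) {
  stopifnot(inherits(table, "anisotropy_table"))
  write_matrix_dialect(path, "r_cm", table$radii, table$angles, table$values,
                       comments = c("2D anisotropy table F(r,theta)",
                                    paste0("provenance: ", table$provenance)))
}

#' Read / write along-away dose-rate tables
#'
#' Layout: header row `z_cm` followed by the ascending away (y) values;
#' each subsequent row an along (z) value followed by dose rate per unit
#' Sk. Excluded grid points are written as `NA`.
#'
#' @param path file path.
#' @return [read_alongaway_csv()] returns an [alongaway_table()].
#' @export
read_alongaway_csv <- function(path) {
  m <- read_matrix_dialect(path, "z_cm")
  alongaway_table(m$col_axis, m$row_axis, m$values,
                  provenance = basename(path))
}

#' @param table an [alongaway_table()].
#' @rdname read_alongaway_csv
#' @export
write_alongaway_csv <- function(table, path) {
  stopifnot(inherits(table, "alongaway_table"))
  write_matrix_dialect(path, "z_cm", table$z_values, table$y_values,
                       table$values,
                       comments = c("along-away dose rate per unit Sk [cGy/h/U]",
                                    paste0("provenance: ", table$provenance)))
}

#' Read / write radial dose models
#'
#' Two-column files `r_cm,g` are read as table-form models; files whose
#' first data line is `degree,c0,c1,...` are read as polynomial models.
#'
#' @param path file path.
#' @param interpolation interpolation for table-form models.
#' @return [read_radial_csv()] returns a [radial_dose_model()].
#' @export
read_radial_csv <- function(path, interpolation = "linear") {
  d <- read_dialect_lines(path)
  if (!length(d$lines)) stop(sprintf("%s: empty file", path))
  first <- strsplit(d$lines[1], ",", fixed = TRUE)[[1]]
  if (trimws(first[1]) == "degree") {
    nums <- suppressWarnings(as.numeric(trimws(first[-1])))
    if (any(is.na(nums)))
      stop(sprintf("%s, line %d: polynomial line must be 'degree,c0,c1,...'",
                   path, d$numbers[1]))
    deg <- as.integer(nums[1])
    co <- nums[-1]
    if (length(co) != deg + 1L)
      stop(sprintf("%s, line %d: degree %d needs %d coefficients, found %d",
                   path, d$numbers[1], deg, deg + 1L, length(co)))
    return(radial_dose_model("polynomial", coefficients = co))
  }
  start <- if (trimws(first[1]) == "r_cm") 2L else 1L
  rows <- lapply(seq(start, length(d$lines)), function(k)
    parse_numeric_fields(d$lines[k], d$numbers[k], path))
  if (any(lengths(rows) != 2L))
    stop(sprintf("%s: radial dose table rows must have two fields (r_cm, g)",
                 path))
  tab <- do.call(rbind, rows)
  radial_dose_model("table", table = tab, interpolation = interpolation)
}

#' @param model a [radial_dose_model()].
#' @rdname read_radial_csv
#' @export
write_radial_csv <- function(model, path) {
  stopifnot(inherits(model, "radial_dose_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# radial dose function g_L(r)", con)
  if (model$form == "polynomial") {
    writeLines(paste(c("degree", length(model$coefficients) - 1L,
                       fmt_num(model$coefficients)), collapse = ","), con)
  } else {
    writeLines("r_cm,g", con)
    for (i in seq_len(nrow(model$table)))
      writeLines(paste(fmt_num(model$table[i, ]), collapse = ","), con)
  }
  invisible(path)
}

#' Read / write dose planes
#'
#' Matrix CSV with `#` metadata header lines (spacing, origin, units,
#' label), then the along-away layout: header `z_cm` + y axis, rows z +
#' dose values.
#'
#' @param path file path.
#' @return [read_dose_plane_csv()] returns a [dose_plane()].
#' @export
read_dose_plane_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  m <- read_matrix_dialect(path, "z_cm")
  spacing <- as.numeric(get_meta("spacing_cm",
                                 as.character(diff(m$col_axis)[1])))
  dose_plane(m$col_axis, m$row_axis, m$values, spacing,
             label = get_meta("label", basename(path)),
             origin = get_meta("origin", "unknown"))
}

#' @param plane a [dose_plane()].
#' @rdname read_dose_plane_csv
#' @export
write_dose_plane_csv <- function(plane, path) {
  stopifnot(inherits(plane, "dose_plane"))
  write_matrix_dialect(path, "z_cm", plane$z, plane$y, plane$values,
                       comments = c("dose plane",
                                    paste0("spacing_cm: ", fmt_num(plane$spacing)),
                                    paste0("origin: ", plane$origin),
                                    paste0("label: ", plane$label),
                                    "units: cGy/h per U"))
}

#' Write a report (pattern report, ODIN report, gamma sweep, ...) as JSON
#'
#' Reports are serialised with a `schema_version` field; data.frame-like
#' members become arrays of records.
#'
#' @param report a list or data.frame.
#' @param path output path.
#' @param seed optional seed recorded in the provenance block.
#' @export
write_report_json <- function(report, path, seed = NULL) {
  payload <- list(schema_version = "1.0",
                  generated_by = "brachyqa",
                  report = report)
  if (!is.null(seed)) payload$seed <- seed
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
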