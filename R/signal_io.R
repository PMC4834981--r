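#' Construct an RR-interval series
#'
#' An `rr_series` is an ordered sequence of cardiac interbeat (RR) intervals
#' in seconds. Every value must be finite and strictly positive; zero-length
#' series are rejected. The object carries a free-text label, an optional
#' note on provenance (e.g. the source ECG sampling rate), and, after
#' artifact filtering, the [filter_rr()] report.
#'
#' @param values numeric vector of interbeat intervals, seconds.
#' @param label free-text identifier (defaults to `"rr"`).
#' @param sampling_note optional provenance text.
#' @param filter_report optional `filter_report` attached by [filter_rr()].
#' @return An object of class `rr_series`.
#' @examples
#' rr <- rr_series(c(0.8, 0.82, 0.79), label = "example")
#' length(rr$values)
#' @export
rr_series <- function(values, label = "rr", sampling_note = NULL,
                      filter_report = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop_validation("empty series")
  if (!all(is.finite(values))) {
    stop_validation("RR series contains non-finite values (first at position %d)",
                    which(!is.finite(values))[1L])
  }
  if (any(values <= 0)) {
    stop_validation("RR intervals must be strictly positive (first violation at position %d)",
                    which(values <= 0)[1L])
  }
  structure(list(values = values, label = as.character(label)[1L],
                 sampling_note = sampling_note, filter_report = filter_report),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series '%s': %d intervals, mean %.4f s, SD %.4f s\n",
              x$label, length(x$values), mean(x$values),
              stats::sd(x$values)))
  if (!is.null(x$filter_report)) {
    cat(sprintf("  filtered: %d of %d input beats excluded\n",
                x$filter_report$n_excluded, x$filter_report$n_input))
  }
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$values)

# Coerce numeric input or rr_series to a bare numeric vector.
series_values <- function(x) {
  if (inherits(x, "rr_series")) x$values else as.numeric(x)
}

#' Read an RR-interval series from a plain-text file
#'
#' Reads one interval per line (`format = "one_column"`) or
#' `time, interval` pairs (`format = "two_column_time_rr"`, second column
#' taken as the interval). Columns may be separated by whitespace or commas.
#' Lines beginning with `#` are comments; blank lines are ignored.
#' Non-numeric content and non-positive intervals are errors that name the
#' offending line -- nothing is silently dropped.
#'
#' @param path file to read.
#' @param format `"one_column"` or `"two_column_time_rr"`.
#' @param units `"s"` (default) or `"ms"`; millisecond input is converted
#'   to seconds on ingest, since all downstream tolerances are in seconds.
#' @param label series label; defaults to the file name.
#' @return An [rr_series()].
#' @export
read_rr <- function(path, format = c("one_column", "two_column_time_rr"),
                    units = c("s", "ms"), label = basename(path)) {
  format <- match.arg(format)
  units <- match.arg(units)
  parsed <- parse_numeric_file(path, format)
  vals <- parsed$values
  if (any(vals <= 0)) {
    bad <- which(vals <= 0)[1L]
    stop_validation("non-positive interval at line %d of %s: %s",
                    parsed$lineno[bad], path, format(vals[bad]))
  }
  if (units == "ms") vals <- vals / 1000
  rr_series(vals, label = label,
            sampling_note = sprintf("read from %s (%s, %s)", path, format, units))
}

#' Read a generic numeric signal from a plain-text file
#'
#' Same file formats as [read_rr()] but without the RR positivity
#' constraint; used for reference signals (noise, sinusoids) and
#' coarse-grained series, which may be negative or zero.
#'
#' @inheritParams read_rr
#' @return Numeric vector.
#' @export
read_signal <- function(path, format = c("one_column", "two_column_time_rr")) {
  format <- match.arg(format)
  parse_numeric_file(path, format)$values
}

# Shared line-oriented numeric parser: '#' comments and blank lines
# skipped, errors name the offending 1-based source line.
parse_numeric_file <- function(path, format) {
  if (!file.exists(path)) stop_io("input file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop_validation("empty series: %s", path)
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  col <- if (format == "one_column") 1L else 2L
  raw <- vapply(fields, function(f) if (length(f) >= col) f[[col]] else NA_character_,
                character(1L))
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop_validation("parse error at line %d of %s: '%s'",
                    lineno[bad], path, lines[bad])
  }
  list(values = vals, lineno = lineno)
}

#' Write an RR-interval series to a plain-text file
#'
#' One interval per line, at a precision (default 15 significant digits)
#' chosen so that read -> write -> read is the identity on valid files.
#'
#' @param series an [rr_series()] or numeric vector.
#' @param path output file.
#' @param digits significant digits to write.
#' @export
write_rr <- function(series, path, digits = 15L) {
  vals <- series_values(series)
  out <- tryCatch(writeLines(sprintf(paste0("%.", digits, "g"), vals), path),
                  error = function(e) stop_io("cannot write %s: %s", path,
                                              conditionMessage(e)))
  invisible(path)
}

#' Write a multiscale entropy curve as tab-separated text
#'
#' Two columns, `scale<TAB>entropy`, one row per scale; undefined entropies
#' (no template matches at the given tolerance) are written as the literal
#' token `NA`. Entropy values are written with 17 significant digits so a
#' round-trip through [read_curve()] reproduces the curve exactly.
#'
#' @param curve an [mse_curve()] result.
#' @param path output file.
#' @export
write_curve <- function(curve, path) {
  if (!inherits(curve, "mse_curve")) stop_validation("not an mse_curve")
  df <- as.data.frame(curve)
  if (nrow(df) == 0L) stop_validation("empty curve")
  txt <- sprintf("%d\t%s", df$scale,
                 ifelse(is.na(df$entropy), "NA", sprintf("%.17g", df$entropy)))
  tryCatch(writeLines(txt, path),
           error = function(e) stop_io("cannot write %s: %s", path,
                                       conditionMessage(e)))
  invisible(path)
}

#' Read a multiscale entropy curve written by [write_curve()]
#'
#' @param path file to read.
#' @return A data frame with columns `scale` and `entropy` (`NA` for scales
#'   at which the entropy was undefined).
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop_io("curve file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop_validation("empty curve file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    scale = vapply(parts, function(p) as.integer(p[[1L]]), integer(1L)),
    entropy = vapply(parts, function(p) {
      if (p[[2L]] == "NA") NA_real_ else as.numeric(p[[2L]])
    }, numeric(1L))
  )
}

#' Write a complexity index summary as JSON
#'
#' Fields: `label`, `scale_min`, `scale_max`, `n_scales_defined`, `index`,
#' and the list of scales (if any) at which the entropy was undefined.
#'
#' @param ci a [complexity_index()] result.
#' @param path output file.
#' @export
write_index_json <- function(ci, path) {
  if (!inherits(ci, "complexity_index")) stop_validation("not a complexity_index")
  obj <- list(label = ci$label, scale_min = ci$scale_min,
              scale_max = ci$scale_max, n_scales_defined = ci$n_defined,
              index = ci$value, undefined_scales = I(ci$undefined_scales))
  tryCatch(jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA),
           error = function(e) stop_io("cannot write %s: %s", path,
                                       conditionMessage(e)))
  invisible(path)
}
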