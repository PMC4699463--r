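# Readers/writers for the package's plain-text interchange formats: long
# plate tables, two-column titrations, JSON/key-value fit reports, grid
# (matrix-export) plates, dot-bracket files and run configuration.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) schema_error(sprintf("'%s' is empty", path))
  if (grepl("\t", first)) "\t" else ","
}

#' Read a long-format plate table
#'
#' Delimited text (comma or tab, auto-detected) with a header and the columns
#' `plate_id`, `well`, `role`, `compound`, `signal`. Validated with
#' [plate_set()]; a missing column raises a schema error naming it and a bad
#' cell a row-level error with its line number.
#'
#' @param path Path to the file.
#' @return A [plate_set()].
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("no such file: '%s'", path))
  sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("plate_id", "well", "role", "compound", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    schema_error(sprintf("'%s' is missing column(s): %s", path,
                         paste(miss, collapse = ", ")))
  sig <- suppressWarnings(as.numeric(df$signal))
  bad <- which(is.na(sig) & !is.na(df$signal))
  if (length(bad) > 0L)
    parse_error(sprintf("non-numeric signal '%s' at line %d of '%s'",
                        df$signal[bad[1L]], bad[1L] + 1L, path))
  df$signal <- sig
  df$compound[is.na(df$compound)] <- ""
  plate_set(df)
}

#' Write a plate set as a delimited table
#'
#' @param plates A [plate_set()].
#' @param path Output path (`.tsv` writes tabs, anything else commas).
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(plates, path) {
  plates <- if (inherits(plates, "plate_set")) plates else plate_set(plates)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(plates, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a two-column titration table
#'
#' Delimited text with a one-line header and two numeric columns
#' (concentration-or-pH, signal). Decimal separator is the dot, regardless of
#' locale.
#'
#' @param path Path to the file.
#' @return A [titration_series()].
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("no such file: '%s'", path))
  sep <- .detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE,
                          strip.white = TRUE)
  if (ncol(df) < 2L)
    schema_error(sprintf("'%s' needs two columns (x, y)", path))
  if (nrow(df) == 0L) schema_error(sprintf("'%s' has no data rows", path))
  x <- suppressWarnings(as.numeric(df[[1L]]))
  y <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad) > 0L)
    parse_error(sprintf("non-numeric value at line %d of '%s'",
                        bad[1L] + 1L, path))
  titration_series(x, y, meta = list(label = basename(path),
                                     columns = names(df)[1:2]))
}

#' Write a titration series
#'
#' @param series A [titration_series()].
#' @param path Output path (`.tsv` writes tabs, anything else commas).
#' @param col_names Header names for the two columns.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path, col_names = c("x", "y")) {
  series <- .as_series(series)
  df <- stats::setNames(data.frame(series$x, series$y), col_names)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Flatten a fit/result object to an ordered named list of scalars.
as_report <- function(obj) {
  flat <- function(x, prefix = "") {
    out <- list()
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (prefix == "") nm else paste0(prefix, ".", nm)
      if (is.numeric(v) && length(v) == 1L) out[[key]] <- unname(v)
      else if (is.character(v) && length(v) == 1L) out[[key]] <- v
      else if (is.logical(v) && length(v) == 1L) out[[key]] <- v
      else if (is.numeric(v) && !is.null(names(v)))
        for (sn in names(v)) out[[paste0(key, ".", sn)]] <- unname(v[[sn]])
    }
    out
  }
  keep <- setdiff(names(obj), c("fitted", "members", "table", "fit"))
  flat(obj[keep])
}

#' Write a fit report
#'
#' Serializes a fit or result object (`kd_fit`, `ic50_fit`, `pka_fit`,
#' `zfactor_result`, `electrostatic_result`, ...) with deterministic field
#' ordering, as JSON (`.json` extension) or flat `key<TAB>value` text
#' (anything else).
#'
#' @param obj The object to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path) {
  rep <- as_report(obj)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    lines <- vapply(names(rep), function(k)
      paste(k, format(rep[[k]], digits = 15L), sep = "\t"), character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an 8x12 grid (matrix) plate export
#'
#' Converts a Tecan-style matrix export — header row `1..12`, row names
#' `A..H`, numeric cells — into the canonical long format, attaching roles
#' and compound names from a layout table (`well`, `role`, `compound`).
#'
#' @param path Path to the grid file (comma or tab delimited).
#' @param layout Data frame mapping wells to roles/compounds.
#' @param plate_id Plate identifier for the output.
#' @return A [plate_set()].
#' @export
read_plate_grid <- function(path, layout, plate_id = "plate01") {
  if (!file.exists(path)) validation_error(sprintf("no such file: '%s'", path))
  sep <- .detect_sep(path)
  m <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                         check.names = FALSE)
  if (nrow(m) != 8L || ncol(m) != 12L)
    schema_error(sprintf("'%s' is not an 8x12 grid (%dx%d)", path,
                         nrow(m), ncol(m)))
  long <- data.frame(
    plate_id = plate_id,
    well = paste0(rep(rownames(m), times = 12L),
                  rep(colnames(m), each = 8L)),
    signal = as.vector(as.matrix(m)),
    stringsAsFactors = FALSE)
  if (!all(c("well", "role") %in% names(layout)))
    schema_error("'layout' needs columns well, role (and optionally compound)")
  if (is.null(layout$compound)) layout$compound <- ""
  merged <- merge(long, layout[c("well", "role", "compound")], by = "well")
  if (nrow(merged) != nrow(layout))
    validation_error("layout wells do not match the grid")
  plate_set(merged[c("plate_id", "well", "role", "compound", "signal")])
}

#' Read a dot-bracket structure file
#'
#' Returns the first non-empty, non-comment (`#`) line.
#'
#' @param path Path to a plain-text file.
#' @return The dot-bracket string.
#' @export
read_dot_bracket <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("no such file: '%s'", path))
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    schema_error(sprintf("'%s' contains no structure line", path))
  lines[[1L]]
}

#' Read a run configuration file
#'
#' A single declarative JSON object; recognized keys include `preset`,
#' `threshold`, `cv`, `seed`, and input/output paths. CLI flags override
#' config values.
#'
#' @param path Path to the JSON config.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("no such file: '%s'", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(cfg)) schema_error(sprintf("'%s' is not a JSON object", path))
  if (!is.null(cfg$threshold) && cfg$threshold <= 0)
    validation_error("'threshold' must be > 0")
  cfg
}
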