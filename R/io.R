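.TIME_FACTORS <- c(s = 1, ms = 1e-3, us = 1e-6)
.CURR_FACTORS <- c(A = 1, mA = 1e-3, uA = 1e-6, nA = 1e-9, pA = 1e-12)

# Parse a unit suffix from a header name like "time_ms" or "i_pA".
.unit_from_header <- function(nm, table) {
  parts <- strsplit(nm, "[_.( ]")[[1]]
  parts <- gsub("[)]", "", parts)
  hit <- parts[parts %in% names(table)]
  if (length(hit)) hit[length(hit)] else NA_character_
}

#' Read an amperometric trace from delimited text
#'
#' Expects a header and at least two columns: time then current (extra
#' columns are ignored). Units are taken from the `time_unit`/`current_unit`
#' arguments, or parsed from header suffixes such as `time_ms`, `i_pA`
#' (supported: s/ms/us and A/mA/uA/nA/pA), defaulting to SI. Values are
#' converted to SI. A non-uniform time grid (jitter above 1 ppm) is resampled
#' onto a uniform grid by linear interpolation with a warning; non-monotone
#' time is an error.
#'
#' @param path File path (comma-, tab- or whitespace-delimited).
#' @param time_unit,current_unit Explicit unit overrides (`"ms"`, `"pA"`, ...).
#' @return An [amp_trace()] with `meta$source = path`.
#' @export
read_trace <- function(path, time_unit = NULL, current_unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", check.names = FALSE)
  if (ncol(df) < 2L) stop("trace file needs time and current columns")
  tu <- time_unit %||% .unit_from_header(names(df)[1], .TIME_FACTORS)
  cu <- current_unit %||% .unit_from_header(names(df)[2], .CURR_FACTORS)
  if (is.na(tu)) tu <- "s"
  if (is.na(cu)) cu <- "A"
  if (!tu %in% names(.TIME_FACTORS)) stop("unparseable time unit: ", tu)
  if (!cu %in% names(.CURR_FACTORS)) stop("unparseable current unit: ", cu)
  t <- as.numeric(df[[1]]) * .TIME_FACTORS[[tu]]
  i <- as.numeric(df[[2]]) * .CURR_FACTORS[[cu]]
  if (any(!is.finite(t)) || any(!is.finite(i)))
    stop("non-numeric values in trace file")
  if (any(diff(t) <= 0)) stop("time column is not strictly increasing")
  dts <- diff(t)
  dt0 <- mean(dts)
  if (max(abs(dts - dt0)) > 1e-6 * dt0) {
    warning("time grid jitter exceeds 1 ppm; resampling onto a uniform grid")
    tu_grid <- seq(t[1], t[length(t)], by = dt0)
    i <- stats::approx(t, i, xout = tu_grid, rule = 2)$y
    t <- tu_grid
  }
  amp_trace(t, i, meta = list(source = path, time_unit = tu,
                              current_unit = cu))
}

#' Write a trace to delimited text
#'
#' @param tr An [amp_trace()].
#' @param path Output path (CSV).
#' @param time_unit,current_unit Output units.
#' @return `path`, invisibly.
#' @export
write_trace <- function(tr, path, time_unit = "s", current_unit = "A") {
  stopifnot(inherits(tr, "amp_trace"))
  df <- data.frame(
    a = formatC(tr$t / .TIME_FACTORS[[time_unit]], format = "e", digits = 12),
    b = formatC(tr$i / .CURR_FACTORS[[current_unit]], format = "e", digits = 12))
  names(df) <- c(paste0("time_", time_unit), paste0("current_", current_unit))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' Writes the per-spike table as a tab-delimited file (floats in scientific
#' notation with 9 significant digits; missing optional fields as empty
#' cells, never zero), a JSON sidecar with full provenance (config, seed,
#' package version), and one CSV per spike with the inverted trajectories
#' (columns `t_s`, `k_per_s`, `r_p_m`).
#'
#' @param report An `analysis_report` from [analyze_trace()].
#' @param path Output stem: writes `<path>.tsv`, `<path>.json` and
#'   `<path>_pore/spike<NNN>.csv`.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  dir <- paste0(path, "_pore")
  parent <- dirname(tsv)
  if (nzchar(parent) && !dir.exists(parent))
    dir.create(parent, recursive = TRUE)
  out <- c(tsv, json)
  df <- report$spikes
  fmt <- df
  for (nm in names(fmt)) {
    if (is.numeric(fmt[[nm]]) && !is.integer(fmt[[nm]]))
      fmt[[nm]] <- ifelse(is.na(df[[nm]]), "",
                          formatC(df[[nm]], format = "e", digits = 8))
  }
  utils::write.table(fmt, tsv, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  jsonlite::write_json(
    list(provenance = report$provenance, units = report$units,
         n_spikes = nrow(df)),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  if (length(report$trajectories)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (j in seq_along(report$trajectories)) {
      tr <- report$trajectories[[j]]
      if (is.null(tr)) next
      f <- file.path(dir, sprintf("spike%03d.csv", j))
      dfj <- data.frame(
        t_s = formatC(tr$t_s, format = "e", digits = 8),
        k_per_s = formatC(tr$k_per_s, format = "e", digits = 8),
        r_p_m = ifelse(is.na(tr$r_p_m), "",
                       formatC(tr$r_p_m, format = "e", digits = 8)))
      utils::write.csv(dfj, f, row.names = FALSE, quote = FALSE)
      out <- c(out, f)
    }
  }
  invisible(out)
}

#' Serialize / deserialize a scenario
#'
#' JSON round trip for [scenario()] objects, preserving all fields.
#'
#' @param sc A [scenario()].
#' @param path JSON path.
#' @return `read_scenario` returns the [scenario()].
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  jsonlite::write_json(unclass(sc), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scenario, x)
}
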