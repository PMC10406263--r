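#' Read a bolus specification from a config file
#'
#' Reads a YAML or JSON file describing a contrast bolus and builds it on
#' the given grid. The config needs an `agent` field (`Gd` or `dOHb`) plus
#' the fields of [gamma_variate_bolus()] (for Gd: `a`, `b`, `c`, `onset`)
#' or [hypoxic_bolus()] (for dOHb: `base_sat`, `target_sat`,
#' `plateau_duration`, `onset`, `rise_tau`, `return_mode`); missing fields
#' fall back to the function defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param grid Fine time grid.
#' @return An `agent_bolus`.
#' @export
read_bolus_config <- function(path, grid) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$agent)) stop("config must name an agent", call. = FALSE)
  args <- cfg[setdiff(names(cfg), "agent")]
  if (cfg$agent == "Gd") {
    do.call(gamma_variate_bolus, c(list(grid = grid), args))
  } else if (cfg$agent == "dOHb") {
    do.call(hypoxic_bolus, c(list(grid = grid), args))
  } else {
    stop("unknown agent: ", cfg$agent, call. = FALSE)
  }
}

#' Write a time course to CSV
#'
#' Two-column CSV (`time_s`, `value`) with the acquisition metadata (agent,
#' TR, TE) as leading comment lines.
#'
#' @param x An `agent_bolus`, `signal_timecourse` or
#'   `relaxation_timecourse`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_timecourse_csv <- function(x, path) {
  value_col <- intersect(c("value", "signal", "dr2s"), names(x))[1]
  meta <- c(
    agent = attr(x, "agent"),
    TR_s = attr(x, "TR"),
    TE_s = attr(x, "TE")
  )
  meta <- meta[!vapply(meta, is.null, logical(1)) & !is.na(meta)]
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  }
  writeLines("time_s,value", con)
  writeLines(sprintf("%.10g,%.10g", x$time, x[[value_col]]), con)
  invisible(path)
}

#' Read a time course CSV written by [write_timecourse_csv()]
#'
#' @param path CSV path.
#' @return A tibble (`time`, `value`); metadata comments become attributes.
#' @export
read_timecourse_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  out <- tibble::tibble(time = df$time_s, value = df$value)
  for (ml in meta_lines) {
    kv <- sub("^# *", "", ml)
    key <- sub(":.*", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    attr(out, key) <- if (is.na(num)) val else num
  }
  out
}
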