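#' Read a concentration time series from tabular text
#'
#' Comma-separated text with a header row; required columns `time_d` and
#' `conc_ug_L`, optional `phase` (constant within a file) and `below_dl`
#' (0/1 or TRUE/FALSE). Validation failures name the offending row.
#'
#' @param path Path to a CSV file.
#' @return A [time_series()].
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_d", "conc_ug_L")
  miss <- setdiff(need, names(dat))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(dat[[col]]))))
    if (length(bad) > 0) {
      stop("malformed value in column '", col, "' at data row ", bad[1],
           call. = FALSE)
    }
    dat[[col]] <- as.numeric(dat[[col]])
  }
  noninc <- which(diff(dat$time_d) <= 0)
  if (length(noninc) > 0) {
    stop("time_d not strictly increasing at data row ", noninc[1] + 1,
         call. = FALSE)
  }
  neg <- which(dat$conc_ug_L < 0)
  if (length(neg) > 0) {
    stop("negative concentration at data row ", neg[1], call. = FALSE)
  }
  phase <- if ("phase" %in% names(dat)) dat$phase[1] else "dissolved"
  below <- if ("below_dl" %in% names(dat)) {
    as.logical(dat$below_dl)
  } else {
    NULL
  }
  time_series(dat$time_d, dat$conc_ug_L, phase = phase, below_dl = below)
}

#' Write a concentration time series as tabular text
#'
#' Canonical comma-separated form (header `time_d,conc_ug_L,phase,
#' below_dl`, '.' decimal separator). Writing and re-reading a canonical
#' file is byte-stable.
#'
#' @param series A [time_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  dat <- as.data.frame(series)
  dat$phase <- attr(series, "phase") %||% "dissolved"
  dat$below_dl <- as.integer(dat$below_dl)
  dat <- dat[, c("time_d", "conc_ug_L", "phase", "below_dl")]
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records, alongside every set of output files, what produced them: the
#' analysis step, the resolved scenario snapshot, the seed, the package
#' version and the output file list. Manifests are YAML and round-trip
#' through [read_manifest()].
#'
#' @param path Manifest path (conventionally `<prefix>_manifest.yml`).
#' @param step Name of the producing step/subcommand.
#' @param setup Optional `lake_setup` snapshot to embed.
#' @param seed Optional integer seed used for randomness.
#' @param outputs Character vector of output file names.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, step, setup = NULL, seed = NULL,
                           outputs = character(0)) {
  man <- list(
    step = step,
    package_version = as.character(utils::packageVersion("cufate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    outputs = as.list(outputs)
  )
  if (!is.null(setup)) {
    man$scenario_snapshot <- write_scenario(setup)
  }
  writeLines(yaml::as.yaml(man), path)
  invisible(man)
}

#' Read a run manifest
#'
#' @param path Manifest path.
#' @return The manifest as a list; any embedded scenario snapshot is
#'   returned as parsed `lake_setup` under `$setup`.
#' @export
read_manifest <- function(path) {
  man <- yaml::yaml.load_file(path)
  if (!is.null(man$scenario_snapshot)) {
    man$setup <- load_scenario(man$scenario_snapshot)
  }
  man
}
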