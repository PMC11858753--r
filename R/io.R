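#' @include moran.R
NULL

#' Read an actigraphy CSV
#'
#' Dialect: comma-separated, UTF-8, header \code{timestamp,activity}, one row
#' per epoch, ISO-8601 timestamps, an empty activity field marking a missing
#' epoch.  The epoch length is inferred from the timestamp grid and must be
#' uniform; gaps that are whole multiples of the epoch are materialized as
#' missing epochs, any other spacing is an error.
#'
#' @param path CSV file path.
#' @param subjectId identifier for the returned recording (default: file
#'   name without extension).
#' @param tz timezone applied to the timestamps (default UTC).
#' @return an [ActigraphyRecording-class].
#' @export
readActigraphyCsv <- function(path, subjectId = NULL, tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("timestamp", "activity")
  if (!all(need %in% names(raw)))
    stop("actigraphy CSV must have header 'timestamp,activity'")
  ts <- rep(as.POSIXct(NA), nrow(raw))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(raw$timestamp[todo], fmt, tz = tz))
  }
  bad <- which(is.na(ts))
  if (length(bad))
    stop("unparseable timestamp at line ", bad[1L] + 1L, ": '",
         raw$timestamp[bad[1L]], "'")
  act <- suppressWarnings(as.numeric(raw$activity))
  badAct <- which(is.na(act) & !(raw$activity %in% c("", "NA")))
  if (length(badAct))
    stop("malformed activity value at line ", badAct[1L] + 1L, ": '",
         raw$activity[badAct[1L]], "'")

  dt <- diff(as.numeric(ts))
  if (any(dt <= 0))
    stop("timestamps are not strictly increasing (line ",
         which(dt <= 0)[1L] + 2L, ")")
  epoch <- min(dt)
  if (any(dt %% epoch != 0))
    stop("mixed epoch lengths: spacing ", dt[which(dt %% epoch != 0)[1L]],
         " s is not a multiple of the inferred epoch ", epoch, " s")
  # materialize interior gaps as missing epochs
  idx <- as.integer(round((as.numeric(ts) - as.numeric(ts[1L])) / epoch)) + 1L
  full <- rep(NA_real_, idx[length(idx)])
  full[idx] <- act
  ActigraphyRecording(full, epochSeconds = as.integer(epoch),
                      startTime = ts[1L],
                      subjectId = subjectId %||%
                        sub("\\.[^.]*$", "", basename(path)))
}

#' Write an actigraphy recording as CSV
#'
#' Inverse of [readActigraphyCsv()]: one row per epoch, ISO-8601 timestamps,
#' empty activity field at missing epochs.
#'
#' @param rec an [ActigraphyRecording-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeActigraphyCsv <- function(rec, path) {
  stopifnot(is(rec, "ActigraphyRecording"))
  n <- length(rec@activity)
  ts <- rec@startTime + (seq_len(n) - 1L) * rec@epochSeconds
  act <- format(rec@activity, trim = TRUE, digits = 10, scientific = FALSE)
  act[rec@missingMask] <- ""
  utils::write.csv(
    data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"), activity = act),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

STUDY_COLUMNS <- c("study_id", "country", "society_scale", "mean_age",
                   "pct_male", "sample_size", "latitude", "longitude",
                   "method")

#' Read a study-level meta-table CSV
#'
#' Required columns: study_id, country, society_scale, mean_age, pct_male,
#' sample_size, latitude, longitude, method, and at least one outcome column
#' (\code{duration_h}, \code{efficiency_pct}).  Unknown columns are preserved.
#' A \code{columns} mapping renames source columns to this schema, so deposits
#' with different headers can be read without editing the file.
#'
#' @param path CSV path.
#' @param columns optional named character vector mapping schema names to
#'   source column names, e.g. \code{c(duration_h = "TST_hours")}.
#' @return validated data.frame of study records.
#' @export
readStudyTable <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    for (k in names(columns)) {
      if (!columns[[k]] %in% names(tab))
        stop("mapped column '", columns[[k]], "' not present in file")
      names(tab)[names(tab) == columns[[k]]] <- k
    }
  }
  miss <- setdiff(STUDY_COLUMNS, names(tab))
  if (length(miss))
    stop("study table lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (!any(c("duration_h", "efficiency_pct") %in% names(tab)))
    stop("study table carries no outcome column (duration_h / efficiency_pct)")
  checkStudyTable(tab)
  tab
}

checkStudyTable <- function(tab) {
  if ("duration_h" %in% names(tab)) {
    d <- tab$duration_h
    if (any(!is.na(d) & (d <= 0 | d >= 24)))
      stop("duration_h out of (0, 24)")
  }
  if ("efficiency_pct" %in% names(tab)) {
    e <- tab$efficiency_pct
    if (any(!is.na(e) & (e <= 0 | e > 100)))
      stop("efficiency_pct out of (0, 100]")
  }
  if (any(abs(tab$latitude) > 90)) stop("latitude out of [-90, 90]")
  if (any(abs(tab$longitude) > 180)) stop("longitude out of [-180, 180]")
  if (any(tab$pct_male < 0 | tab$pct_male > 100))
    stop("pct_male out of [0, 100]")
  invisible(tab)
}

#' Apply the study inclusion criteria as row filters
#'
#' Implements the implementable inclusion criteria as filters with per-row
#' exclusion reasons: mean participant age within the accepted adult range
#' (default 18-75 years) and an objective measurement method (PSG or
#' actigraphy; rows relying on self-reported sleep are rejected).  Health /
#' baseline-only criteria are study-design metadata that cannot be recomputed
#' from the table and pass through untouched.
#'
#' @param table a study table (see [readStudyTable()]).
#' @param ageRange numeric(2), accepted mean-age range.
#' @param allowedMethods accepted measurement methods.
#' @return list with \code{clean} (retained rows) and \code{exclusions}
#'   (data.frame: study_id, reason).
#' @export
validateStudyTable <- function(table, ageRange = c(18, 75),
                               allowedMethods = c("PSG", "actigraphy")) {
  checkStudyTable(table)
  reasons <- rep(NA_character_, nrow(table))
  badAge <- table$mean_age < ageRange[1] | table$mean_age > ageRange[2]
  reasons[badAge] <- "age range"
  badMethod <- !table$method %in% allowedMethods
  reasons[is.na(reasons) & badMethod] <- "measurement method"
  keep <- is.na(reasons)
  if (!any(keep)) stop("no studies remain after applying inclusion criteria")
  list(clean = table[keep, , drop = FALSE],
       exclusions = data.frame(study_id = table$study_id[!keep],
                               reason = reasons[!keep],
                               stringsAsFactors = FALSE))
}

#' Write study table CSV
#' @param table study table data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStudyTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write NPCRA results as JSON
#'
#' One record per subject carrying every statistic plus an echo of the
#' configuration that produced it, so any output is regenerable from its own
#' metadata.
#'
#' @param results an [NPCRAResult-class] or list of them.
#' @param path output JSON path.
#' @param config named list echoed under \code{$config}.
#' @return \code{path}, invisibly.
#' @export
writeNpcraJson <- function(results, path, config = list()) {
  tab <- npcraTable(results)
  jsonlite::write_json(
    list(config = config, results = tab), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a posterior summary in the dual-interval table layout
#'
#' @param fit a [HierFit-class] or a posterior summary data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePosteriorCsv <- function(fit, path) {
  summ <- if (is(fit, "HierFit")) fit@summary else fit
  utils::write.csv(summ, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML file with any of the sections \code{npcra} (binsPerDay, minDays,
#' allowShort, maxMissingFrac, impute), \code{mcmc} (chains, iter, warmup,
#' adapt, seed), \code{priors}, \code{moran} (rowStandardize, nPermutations),
#' \code{generator}.  Missing entries fall back to package defaults; CLI
#' flags override file values.
#'
#' @param path YAML path, or \code{NULL} for all defaults.
#' @return nested list of settings.
#' @export
readRunConfig <- function(path = NULL) {
  defaults <- list(
    npcra = list(binsPerDay = 24L, minDays = 6L, allowShort = FALSE,
                 maxMissingFrac = 0.2, impute = "none"),
    mcmc = list(chains = 4L, iter = 2000L, warmup = 1000L, adapt = 500L,
                seed = 1L),
    moran = list(rowStandardize = TRUE, nPermutations = 9999L),
    generator = list(days = 7L, epochSeconds = 60L)
  )
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}
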