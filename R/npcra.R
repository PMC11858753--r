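#' @include AllClasses.R AllGenerics.R
NULL

# restore the caller's RNG state after seeded simulation / permutation
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Construct an actigraphy recording
#'
#' @param activity numeric vector of epoch activity counts; \code{NA} marks a
#'   missing epoch.
#' @param epochSeconds seconds per epoch; must divide 3600.
#' @param startTime POSIXct start of the first epoch (default: a midnight, so
#'   the recording is day-aligned).
#' @param subjectId subject identifier.
#' @param missingMask optional logical mask; defaults to \code{is.na(activity)}.
#' @return an [ActigraphyRecording-class] object.
#' @export
ActigraphyRecording <- function(activity, epochSeconds = 60L,
                                startTime = as.POSIXct("2020-01-06 00:00:00",
                                                       tz = "UTC"),
                                subjectId = "subject",
                                missingMask = is.na(activity)) {
  new("ActigraphyRecording", subjectId = as.character(subjectId),
      startTime = startTime, epochSeconds = as.integer(epochSeconds),
      activity = as.numeric(activity), missingMask = as.logical(missingMask))
}

#' Bin an actigraphy recording into a day-aligned series
#'
#' Trims partial leading/trailing days (day boundary at the local midnight of
#' the recording's start time), then averages non-missing epochs within each
#' of \code{binsPerDay} equal bins per day.  A bin whose epochs are at least
#' 50% missing is itself treated as missing; by default any missing bin aborts
#' (the IS/IV formulas assume complete balanced days), while
#' \code{impute = "profile"} fills missing bins with the bin-of-day mean and
#' warns.
#'
#' @param rec an [ActigraphyRecording-class].
#' @param binsPerDay bins per day; \code{86400 / epochSeconds} must be a
#'   multiple of it.  Default 24 (hourly bins, the NPCRA convention).
#' @param maxMissingFrac maximum tolerated fraction of missing epochs in the
#'   trimmed recording (default 0.2).
#' @param impute \code{"none"} (default) or \code{"profile"} (bin-of-day mean).
#' @return a [BinnedSeries-class].
#' @export
binRecording <- function(rec, binsPerDay = 24L, maxMissingFrac = 0.2,
                         impute = c("none", "profile")) {
  stopifnot(is(rec, "ActigraphyRecording"))
  impute <- match.arg(impute)
  binsPerDay <- as.integer(binsPerDay)
  epd <- 86400L %/% rec@epochSeconds      # epochs per day
  if (86400L %% rec@epochSeconds != 0L)
    stop("epochSeconds must divide 86400")
  if (epd %% binsPerDay != 0L)
    stop("binsPerDay (", binsPerDay, ") must divide the ", epd,
         " epochs per day")
  epb <- epd %/% binsPerDay               # epochs per bin

  # seconds into the local day at the first epoch -> trim to first midnight
  secOfDay <- as.integer(as.numeric(rec@startTime) -
    as.numeric(trunc(rec@startTime, units = "days")))
  skip <- if (secOfDay == 0L) 0L else
    (86400L - secOfDay) %/% rec@epochSeconds
  n <- length(rec@activity)
  d <- (n - skip) %/% epd
  if (d < 1L)
    stop("recording has zero complete days after trimming partial days")

  x <- rec@activity[(skip + 1L):(skip + d * epd)]
  x[rec@missingMask[(skip + 1L):(skip + d * epd)]] <- NA_real_
  if (mean(is.na(x)) > maxMissingFrac)
    stop(sprintf("missing fraction %.1f%% exceeds maxMissingFrac %.1f%%",
                 100 * mean(is.na(x)), 100 * maxMissingFrac))

  g <- rep(seq_len(d * binsPerDay), each = epb)
  nMiss <- tapply(is.na(x), g, sum)
  vals <- tapply(x, g, mean, na.rm = TRUE)
  vals[nMiss >= epb / 2] <- NA_real_      # >= 50% missing => missing bin
  bad <- which(is.na(vals))
  if (length(bad) && impute == "none")
    stop("bin ", bad[1L], " (day ", (bad[1L] - 1L) %/% binsPerDay + 1L,
         ", bin-of-day ", (bad[1L] - 1L) %% binsPerDay + 1L,
         ") is missing (>= 50% missing epochs); complete balanced days are ",
         "required unless impute = 'profile'")

  if (anyNA(vals) && impute == "profile") {
    prof <- tapply(vals, rep_len(seq_len(binsPerDay), length(vals)), mean,
                   na.rm = TRUE)
    if (anyNA(prof))
      stop("cannot impute: some bin-of-day has no observed value in any day")
    idx <- which(is.na(vals))
    vals[idx] <- prof[(idx - 1L) %% binsPerDay + 1L]
    warning(length(idx), " missing bin(s) imputed by bin-of-day mean")
  }
  new("BinnedSeries", values = as.numeric(vals), binsPerDay = binsPerDay,
      nDays = as.integer(d))
}

binMatrix <- function(s) {
  matrix(s@values, nrow = s@binsPerDay, ncol = s@nDays)
}

#' Interdaily stability (IS)
#'
#' Ratio of the variance of the average 24-h profile to the total variance:
#' \deqn{IS = \frac{\sum_h (\bar x_h - \bar x)^2 / p}{\sum_i (x_i - \bar x)^2 / n}}
#' where \eqn{\bar x_h} is the mean over days of bin-of-day \eqn{h}.  IS is 1
#' when every day repeats the same profile exactly and tends to 0 for noise.
#'
#' @param s a [BinnedSeries-class] with at least 2 complete days and no
#'   missing bins.
#' @return IS in [0, 1].
#' @export
interdailyStability <- function(s) {
  stopifnot(is(s, "BinnedSeries"))
  if (s@nDays < 2L) stop("IS needs at least 2 complete days")
  x <- s@values
  if (anyNA(x)) stop("IS is undefined with missing bins (see binRecording)")
  xbar <- mean(x)
  hourly <- rowMeans(binMatrix(s))
  denom <- sum((x - xbar)^2) / length(x)
  if (denom == 0) stop("undefined IS: series is constant (zero variance)")
  (sum((hourly - xbar)^2) / s@binsPerDay) / denom
}

#' Intradaily variability (IV)
#'
#' Normalized mean squared successive difference:
#' \deqn{IV = \frac{\sum_{i=2}^n (x_i - x_{i-1})^2 / (n-1)}{\sum_i (x_i - \bar x)^2 / n}}
#' IV is near 0 for a smooth sinusoid, near 2 for white noise, and can exceed
#' 2 for anti-correlated (rapidly alternating) series.
#'
#' @param s a [BinnedSeries-class] (or any numeric vector of length >= 2 via
#'   \code{intradailyVariability(asBinnedSeries(x))}).
#' @return IV >= 0.
#' @export
intradailyVariability <- function(s) {
  stopifnot(is(s, "BinnedSeries"))
  x <- s@values
  if (length(x) < 2L) stop("IV needs at least 2 bins")
  if (anyNA(x)) stop("IV is undefined with missing bins (see binRecording)")
  denom <- sum((x - mean(x))^2) / length(x)
  if (denom == 0) stop("undefined IV: series is constant (zero variance)")
  (sum(diff(x)^2) / (length(x) - 1L)) / denom
}

#' Relative amplitude (RA) via M10 and L5
#'
#' Computed on the average day profile with circular wrap-around: M10 is the
#' largest mean over all windows of 10 consecutive hours, L5 the smallest mean
#' over all windows of 5 consecutive hours, and
#' \eqn{RA = (M10 - L5)/(M10 + L5)} (0 by convention when \eqn{M10 + L5 = 0}).
#'
#' @param s a [BinnedSeries-class] of non-negative values whose
#'   \code{binsPerDay} admits exact 10-h and 5-h windows (any multiple of 24,
#'   and also p for which \code{10p/24} and \code{5p/24} are integers).
#' @return list with \code{RA}, \code{M10}, \code{L5}, \code{M10onsetHour},
#'   \code{L5onsetHour}.
#' @export
relativeAmplitude <- function(s) {
  stopifnot(is(s, "BinnedSeries"))
  x <- s@values
  if (anyNA(x)) stop("RA is undefined with missing bins (see binRecording)")
  if (any(x < 0)) stop("RA requires non-negative activity values")
  p <- s@binsPerDay
  w10 <- 10L * p / 24L
  w5  <- 5L * p / 24L
  if (w10 != as.integer(w10) || w5 != as.integer(w5))
    stop("binsPerDay = ", p, " does not admit exact 10-h and 5-h windows")
  prof <- rowMeans(binMatrix(s))
  scan <- function(width) {
    ext <- c(prof, prof[seq_len(width - 1L)])       # circular wrap
    means <- vapply(seq_len(p), function(i) mean(ext[i:(i + width - 1L)]),
                    numeric(1))
    means
  }
  m10means <- scan(as.integer(w10))
  l5means <- scan(as.integer(w5))
  i10 <- which.max(m10means)    # first window on ties
  i5 <- which.min(l5means)
  M10 <- m10means[i10]; L5 <- l5means[i5]
  RA <- if (M10 + L5 == 0) 0 else (M10 - L5) / (M10 + L5)
  list(RA = RA, M10 = M10, L5 = L5,
       M10onsetHour = (i10 - 1) * 24 / p,
       L5onsetHour = (i5 - 1) * 24 / p)
}

#' Compose the circadian function index (CFI)
#'
#' IV is inverted and normalized to [0, 1] as \code{clip(1 - IV/2, 0, 1)}
#' (1 for a perfect sinusoid, 0 for noise-level fragmentation or worse), and
#' CFI is the arithmetic mean of IS, the inverted-normalized IV, and RA, so
#' that 0 marks absence of circadian rhythmicity and 1 a robust rhythm.
#'
#' @param IS interdaily stability in [0, 1].
#' @param IV intradaily variability >= 0.
#' @param RA relative amplitude in [0, 1].
#' @return list with \code{IVinvNorm} and \code{CFI}.
#' @export
cfiCompose <- function(IS, IV, RA) {
  if (!is.finite(IS) || IS < 0 || IS > 1) stop("IS must lie in [0, 1]")
  if (!is.finite(IV) || IV < 0) stop("IV must be >= 0")
  if (!is.finite(RA) || RA < 0 || RA > 1) stop("RA must lie in [0, 1]")
  IVinvNorm <- min(max(1 - IV / 2, 0), 1)
  list(IVinvNorm = IVinvNorm, CFI = (IS + IVinvNorm + RA) / 3)
}

#' Full NPCRA pipeline: recording to circadian statistics
#'
#' Bins the recording, computes IS, IV and RA (with M10/L5 and onsets), and
#' composes the CFI.  Recordings shorter than \code{minDays} complete days
#' (default 6, the suggested minimum number of consecutive nights for stable
#' NPCRA statistics) are rejected unless \code{allowShort = TRUE}, which
#' downgrades the rejection to a warning.
#'
#' @inheritParams binRecording
#' @param minDays minimum complete days required (default 6).
#' @param allowShort if TRUE, short recordings produce a warning, not an error.
#' @return an [NPCRAResult-class].
#' @export
npcra <- function(rec, binsPerDay = 24L, minDays = 6L, allowShort = FALSE,
                  maxMissingFrac = 0.2, impute = c("none", "profile")) {
  s <- binRecording(rec, binsPerDay = binsPerDay,
                    maxMissingFrac = maxMissingFrac, impute = impute)
  if (s@nDays < minDays) {
    msg <- sprintf(
      "recording '%s' has %d complete days; NPCRA statistics need a minimum of %d consecutive nights",
      rec@subjectId, s@nDays, minDays)
    if (!allowShort) stop(msg)
    warning(msg, "; proceeding because allowShort = TRUE")
  }
  IS <- interdailyStability(s)
  IV <- intradailyVariability(s)
  ra <- relativeAmplitude(s)
  comp <- cfiCompose(min(max(IS, 0), 1), IV, ra$RA)
  new("NPCRAResult", subjectId = rec@subjectId, IS = IS, IV = IV, RA = ra$RA,
      M10 = ra$M10, L5 = ra$L5, M10onsetHour = ra$M10onsetHour,
      L5onsetHour = ra$L5onsetHour, IVinvNorm = comp$IVinvNorm,
      CFI = comp$CFI, nDays = s@nDays)
}

#' Wrap a day-aligned numeric vector as a BinnedSeries
#'
#' Convenience constructor for analyses that start from already-binned values
#' (e.g. hourly counts exported by other software).
#'
#' @param values numeric vector of length \code{binsPerDay * nDays}.
#' @param binsPerDay bins per day.
#' @return a [BinnedSeries-class].
#' @export
asBinnedSeries <- function(values, binsPerDay = 24L) {
  binsPerDay <- as.integer(binsPerDay)
  if (length(values) %% binsPerDay != 0L)
    stop("length(values) must be a multiple of binsPerDay")
  new("BinnedSeries", values = as.numeric(values), binsPerDay = binsPerDay,
      nDays = as.integer(length(values) %/% binsPerDay))
}
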