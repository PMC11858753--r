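#' @include npcra.R
NULL

# multiplicative state-switch factors for the fragmentation process
FRAG_UP <- 1.35
FRAG_DOWN <- 0.65

#' Simulate one actigraphy recording
#'
#' Generates a rectified-cosine rest-activity signal with controllable
#' day-to-day phase jitter (drives IS down), a two-state multiplicative
#' fragmentation process (drives IV up), additive Gaussian noise, and a
#' nocturnal activity floor (drives RA down):
#' \deqn{x_t = \max(0,\; m + A\cos(2\pi(t - \phi_d)/24) + \epsilon_t)\cdot s_t + f\,[\cos(2\pi(t-\phi_d)/24) < 0]}
#' where \eqn{\phi_d} is the day's acrophase (base acrophase plus Gaussian
#' jitter), \eqn{s_t} a two-state process toggling between scaled-up and
#' scaled-down activity with per-epoch probability \code{fragmentationRate},
#' and \eqn{f} the \code{nightFloor} added inside the nocturnal half-cycle.
#' Output is deterministic given \code{seed}.
#'
#' @param mesor baseline activity level (counts, >= 0).
#' @param amplitude cosine amplitude (counts, >= 0).
#' @param acrophaseHour hour-of-day of peak activity, in [0, 24).
#' @param noiseSd sd of additive Gaussian noise (counts, >= 0).
#' @param phaseJitterSdHours sd of the day-to-day acrophase jitter (hours).
#' @param fragmentationRate per-epoch probability of toggling the
#'   fragmentation state, in [0, 1].
#' @param nightFloor activity added during the nocturnal half-cycle (counts).
#' @param days number of complete days to generate (>= 1).
#' @param epochSeconds epoch length in seconds (must divide 3600).
#' @param seed integer seed; \code{NULL} uses the current RNG stream.
#' @param subjectId identifier stored in the recording.
#' @return an [ActigraphyRecording-class] starting at midnight.
#' @export
simulateRecording <- function(mesor = 40, amplitude = 35, acrophaseHour = 14,
                              noiseSd = 0, phaseJitterSdHours = 0,
                              fragmentationRate = 0, nightFloor = 0,
                              days = 7L, epochSeconds = 60L, seed = NULL,
                              subjectId = "sim") {
  if (days < 1L) stop("days must be >= 1")
  stopifnot(mesor >= 0, amplitude >= 0, noiseSd >= 0,
            phaseJitterSdHours >= 0, nightFloor >= 0,
            fragmentationRate >= 0, fragmentationRate <= 1,
            acrophaseHour >= 0, acrophaseHour < 24)
  withSeed(seed, {
    epd <- 86400L %/% as.integer(epochSeconds)
    n <- as.integer(days) * epd
    tHours <- (seq_len(n) - 0.5) * epochSeconds / 3600
    dayIdx <- pmin(floor(tHours / 24) + 1L, days)
    acro <- acrophaseHour + stats::rnorm(days, 0, phaseJitterSdHours)
    phase <- 2 * pi * (tHours - acro[dayIdx]) / 24
    base <- mesor + amplitude * cos(phase)
    eps <- if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else numeric(n)
    core <- pmax(0, base + eps)
    if (fragmentationRate > 0) {
      state <- cumsum(stats::runif(n) < fragmentationRate) %% 2L
      core <- core * ifelse(state == 0L, FRAG_UP, FRAG_DOWN)
    }
    x <- core + nightFloor * (cos(phase) < 0)
    ActigraphyRecording(x, epochSeconds = epochSeconds, subjectId = subjectId)
  })
}

# Cohort presets: per-subject parameter distributions for the two society
# scales.  The constants were calibrated once, by simulating cohorts through
# the package's own NPCRA pipeline, so that default cohorts reproduce the
# descriptive CFI moments the package targets (non-industrial mean ~0.70;
# industrial mean ~0.63, sd ~0.07); they are frozen, not user-tunable knobs.
PRESETS <- list(
  "non-industrial" = list(
    mesorMeanlog = log(40), mesorSdlog = 0.25,
    ampRatioShape1 = 18, ampRatioShape2 = 2,       # amplitude / mesor ~ Beta
    noiseRatioMeanlog = log(0.42), noiseRatioSdlog = 0.30,
    jitterMeanlog = log(0.95), jitterSdlog = 0.40, # hours
    fragShape1 = 1.5, fragShape2 = 500,            # per-epoch toggle prob
    nightRatioMeanlog = log(0.13), nightRatioSdlog = 0.50,
    ageMean = 35, ageSd = 12, pMale = 0.5
  ),
  industrial = list(
    mesorMeanlog = log(40), mesorSdlog = 0.25,
    ampRatioShape1 = 16, ampRatioShape2 = 3.6,
    noiseRatioMeanlog = log(0.50), noiseRatioSdlog = 0.28,
    jitterMeanlog = log(1.1), jitterSdlog = 0.35,
    fragShape1 = 2.5, fragShape2 = 700,
    nightRatioMeanlog = log(0.18), nightRatioSdlog = 0.45,
    ageMean = 52, ageSd = 11, pMale = 0.47
  )
)

#' Society-scale cohort presets
#'
#' Returns the per-subject parameter distribution defining a cohort preset.
#' Two presets are built in: \code{"non-industrial"} (stabler, higher-contrast
#' rhythms) and \code{"industrial"} (more phase jitter, fragmentation and
#' nocturnal activity), calibrated so that default cohorts pushed through
#' [npcra()] reproduce the target descriptive CFI moments.
#'
#' @param label \code{"non-industrial"} or \code{"industrial"}.
#' @return a named list of distribution hyper-parameters.
#' @export
groupPreset <- function(label = c("non-industrial", "industrial")) {
  if (!is.character(label) || length(label) != 1L ||
      !label %in% names(PRESETS))
    stop("unknown preset label: ", paste(label, collapse = ", "),
         " (expected 'non-industrial' or 'industrial')")
  c(PRESETS[[label]], list(label = label))
}

drawSubjectParams <- function(preset) {
  mesor <- stats::rlnorm(1, preset$mesorMeanlog, preset$mesorSdlog)
  list(
    mesor = mesor,
    amplitude = mesor * stats::rbeta(1, preset$ampRatioShape1,
                                     preset$ampRatioShape2),
    acrophaseHour = (14 + stats::rnorm(1, 0, 1.2)) %% 24,
    noiseSd = mesor * stats::rlnorm(1, preset$noiseRatioMeanlog,
                                    preset$noiseRatioSdlog),
    phaseJitterSdHours = stats::rlnorm(1, preset$jitterMeanlog,
                                       preset$jitterSdlog),
    fragmentationRate = stats::rbeta(1, preset$fragShape1, preset$fragShape2),
    nightFloor = mesor * stats::rlnorm(1, preset$nightRatioMeanlog,
                                       preset$nightRatioSdlog)
  )
}

#' Simulate a cohort of actigraphy recordings with covariates
#'
#' Draws per-subject rhythm parameters from a society-scale preset, generates
#' one recording per subject, and attaches age (truncated-normal, years) and
#' sex covariates.  Seed-deterministic.
#'
#' @param preset a preset label accepted by [groupPreset()] or the list it
#'   returns.
#' @param n number of subjects (>= 1).
#' @param days days per recording (default 7).
#' @param epochSeconds epoch length (default 60 s).
#' @param seed integer seed.
#' @return list with \code{recordings} (list of
#'   [ActigraphyRecording-class]) and \code{covariates} (data.frame with
#'   subject_id, society_scale, age, sex).
#' @export
simulateCohort <- function(preset, n, days = 7L, epochSeconds = 60L,
                           seed = NULL) {
  if (is.character(preset)) preset <- groupPreset(preset)
  if (!is.list(preset) || is.null(preset$label))
    stop("preset must be a label or a groupPreset() list")
  if (!is.numeric(n) || n < 1L) stop("cohort size n must be >= 1")
  n <- as.integer(n)
  withSeed(seed, {
    age <- pmin(pmax(stats::rnorm(n, preset$ageMean, preset$ageSd), 18), 75)
    sex <- ifelse(stats::runif(n) < preset$pMale, "male", "female")
    ids <- sprintf("%s_%03d", gsub("[^a-z]", "", preset$label), seq_len(n))
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      p <- drawSubjectParams(preset)
      recs[[i]] <- simulateRecording(
        mesor = p$mesor, amplitude = p$amplitude,
        acrophaseHour = p$acrophaseHour, noiseSd = p$noiseSd,
        phaseJitterSdHours = p$phaseJitterSdHours,
        fragmentationRate = p$fragmentationRate, nightFloor = p$nightFloor,
        days = days, epochSeconds = epochSeconds, subjectId = ids[i])
    }
    list(recordings = recs,
         covariates = data.frame(subject_id = ids,
                                 society_scale = preset$label,
                                 age = age, sex = sex,
                                 stringsAsFactors = FALSE))
  })
}

#' Run NPCRA over a cohort and assemble the subject table
#'
#' @param cohort the list returned by [simulateCohort()].
#' @param ... passed to [npcra()].
#' @return data.frame: covariates joined with per-subject NPCRA statistics
#'   (including \code{cfi}).
#' @export
cohortCfi <- function(cohort, ...) {
  res <- npcraTable(lapply(cohort$recordings, npcra, ...))
  out <- merge(cohort$covariates, res, by = "subject_id", sort = FALSE)
  out$cfi <- out$CFI
  out
}

#' Simulate a study-level meta-table from the hierarchical generative model
#'
#' Generates a population-level sleep meta-table
#' \deqn{y_j = \beta_0 + \beta_s I(\text{non-industrial}_j) + \beta_a z^{age}_j + \beta_m z^{male}_j + u_{c(j)} + \epsilon_j}
#' with country random intercepts \eqn{u_c \sim N(0, \tau)} and residual
#' \eqn{\epsilon_j \sim N(0, \sigma)}.  Society scale is assigned at the
#' country level (countries nest within scale, as in real cross-cultural
#' meta-tables); the covariates entering the linear predictor are the
#' z-scored versions of the emitted raw age / % male columns, matching the
#' standardization the fitter applies.  Defaults for the true coefficients
#' are the posterior means the package's duration model targets.
#'
#' @param nStudies number of study rows (default 54).
#' @param nCountries number of countries (default 21; \code{nStudies >=
#'   nCountries >= 2}); every country receives at least one study.
#' @param outcome \code{"duration"} (hours) or \code{"efficiency"} (percent);
#'   selects default truths and the output column name.
#' @param intercept,betaSociety,betaAge,betaMale true fixed effects (defaults:
#'   duration 7.16, -0.75, -0.19, -0.13 h; efficiency 87.91, -14.01, -2.80,
#'   0.64).
#' @param countrySd true country random-intercept sd (defaults 0.73 h / 5.42).
#' @param residualSd true residual sd (defaults 0.5 h / 2.5).
#' @param propNonIndustrial proportion of countries that are non-industrial
#'   (default 0.35; both levels always present).
#' @param seed integer seed.
#' @return data.frame of study records: study_id, country, society_scale,
#'   outcome column (\code{duration_h} or \code{efficiency_pct}), mean_age,
#'   pct_male, sample_size, latitude, longitude, method.
#' @export
simulateStudyTable <- function(nStudies = 54L, nCountries = 21L,
                               outcome = c("duration", "efficiency"),
                               intercept = NULL, betaSociety = NULL,
                               betaAge = NULL, betaMale = NULL,
                               countrySd = NULL, residualSd = NULL,
                               propNonIndustrial = 0.35, seed = NULL) {
  outcome <- match.arg(outcome)
  defs <- if (outcome == "duration")
    list(intercept = 7.16, betaSociety = -0.75, betaAge = -0.19,
         betaMale = -0.13, countrySd = 0.73, residualSd = 0.5)
  else
    list(intercept = 87.91, betaSociety = -14.01, betaAge = -2.80,
         betaMale = 0.64, countrySd = 5.42, residualSd = 2.5)
  intercept <- intercept %||% defs$intercept
  betaSociety <- betaSociety %||% defs$betaSociety
  betaAge <- betaAge %||% defs$betaAge
  betaMale <- betaMale %||% defs$betaMale
  countrySd <- countrySd %||% defs$countrySd
  residualSd <- residualSd %||% defs$residualSd
  if (countrySd < 0 || residualSd < 0)
    stop("countrySd and residualSd must be >= 0")
  nStudies <- as.integer(nStudies); nCountries <- as.integer(nCountries)
  if (nStudies < nCountries || nCountries < 2L)
    stop("need nStudies >= nCountries >= 2")

  withSeed(seed, {
    country <- sprintf("country_%02d", seq_len(nCountries))
    nNon <- max(1L, min(nCountries - 1L,
                        round(propNonIndustrial * nCountries)))
    scaleByCountry <- c(rep("non-industrial", nNon),
                        rep("industrial", nCountries - nNon))
    lat <- stats::runif(nCountries, -55, 65)
    lon <- stats::runif(nCountries, -180, 180)
    # every country gets one study; remaining studies spread at random
    cidx <- c(seq_len(nCountries),
              sample.int(nCountries, nStudies - nCountries, replace = TRUE))
    u <- stats::rnorm(nCountries, 0, countrySd)

    meanAge <- pmin(pmax(stats::rnorm(nStudies, 42, 11), 18), 75)
    pctMale <- pmin(pmax(stats::rnorm(nStudies, 50, 15), 0), 100)
    zAge <- as.numeric(scale(meanAge))
    zMale <- as.numeric(scale(pctMale))
    nonInd <- as.integer(scaleByCountry[cidx] == "non-industrial")
    y <- intercept + betaSociety * nonInd + betaAge * zAge +
      betaMale * zMale + u[cidx] + stats::rnorm(nStudies, 0, residualSd)

    out <- data.frame(
      study_id = sprintf("study_%02d", seq_len(nStudies)),
      country = country[cidx],
      society_scale = scaleByCountry[cidx],
      mean_age = meanAge, pct_male = pctMale,
      sample_size = sample(20:400, nStudies, replace = TRUE),
      latitude = lat[cidx], longitude = lon[cidx],
      method = sample(c("actigraphy", "PSG"), nStudies, replace = TRUE,
                      prob = c(0.7, 0.3)),
      stringsAsFactors = FALSE)
    # keep outcomes inside their physical ranges; the tail mass affected is
    # tiny at the default truths, so recovery stays well-posed
    if (outcome == "duration") out$duration_h <- pmin(pmax(y, 0.1), 23.9)
    else out$efficiency_pct <- pmin(pmax(y, 0.1), 100)
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
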