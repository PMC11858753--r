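#' @import methods
NULL

#' ActigraphyRecording: epoch-level activity counts for one subject
#'
#' Container for a single subject's wrist-actigraphy time series: activity
#' counts accumulated over fixed epochs (e.g. 60 s), a per-epoch missingness
#' mask, and the calendar start time that anchors day boundaries.
#'
#' @slot subjectId character(1) opaque subject identifier.
#' @slot startTime \code{POSIXct} timestamp of the first epoch.
#' @slot epochSeconds integer(1), seconds per epoch; must divide 3600 so that
#'   epochs nest inside hours.
#' @slot activity numeric vector of non-negative activity counts; entries at
#'   missing epochs are \code{NA}.
#' @slot missingMask logical vector, \code{TRUE} where the epoch is missing.
#'
#' @seealso [simulateRecording()], [readActigraphyCsv()], [npcra()]
#' @export
setClass("ActigraphyRecording",
  representation(
    subjectId    = "character",
    startTime    = "POSIXct",
    epochSeconds = "integer",
    activity     = "numeric",
    missingMask  = "logical"
  )
)

setValidity("ActigraphyRecording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(object@epochSeconds) != 1L || is.na(object@epochSeconds) ||
      object@epochSeconds < 1L)
    msg <- c(msg, "epochSeconds must be a single positive integer")
  else if (3600L %% object@epochSeconds != 0L)
    msg <- c(msg, "epochSeconds must divide 3600 (epochs must nest in hours)")
  if (length(object@activity) != length(object@missingMask))
    msg <- c(msg, "activity and missingMask must have equal length")
  obs <- object@activity[!object@missingMask]
  if (anyNA(obs))
    msg <- c(msg, "non-missing epochs must carry a numeric activity value")
  if (any(obs < 0, na.rm = TRUE))
    msg <- c(msg, "activity counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' BinnedSeries: day-aligned binned activity
#'
#' Activity averaged into \code{binsPerDay} equal bins per day over
#' \code{nDays} complete days, in temporal order.  This is the input the
#' IS/IV/RA formulas operate on; \code{length(values) == binsPerDay * nDays}
#' always holds.
#'
#' @slot values numeric vector, length \code{binsPerDay * nDays}; \code{NA}
#'   marks a bin with too many missing epochs.
#' @slot binsPerDay integer(1), bins per day (default pipeline uses 24).
#' @slot nDays integer(1), number of complete days (>= 1).
#' @export
setClass("BinnedSeries",
  representation(
    values     = "numeric",
    binsPerDay = "integer",
    nDays      = "integer"
  )
)

setValidity("BinnedSeries", function(object) {
  msg <- character()
  if (object@binsPerDay < 1L) msg <- c(msg, "binsPerDay must be >= 1")
  if (object@nDays < 1L) msg <- c(msg, "nDays must be >= 1")
  if (length(object@values) != object@binsPerDay * object@nDays)
    msg <- c(msg, "length(values) must equal binsPerDay * nDays")
  if (length(msg)) msg else TRUE
})

#' NPCRAResult: non-parametric circadian rhythm statistics for one subject
#'
#' Holds interdaily stability (IS), intradaily variability (IV), relative
#' amplitude (RA) with its M10/L5 components and onset hours, the
#' inverted-normalized IV, and the composite circadian function index
#' CFI = (IS + IVinv + RA) / 3.
#'
#' @slot subjectId character(1).
#' @slot IS numeric(1) in [0, 1]; 1 = identical days, ~0 = noise.
#' @slot IV numeric(1) >= 0; ~0 = smooth sinusoid, ~2 = white noise.
#' @slot RA numeric(1) in [0, 1]; normalized day-night contrast.
#' @slot M10,L5 mean activity of the most active 10 / least active 5
#'   consecutive hours of the average day.
#' @slot M10onsetHour,L5onsetHour hour-of-day in [0, 24) where each window
#'   begins.
#' @slot IVinvNorm numeric(1) in [0, 1]: \code{clip(1 - IV/2, 0, 1)}.
#' @slot CFI numeric(1) in [0, 1].
#' @slot nDays integer(1), complete days analysed.
#' @export
setClass("NPCRAResult",
  representation(
    subjectId    = "character",
    IS           = "numeric",
    IV           = "numeric",
    RA           = "numeric",
    M10          = "numeric",
    L5           = "numeric",
    M10onsetHour = "numeric",
    L5onsetHour  = "numeric",
    IVinvNorm    = "numeric",
    CFI          = "numeric",
    nDays        = "integer"
  )
)

setValidity("NPCRAResult", function(object) {
  msg <- character()
  chk01 <- function(x, nm) {
    if (!is.na(x) && (x < -1e-12 || x > 1 + 1e-12))
      sprintf("%s must lie in [0, 1]", nm)
  }
  msg <- c(msg, chk01(object@IS, "IS"), chk01(object@RA, "RA"),
           chk01(object@IVinvNorm, "IVinvNorm"), chk01(object@CFI, "CFI"))
  if (!is.na(object@IV) && object@IV < 0) msg <- c(msg, "IV must be >= 0")
  if (abs(object@CFI - (object@IS + object@IVinvNorm + object@RA) / 3) > 1e-9)
    msg <- c(msg, "CFI must equal (IS + IVinvNorm + RA) / 3")
  if (length(msg)) msg else TRUE
})

#' HierFit: a fitted Bayesian hierarchical sleep/CFI model
#'
#' Wraps the MCMC draws (a \code{coda::mcmc.list}), the posterior summary
#' table with dual 89%/95% credible intervals and support labels, convergence
#' diagnostics, pointwise log-likelihood draws (for LOO), and the model
#' metadata needed to reproduce the fit.
#'
#' @slot draws mcmc.list of posterior draws, one chain per element.
#' @slot summary data.frame: one row per reported parameter (estimate, se,
#'   ci89/ci95 bounds, pct_negative, support).
#' @slot model character(1): "duration", "efficiency" or "cfi".
#' @slot terms character vector of fixed-effect terms included.
#' @slot ranef data.frame of per-group random-intercept posterior means (empty
#'   for fixed-effects-only models).
#' @slot loglik matrix draws x observations of pointwise log-likelihoods.
#' @slot data data.frame: the (standardized) model frame used.
#' @slot diagnostics list: split-Rhat and effective sample size per parameter.
#' @slot priors list echoing the prior set used.
#' @slot seed integer(1) MCMC seed.
#' @export
setClass("HierFit",
  representation(
    draws       = "ANY",
    summary     = "data.frame",
    model       = "character",
    terms       = "character",
    ranef       = "data.frame",
    loglik      = "matrix",
    data        = "data.frame",
    diagnostics = "list",
    priors      = "list",
    seed        = "integer"
  )
)

#' MoranResult: Moran's I spatial autocorrelation diagnostic
#'
#' @slot I observed Moran's I statistic.
#' @slot expectedI null expectation, exactly \code{-1/(n - 1)}.
#' @slot pValue two-sided permutation p-value in (0, 1].
#' @slot nUnits number of spatial units.
#' @slot weightScheme descriptor of the spatial weight matrix used.
#' @slot nPermutations permutations drawn for the null distribution.
#' @export
setClass("MoranResult",
  representation(
    I             = "numeric",
    expectedI     = "numeric",
    pValue        = "numeric",
    nUnits        = "integer",
    weightScheme  = "character",
    nPermutations = "integer"
  )
)

setValidity("MoranResult", function(object) {
  msg <- character()
  if (abs(object@expectedI - (-1 / (object@nUnits - 1))) > 1e-12)
    msg <- c(msg, "expectedI must equal -1/(nUnits - 1)")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
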