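#' @include simulate.R
NULL

#' Prior set for the hierarchical sleep / CFI models
#'
#' The intercept priors are informative and outcome-specific: Normal(8, 1) h
#' for sleep duration, Normal(85, 10) for sleep efficiency (%), and
#' Normal(0.58, 0.1) for the CFI.  Slope priors are weakly informative
#' Normal(0, 2 sd(y)); group-level and residual sds get half-Normal(0, 2 sd(y))
#' priors.  Scales left \code{NULL} are resolved from the outcome at fit time.
#'
#' @param outcome "duration", "efficiency" or "cfi".
#' @param interceptMean,interceptSd intercept prior moments (defaults above).
#' @param slopeScale,groupSdScale,residSdScale prior scales; \code{NULL} means
#'   2 sd of the outcome.
#' @return list of prior hyper-parameters.
#' @export
priorSet <- function(outcome = c("duration", "efficiency", "cfi"),
                     interceptMean = NULL, interceptSd = NULL,
                     slopeScale = NULL, groupSdScale = NULL,
                     residSdScale = NULL) {
  outcome <- match.arg(outcome)
  defs <- switch(outcome,
    duration = c(8, 1), efficiency = c(85, 10), cfi = c(0.58, 0.1))
  out <- list(outcome = outcome,
              interceptMean = interceptMean %||% defs[1],
              interceptSd = interceptSd %||% defs[2],
              slopeScale = slopeScale, groupSdScale = groupSdScale,
              residSdScale = residSdScale)
  if (out$interceptSd <= 0) stop("interceptSd must be > 0")
  out
}

# split-Rhat (each chain halved) and bulk ESS from a draws matrix list
splitRhat <- function(chainList) {
  halves <- unlist(lapply(chainList, function(ch) {
    m <- length(ch) %/% 2L
    list(ch[seq_len(m)], ch[(m + 1L):(2L * m)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

jagsHierModel <- function(hasRanef, priorOnly) {
  lik <- if (!priorOnly) "
  for (i in 1:N) {
    mu[i] <- inprod(X[i, ], beta[]) %s
    y[i] ~ dnorm(mu[i], prec)
    loglik[i] <- logdensity.norm(y[i], mu[i], prec)
  }" else ""
  if (nzchar(lik))
    lik <- sprintf(lik, if (hasRanef) "+ u[g[i]]" else "")
  ranef <- if (hasRanef) "
  for (c in 1:C) { u[c] ~ dnorm(0, precU) }
  tau ~ dnorm(0, 1 / (groupScale * groupScale)) T(0,)
  precU <- 1 / (tau * tau)" else ""
  sprintf("model {%s
  beta[1] ~ dnorm(b0mean, 1 / (b0sd * b0sd))
  for (k in 2:K) { beta[k] ~ dnorm(0, 1 / (slopeScale * slopeScale)) }%s
  sigma ~ dnorm(0, 1 / (residScale * residScale)) T(0,)
  prec <- 1 / (sigma * sigma)
}", lik, ranef)
}

runHierMcmc <- function(X, y, g, priors, chains, iter, warmup, adapt, seed,
                        priorOnly = FALSE) {
  hasRanef <- !is.null(g)
  sdY <- if (priorOnly) priors$interceptSd else stats::sd(y)
  data <- list(K = ncol(X),
               b0mean = priors$interceptMean, b0sd = priors$interceptSd,
               slopeScale = priors$slopeScale %||% (2 * sdY),
               residScale = priors$residSdScale %||% (2 * sdY))
  if (!priorOnly) {
    data$N <- nrow(X); data$X <- X; data$y <- y
    if (hasRanef) data$g <- g
  }
  if (hasRanef) {
    data$C <- if (is.null(g)) 0L else max(g)
    data$groupScale <- priors$groupSdScale %||% (2 * sdY)
  }
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((as.numeric(seed) * 1009 + ch) %% 2147483647))
  })
  monitors <- c("beta", "sigma",
                if (hasRanef) c("tau", "u"),
                if (!priorOnly) "loglik")
  # blocked conjugate updates for the linear-model nodes; without this the
  # society contrast and the country intercepts mix an order of magnitude
  # more slowly
  rjags::load.module("glm", quiet = TRUE)
  mod <- rjags::jags.model(textConnection(jagsHierModel(hasRanef, priorOnly)),
                           data = data, inits = inits, n.chains = chains,
                           n.adapt = adapt, quiet = TRUE)
  stats::update(mod, warmup, progress.bar = "none")
  rjags::coda.samples(mod, monitors, n.iter = iter, progress.bar = "none")
}

#' Summarize posterior draws with dual credible intervals
#'
#' Computes the posterior mean, sd, equal-tailed 89% and 95% percentile
#' intervals, the percentage of draws below zero, and the directional support
#' label derived from it via [supportClassification()] (direction: negative,
#' the convention used for the sleep coefficients).
#'
#' @param draws numeric vector of posterior draws, or a \code{coda::mcmc.list}.
#' @param parameter parameter (column) name when \code{draws} is an mcmc.list;
#'   also used to label the output row.
#' @return one-row data.frame: parameter, estimate, se, ci89_low, ci89_high,
#'   ci95_low, ci95_high, pct_negative, support, n_draws.
#' @export
summarizePosterior <- function(draws, parameter = "parameter") {
  if (inherits(draws, "mcmc.list") || inherits(draws, "mcmc")) {
    m <- as.matrix(draws)
    if (!parameter %in% colnames(m))
      stop("parameter '", parameter, "' not found in draws")
    draws <- m[, parameter]
  }
  draws <- as.numeric(draws)
  if (length(draws) == 0L) stop("no draws to summarize")
  q <- stats::quantile(draws, c(0.055, 0.945, 0.025, 0.975), names = FALSE)
  pctNeg <- 100 * mean(draws < 0)
  data.frame(parameter = parameter, estimate = mean(draws),
             se = stats::sd(draws), ci89_low = q[1], ci89_high = q[2],
             ci95_low = q[3], ci95_high = q[4], pct_negative = pctNeg,
             support = supportClassification(pctNeg),
             n_draws = length(draws), stringsAsFactors = FALSE)
}

#' Classify directional posterior support
#'
#' Maps the percentage of posterior draws in the predicted direction to the
#' labels none (<= 85), weak (85-90], support (90-95], strong (> 95) --
#' intervals closed on the right.
#'
#' @param pct percentage(s) in [0, 100].
#' @return character vector of labels.
#' @export
supportClassification <- function(pct) {
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100))
    stop("pct must lie in [0, 100]")
  labs <- c("none", "weak", "support", "strong")
  labs[findInterval(pct, c(85, 90, 95), left.open = TRUE) + 1L]
}

buildDesign <- function(terms, socInd, zAge, third) {
  X <- cbind(intercept = rep(1, length(socInd)))
  if ("society" %in% terms) X <- cbind(X, society = socInd)
  if ("age" %in% terms) X <- cbind(X, age = zAge)
  if (!is.null(third) && attr(third, "term") %in% terms)
    X <- cbind(X, third)
  X
}

assembleFit <- function(samples, X, grpLevels, model, terms, priors, seed,
                        frame) {
  m <- as.matrix(samples)
  betaCols <- grep("^beta(\\[|$)", colnames(m))
  parNames <- colnames(X)
  prettyNames <- c(intercept = "intercept",
                   society = "society_scale_non_industrial",
                   age = "age_z", male = "pct_male_z", sex = "sex_male")
  rows <- lapply(seq_along(betaCols), function(k)
    summarizePosterior(m[, betaCols[k]],
                       prettyNames[parNames[k]] %||% parNames[k]))
  if (!is.null(grpLevels))
    rows <- c(rows, list(summarizePosterior(m[, "tau"], "country_sd")))
  rows <- c(rows, list(summarizePosterior(m[, "sigma"], "sigma")))
  summ <- do.call(rbind, rows)

  check <- c(colnames(m)[betaCols], if (!is.null(grpLevels)) "tau", "sigma")
  chainsOf <- function(p) lapply(samples, function(ch) as.numeric(ch[, p]))
  rhat <- vapply(check, function(p) splitRhat(chainsOf(p)), numeric(1))
  ess <- tryCatch(coda::effectiveSize(samples)[check],
                  error = function(e) stats::setNames(
                    rep(NA_real_, length(check)), check))
  if (max(rhat) > 1.01)
    stop(sprintf("MCMC has not converged: max split-Rhat %.3f > 1.01 (%s)",
                 max(rhat), check[which.max(rhat)]))

  ranef <- if (!is.null(grpLevels)) {
    uCols <- grep("^u\\[", colnames(m))
    data.frame(country = grpLevels, estimate = colMeans(m[, uCols]),
               stringsAsFactors = FALSE)
  } else data.frame()

  llCols <- grep("^loglik\\[", colnames(m))
  loglik <- if (length(llCols)) m[, llCols, drop = FALSE] else
    matrix(numeric(0), 0, 0)

  new("HierFit", draws = samples, summary = summ, model = model,
      terms = terms, ranef = ranef, loglik = loglik, data = frame,
      diagnostics = list(rhat = rhat, ess = ess), priors = priors,
      seed = as.integer(seed))
}

#' Fit the hierarchical population-level sleep model
#'
#' Gaussian model of per-study mean sleep duration (hours) or efficiency (%)
#' with fixed effects for society scale (industrial is the reference level),
#' z-scored mean age and z-scored % male, and a country random intercept
#' \eqn{u_c \sim N(0, \tau)}.  Posteriors are drawn by MCMC (Gibbs, 4 chains
#' by default) under the informative intercept prior from [priorSet()]; the
#' fit aborts if any monitored parameter has split-Rhat > 1.01.
#'
#' @param table study table as returned by [readStudyTable()] or
#'   [simulateStudyTable()] (columns country, society_scale, mean_age,
#'   pct_male and the outcome column \code{duration_h} / \code{efficiency_pct}).
#' @param outcome "duration" or "efficiency".
#' @param priors a [priorSet()] (default: the outcome's standard priors).
#' @param terms fixed-effect terms to include (subset of
#'   \code{c("society", "age", "male")}).
#' @param chains,iter,warmup,adapt MCMC configuration (post-warmup iterations
#'   per chain).
#' @param seed integer seed driving all chains.
#' @param priorOnly if TRUE, sample from the prior only (no likelihood); used
#'   to verify prior dominance in the no-data limit.
#' @return a [HierFit-class].
#' @export
fitSleepModel <- function(table = NULL, outcome = c("duration", "efficiency"),
                          priors = NULL,
                          terms = c("society", "age", "male"),
                          chains = 4L, iter = 4000L, warmup = 2000L,
                          adapt = 500L, seed = 1L, priorOnly = FALSE) {
  outcome <- match.arg(outcome)
  priors <- priors %||% priorSet(outcome)
  ycol <- if (outcome == "duration") "duration_h" else "efficiency_pct"
  if (priorOnly) {
    table <- data.frame(country = character(), society_scale = character(),
                        mean_age = numeric(), pct_male = numeric())
    table[[ycol]] <- numeric()
  }
  if (!priorOnly) {
    need <- c("country", "society_scale", "mean_age", "pct_male", ycol)
    miss <- setdiff(need, names(table))
    if (length(miss))
      stop("study table lacks column(s): ", paste(miss, collapse = ", "))
    table <- table[!is.na(table[[ycol]]), , drop = FALSE]
    if (!nrow(table)) stop("no rows carry the ", outcome, " outcome")
    if (length(unique(table$country)) < 2L)
      stop("country random intercept is unidentifiable with a single country")
    if ("society" %in% terms && length(unique(table$society_scale)) < 2L)
      stop("society_scale is constant: the contrast is unidentifiable")
  }
  socInd <- as.numeric(table$society_scale == "non-industrial")
  zMale <- cbind(male = zscore(table$pct_male))
  attr(zMale, "term") <- "male"
  X <- buildDesign(terms, socInd, zscore(table$mean_age), zMale)
  g <- as.integer(factor(table$country))
  samples <- runHierMcmc(X, table[[ycol]], if (priorOnly) NULL else g,
                         priors, chains, iter, warmup, adapt, seed,
                         priorOnly = priorOnly)
  assembleFit(samples, X,
              if (priorOnly) NULL else levels(factor(table$country)),
              outcome, terms, priors, seed, as.data.frame(table))
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Fit the subject-level CFI model
#'
#' Gaussian fixed-effects model CFI ~ society_scale + age + sex with the
#' informative Normal(0.58, 0.1) intercept prior; no random term.  Age is
#' z-scored; sex enters as a male indicator.
#'
#' @param table subject table with columns cfi, society_scale, age, sex.
#' @inheritParams fitSleepModel
#' @return a [HierFit-class].
#' @export
fitCfiModel <- function(table, priors = NULL,
                        terms = c("society", "age", "sex"),
                        chains = 4L, iter = 2000L, warmup = 1000L,
                        adapt = 500L, seed = 1L) {
  priors <- priors %||% priorSet("cfi")
  need <- c("cfi", "society_scale", "age", "sex")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("subject table lacks column(s): ", paste(miss, collapse = ", "))
  if (stats::sd(table$cfi) == 0)
    stop("cfi outcome is constant: the model is degenerate")
  if (length(unique(table$society_scale)) < 2L)
    stop("society_scale is constant: the contrast is unidentifiable")
  socInd <- as.numeric(table$society_scale == "non-industrial")
  sexInd <- cbind(sex = as.numeric(table$sex == "male"))
  attr(sexInd, "term") <- "sex"
  X <- buildDesign(terms, socInd, zscore(table$age), sexInd)
  samples <- runHierMcmc(X, table$cfi, NULL, priors, chains, iter, warmup,
                         adapt, seed)
  assembleFit(samples, X, NULL, "cfi", terms, priors, seed,
              as.data.frame(table))
}

#' Posterior contrast between society scales
#'
#' Posterior of the industrial-minus-non-industrial expected outcome
#' difference; with industrial as the reference level this is exactly the
#' negated society-scale coefficient.
#'
#' @param fit a [HierFit-class] whose terms include \code{"society"}.
#' @return one-row posterior summary data.frame (see [summarizePosterior()]).
#' @export
groupContrast <- function(fit) {
  stopifnot(is(fit, "HierFit"))
  if (!"society" %in% fit@terms)
    stop("fit has no society_scale term; no contrast to compute")
  m <- as.matrix(fit@draws)
  idx <- match("society_scale_non_industrial", fit@summary$parameter)
  betaCol <- grep("^beta(\\[|$)", colnames(m))[idx]
  summarizePosterior(-m[, betaCol], "industrial_minus_non_industrial")
}

#' Compare candidate models by leave-one-out predictive fit
#'
#' Computes each candidate's expected log pointwise predictive density (elpd)
#' by leave-one-out cross-validation, either by truncated importance sampling
#' on the full-posterior pointwise log-likelihoods (default; weights truncated
#' at \eqn{\bar w \sqrt S}) or by exact refit per left-out row.  Candidates
#' are fixed-effect term subsets fitted on identical rows.
#'
#' @param table study table (see [fitSleepModel()]).
#' @param termsList named list of character vectors of fixed-effect terms.
#' @param outcome "duration" or "efficiency".
#' @param method "is" (truncated importance sampling) or "exact".
#' @param ... further arguments (chains, iter, seed, ...) for the fits.
#' @return list with \code{elpd} (data.frame: model, elpd, se, ranked best
#'   first) and \code{pairwise} (data.frame of elpd differences with standard
#'   errors, antisymmetric).
#' @export
compareModels <- function(table, termsList, outcome = "duration",
                          method = c("is", "exact"), ...) {
  method <- match.arg(method)
  if (length(termsList) < 2L) stop("need at least 2 candidate models")
  if (is.null(names(termsList)))
    names(termsList) <- vapply(termsList, function(t)
      paste(c("1", t), collapse = "+"), character(1))
  pointwise <- lapply(termsList, function(terms) {
    if (method == "is") {
      fit <- fitSleepModel(table, outcome, terms = terms, ...)
      L <- fit@loglik                       # S x N
      S <- nrow(L)
      vapply(seq_len(ncol(L)), function(i) {
        logw <- -L[, i]
        cap <- logSumExp(logw) - log(S) + 0.5 * log(S)   # wbar * sqrt(S)
        logw <- pmin(logw, cap)
        logSumExp(logw + L[, i]) - logSumExp(logw)
      }, numeric(1))
    } else {
      vapply(seq_len(nrow(table)), function(i) {
        fit <- fitSleepModel(table[-i, , drop = FALSE], outcome,
                             terms = terms, ...)
        m <- as.matrix(fit@draws)
        mu <- predictRow(fit, m, table[i, , drop = FALSE])
        ycol <- if (outcome == "duration") "duration_h" else "efficiency_pct"
        logSumExp(stats::dnorm(table[[ycol]][i], mu, m[, "sigma"],
                               log = TRUE)) - log(nrow(m))
      }, numeric(1))
    }
  })
  n <- unique(vapply(pointwise, length, integer(1)))
  if (length(n) != 1L) stop("candidates were scored on mismatched row sets")
  elpd <- data.frame(
    model = names(termsList),
    elpd = vapply(pointwise, sum, numeric(1)),
    se = vapply(pointwise, function(p) stats::sd(p) * sqrt(length(p)),
                numeric(1)),
    stringsAsFactors = FALSE)
  elpd <- elpd[order(-elpd$elpd), ]
  pairs <- expand.grid(model_a = names(termsList), model_b = names(termsList),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$model_a != pairs$model_b, ]
  pairs$elpd_diff <- mapply(function(a, b) sum(pointwise[[a]] - pointwise[[b]]),
                            pairs$model_a, pairs$model_b)
  pairs$se_diff <- mapply(function(a, b)
    stats::sd(pointwise[[a]] - pointwise[[b]]) * sqrt(n),
    pairs$model_a, pairs$model_b)
  rownames(elpd) <- rownames(pairs) <- NULL
  list(elpd = elpd, pairwise = pairs)
}

# posterior linear predictor for a held-out study row (mean over its country's
# posterior intercept draws; a new country draws u ~ N(0, tau))
predictRow <- function(fit, m, row) {
  X <- fit@data
  zA <- (row$mean_age - mean(X$mean_age)) / stats::sd(X$mean_age)
  zM <- (row$pct_male - mean(X$pct_male)) / stats::sd(X$pct_male)
  betaCols <- grep("^beta(\\[|$)", colnames(m))
  pars <- fit@summary$parameter
  mu <- m[, betaCols[1]]
  if ("society_scale_non_industrial" %in% pars)
    mu <- mu + m[, betaCols[match("society_scale_non_industrial", pars)]] *
      (row$society_scale == "non-industrial")
  if ("age_z" %in% pars)
    mu <- mu + m[, betaCols[match("age_z", pars)]] * zA
  if ("pct_male_z" %in% pars)
    mu <- mu + m[, betaCols[match("pct_male_z", pars)]] * zM
  uCols <- grep("^u\\[", colnames(m))
  if (length(uCols)) {
    lev <- levels(factor(X$country))
    j <- match(row$country, lev)
    mu <- mu + if (!is.na(j)) m[, uCols[j]] else
      stats::rnorm(nrow(m), 0, m[, "tau"])
  }
  mu
}
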