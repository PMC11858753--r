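test_that("posterior summaries report dual intervals and signs correctly", {
  d <- rep(c(-1, -1, 1, 1), 500)
  s <- summarizePosterior(d, "sym")
  expect_equal(s$pct_negative, 50)
  expect_equal(s$estimate, 0)
  expect_identical(s$support, "none")

  set.seed(1)
  z <- rnorm(1e5)
  s <- summarizePosterior(z)
  expect_equal(s$ci95_low, -1.96, tolerance = 0.02)
  expect_equal(s$ci95_high, 1.96, tolerance = 0.02)
  expect_equal(s$ci89_low, qnorm(0.055), tolerance = 0.02)

  # the 89% interval contains ~89% of fresh draws from the same distribution
  held <- rnorm(1e5)
  inside <- mean(held >= s$ci89_low & held <= s$ci89_high)
  expect_equal(inside, 0.89, tolerance = 0.01)

  # permutation invariance
  p <- sample(length(z))
  expect_equal(summarizePosterior(z[p])[-1], s[-1])

  expect_error(summarizePosterior(numeric(0)), "no draws")
})

test_that("support classification reproduces the reporting bands", {
  expect_identical(supportClassification(98.4), "strong")
  expect_identical(supportClassification(100), "strong")
  expect_identical(supportClassification(50), "none")
  expect_identical(supportClassification(87), "weak")
  # right-closed boundaries
  expect_identical(supportClassification(c(85, 90, 95)),
                   c("none", "weak", "support"))
  expect_identical(supportClassification(c(85.0001, 90.0001, 95.0001)),
                   c("weak", "support", "strong"))
  expect_error(supportClassification(101), "0, 100")
  expect_error(supportClassification(-2), "0, 100")
  # total function: labels partition [0, 100]
  grid <- seq(0, 100, by = 0.25)
  expect_true(all(supportClassification(grid) %in%
                    c("none", "weak", "support", "strong")))
})

test_that("sleep-model preconditions fail loudly", {
  tab <- simulateStudyTable(nStudies = 10, nCountries = 4, seed = 1)
  one <- tab; one$country <- "X"
  expect_error(fitSleepModel(one, "duration"), "single country")
  flat <- tab; flat$society_scale <- "industrial"
  expect_error(fitSleepModel(flat, "duration"), "constant")
  expect_error(fitSleepModel(tab, "efficiency"), "efficiency")
  expect_error(fitSleepModel(tab[0, ], "duration"), "")
})

test_that("duration model recovers known truths from simulated tables", {
  tab <- simulateStudyTable(seed = 77)
  fit <- fitSleepModel(tab, "duration", seed = 7)
  summ <- posteriorSummary(fit)
  b <- summ[summ$parameter == "society_scale_non_industrial", ]
  expect_lt(abs(b$estimate - (-0.75)), 2 * b$se)
  i <- summ[summ$parameter == "intercept", ]
  expect_lt(abs(i$estimate - 7.16), 2.5 * i$se)
  # dual intervals are nested
  expect_true(all(summ$ci89_low >= summ$ci95_low - 1e-9))
  expect_true(all(summ$ci89_high <= summ$ci95_high + 1e-9))
  expect_true(all(fit@diagnostics$rhat < 1.01))
  expect_equal(nrow(randomIntercepts(fit)), 21L)

  # contrast is the negated society coefficient
  ct <- groupContrast(fit)
  expect_equal(ct$estimate, -b$estimate)

  fit0 <- fitSleepModel(tab, "duration", terms = c("age", "male"),
                        chains = fastMcmc$chains, iter = fastMcmc$iter,
                        warmup = fastMcmc$warmup, adapt = fastMcmc$adapt,
                        seed = 7)
  expect_error(groupContrast(fit0), "society")
})

test_that("a pure group offset is recovered by the contrast", {
  tab <- simulateStudyTable(nStudies = 30, nCountries = 10, intercept = 7,
                            betaSociety = -0.9, betaAge = 0, betaMale = 0,
                            countrySd = 0.05, residualSd = 0.05, seed = 21)
  fit <- fitSleepModel(tab, "duration", chains = fastMcmc$chains,
                       iter = fastMcmc$iter, warmup = fastMcmc$warmup,
                       adapt = fastMcmc$adapt, seed = 2)
  expect_equal(groupContrast(fit)$estimate, 0.9, tolerance = 0.12)
})

test_that("with no data the duration intercept posterior is its prior", {
  fit <- fitSleepModel(outcome = "duration", priorOnly = TRUE, seed = 5)
  s <- posteriorSummary(fit)
  i <- s[s$parameter == "intercept", ]
  expect_equal(i$estimate, 8, tolerance = 0.05)
  expect_equal(i$se, 1, tolerance = 0.05)
})

test_that("the CFI model detects the preset contrast and rejects bad input", {
  non <- cohortCfi(simulateCohort("non-industrial", 40, seed = 1))
  ind <- cohortCfi(simulateCohort("industrial", 60, seed = 2))
  tab <- rbind(non, ind)
  fit <- fitCfiModel(tab, seed = 3)
  summ <- posteriorSummary(fit)
  b <- summ[summ$parameter == "society_scale_non_industrial", ]
  # CFI model codes the non-industrial level, whose CFI is higher: the
  # coefficient is positive, i.e. nearly no draws negative
  expect_lt(b$pct_negative, 5)
  expect_identical(summ$parameter[1], "intercept")

  flat <- tab; flat$cfi <- 0.5
  expect_error(fitCfiModel(flat), "constant")
  one <- tab; one$society_scale <- "industrial"
  expect_error(fitCfiModel(one), "unidentifiable")
})

test_that("a zero true age effect yields an age interval covering zero", {
  non <- cohortCfi(simulateCohort("non-industrial", 30, seed = 11))
  ind <- cohortCfi(simulateCohort("industrial", 30, seed = 12))
  tab <- rbind(non, ind)
  # age is generated independently of the rhythm parameters, so its true
  # effect on CFI is nil by construction
  fit <- fitCfiModel(tab, chains = fastMcmc$chains, iter = fastMcmc$iter,
                     warmup = fastMcmc$warmup, adapt = fastMcmc$adapt,
                     seed = 4)
  s <- posteriorSummary(fit)
  a <- s[s$parameter == "age_z", ]
  expect_lt(a$ci95_low, 0)
  expect_gt(a$ci95_high, 0)
})

test_that("LOO comparison ranks models by predictive fit", {
  mc <- list(chains = 2L, iter = 3500L, warmup = 1000L, adapt = 300L,
             seed = 8)
  tab <- simulateStudyTable(nStudies = 40, nCountries = 10,
                            betaSociety = -2.5, countrySd = 0.8,
                            residualSd = 0.5, seed = 31)
  cmp <- do.call(compareModels,
                 c(list(tab, list(full = c("society", "age", "male"),
                                  nosoc = c("age", "male"))), mc))
  expect_identical(cmp$elpd$model[1], "full")
  d <- cmp$pairwise
  expect_gt(d$elpd_diff[d$model_a == "full" & d$model_b == "nosoc"], 0)
  # antisymmetry
  expect_equal(d$elpd_diff[d$model_a == "full"],
               -d$elpd_diff[d$model_a == "nosoc"])

  # identical candidates tie to numerical tolerance
  cmp2 <- do.call(compareModels,
                  c(list(tab, list(a = c("society"), b = c("society"))), mc))
  expect_lt(abs(cmp2$pairwise$elpd_diff[1]), 1e-6)

  # with no true society effect the elpd difference is within 2 se
  tab0 <- simulateStudyTable(nStudies = 40, nCountries = 10,
                             betaSociety = 0, seed = 32)
  cmp0 <- do.call(compareModels,
                  c(list(tab0, list(full = c("society", "age", "male"),
                                    nosoc = c("age", "male"))), mc))
  d0 <- cmp0$pairwise[1, ]
  expect_lt(abs(d0$elpd_diff), 2 * max(d0$se_diff, 0.5))

  expect_error(compareModels(tab, list(c("society"))), "at least 2")
})

test_that("exact and importance-sampling LOO agree on a small table", {
  mc <- list(chains = 2L, iter = 2500L, warmup = 800L, adapt = 300L, seed = 6)
  tab <- simulateStudyTable(nStudies = 12, nCountries = 4, seed = 41)
  is_ <- do.call(compareModels,
                 c(list(tab, list(m1 = "society", m2 = character(0)),
                        method = "is"), mc))
  ex <- do.call(compareModels,
                c(list(tab, list(m1 = "society", m2 = character(0)),
                       method = "exact"), mc))
  m <- merge(is_$elpd, ex$elpd, by = "model")
  expect_equal(m$elpd.x, m$elpd.y, tolerance = 0.25)
})
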