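test_that("binning averages epochs, trims partial days, and flags bad bins", {
  # constant 1-min signal over one day
  rec <- ActigraphyRecording(rep(5, 1440))
  s <- binRecording(rec)
  expect_identical(nDays(s), 1L)
  expect_equal(binValues(s), rep(5, 24), ignore_attr = TRUE)

  # 2 complete days + 3 trailing hours -> trailing hours trimmed
  rec <- ActigraphyRecording(c(rep(1, 2 * 1440), rep(9, 180)))
  s <- binRecording(rec)
  expect_identical(nDays(s), 2L)
  expect_equal(binValues(s), rep(1, 48), ignore_attr = TRUE)

  # leading partial day (start at 21:00) is dropped before binning
  rec <- ActigraphyRecording(
    c(rep(9, 180), rep(2, 1440)),
    startTime = as.POSIXct("2020-01-05 21:00:00", tz = "UTC"))
  s <- binRecording(rec)
  expect_identical(nDays(s), 1L)
  expect_equal(binValues(s), rep(2, 24), ignore_attr = TRUE)

  # alternating 0/10 within each hour averages to 5
  rec <- ActigraphyRecording(rep(c(0, 10), 1440 / 2))
  expect_equal(binValues(binRecording(rec)), rep(5, 24), ignore_attr = TRUE)

  # binned value equals the plain mean of that bin's epochs
  set.seed(42)
  x <- rpois(2 * 1440, 20)
  s <- binRecording(ActigraphyRecording(x))
  expect_equal(binValues(s),
               as.numeric(tapply(x, rep(1:48, each = 60), mean)),
               ignore_attr = TRUE)

  # zero complete days
  expect_error(binRecording(ActigraphyRecording(rep(1, 100))),
               "zero complete days")

  # an all-missing bin is named in the error
  x <- rep(5, 1440); x[61:120] <- NA
  expect_error(binRecording(ActigraphyRecording(x), maxMissingFrac = 0.5),
               "bin 2")

  # missing-fraction gate
  x <- rep(5, 1440); x[1:600] <- NA
  expect_error(binRecording(ActigraphyRecording(x)), "missing fraction")
})

test_that("profile imputation fills missing bins and warns", {
  x <- rep(rep(1:24, each = 60), 3)
  x[1:45] <- NA                      # bin 1 of day 1 is 75% missing
  rec <- ActigraphyRecording(x)
  expect_warning(s <- binRecording(rec, impute = "profile"), "imputed")
  expect_equal(binValues(s)[1], 1)   # bin-of-day mean from days 2-3
  expect_error(binRecording(rec, impute = "none"), "missing")
})

test_that("interdaily stability is 1 for repeated days and matches the formula", {
  day <- c(rep(100, 10), rep(0, 14))
  expect_equal(interdailyStability(asBinnedSeries(rep(day, 7))), 1)

  expect_error(interdailyStability(asBinnedSeries(rep(3, 48))),
               "undefined IS")
  expect_error(interdailyStability(asBinnedSeries(1:24)), "at least 2")

  set.seed(7)
  x <- rnorm(24 * 30)
  expect_equal(interdailyStability(asBinnedSeries(x)), bruteIS(x, 24))
})

test_that("intradaily variability matches closed forms and the oracle", {
  # sampled pure cosine: IV = [n/(n-1)] * 2 * (1 - cos(2*pi/p))
  p <- 24; d <- 7; n <- p * d
  x <- 50 + 40 * cos(2 * pi * (0:(n - 1)) / p)
  expect_equal(intradailyVariability(asBinnedSeries(x)),
               n / (n - 1) * 2 * (1 - cos(2 * pi / p)), tolerance = 1e-3)

  # alternating two values: IV = 4 exactly (MSSD (a-b)^2, variance (a-b)^2/4)
  expect_equal(intradailyVariability(asBinnedSeries(rep(c(2, 8), 24))), 4)

  # iid Gaussian noise -> IV ~ 2
  set.seed(11)
  g <- rnorm(9984)
  expect_equal(intradailyVariability(asBinnedSeries(g)), 2, tolerance = 0.05)

  set.seed(3)
  x <- rlnorm(24 * 10)
  expect_equal(intradailyVariability(asBinnedSeries(x)), bruteIV(x))

  expect_error(intradailyVariability(asBinnedSeries(rep(1, 48))),
               "undefined IV")
})

test_that("relative amplitude handles square waves, constants and cosines", {
  day <- c(rep(0, 8), rep(100, 10), rep(0, 6))   # on 08:00-18:00
  ra <- relativeAmplitude(asBinnedSeries(rep(day, 7)))
  expect_equal(ra$RA, 1)
  expect_equal(ra$M10, 100)
  expect_equal(ra$L5, 0)
  expect_equal(ra$M10onsetHour, 8)

  rc <- relativeAmplitude(asBinnedSeries(rep(3, 24)))
  expect_equal(rc$RA, 0)
  expect_equal(rc$M10, 3)

  # all-zero profile: RA = 0 by convention
  expect_equal(relativeAmplitude(asBinnedSeries(rep(0, 24)))$RA, 0)

  # cosine profile: equals exhaustive wrapped-window search
  prof <- 1 + cos(2 * pi * ((0:23) - 14) / 24)
  ra <- relativeAmplitude(asBinnedSeries(prof))
  expect_equal(ra$RA, bruteRA(prof))

  expect_error(relativeAmplitude(asBinnedSeries(c(-1, rep(1, 23)))),
               "non-negative")
})

test_that("RA window scan equals brute force on random wrapped profiles", {
  set.seed(99)
  for (i in 1:25) {
    prof <- rlnorm(24)
    expect_equal(relativeAmplitude(asBinnedSeries(prof))$RA, bruteRA(prof))
  }
})

test_that("CFI composition is the mean of the normalized components", {
  expect_equal(cfiCompose(1, 0, 1)$CFI, 1)
  expect_equal(cfiCompose(0, 2, 0)$CFI, 0)

  c1 <- cfiCompose(0.6, 0.8, 0.7)
  expect_equal(c1$IVinvNorm, 0.6)
  expect_equal(c1$CFI, (0.6 + 0.6 + 0.7) / 3)

  # IV beyond 2 clips the inverted component at 0
  c2 <- cfiCompose(0.5, 3.0, 0.5)
  expect_equal(c2$IVinvNorm, 0)
  expect_equal(c2$CFI, 1 / 3)

  expect_error(cfiCompose(1.2, 0, 0.5), "IS")
  expect_error(cfiCompose(0.5, -1, 0.5), "IV")
  expect_error(cfiCompose(0.5, 0, 2), "RA")

  # exact-mean property over random admissible triples
  set.seed(5)
  for (i in 1:20) {
    IS <- runif(1); IV <- runif(1, 0, 3); RA <- runif(1)
    cc <- cfiCompose(IS, IV, RA)
    expect_identical(cc$CFI, (IS + cc$IVinvNorm + RA) / 3)
    expect_gte(cc$CFI, 0); expect_lte(cc$CFI, 1)
  }
})

test_that("end-to-end NPCRA matches the component oracles on a square wave", {
  rec <- squareWaveRecording(days = 7)
  r <- npcra(rec)
  # IS = 1 (identical days), RA = 1, IV from the binned square wave directly
  day <- c(rep(0, 8), rep(100, 10), rep(0, 6))
  expect_equal(r@IS, 1)
  expect_equal(r@RA, 1)
  expect_equal(r@IV, bruteIV(rep(day, 7)))
  comp <- cfiCompose(1, bruteIV(rep(day, 7)), 1)
  expect_equal(cfi(r), comp$CFI)
  expect_identical(nDays(r), 7L)
})

test_that("the six-night minimum is enforced and overridable", {
  rec5 <- squareWaveRecording(days = 5)
  expect_error(npcra(rec5), "6")
  expect_warning(r <- npcra(rec5, allowShort = TRUE), "5 complete days")
  expect_s4_class(r, "NPCRAResult")
  expect_identical(nDays(r), 5L)
})

test_that("NPCRA statistics obey their scale and shift invariances", {
  set.seed(21)
  base <- abs(50 + 40 * cos(2 * pi * (0:(24 * 7 - 1)) / 24) +
                rnorm(24 * 7, 0, 10))
  s <- asBinnedSeries(base)
  IS <- interdailyStability(s); IV <- intradailyVariability(s)
  RA <- relativeAmplitude(s)$RA

  for (k in c(0.5, 3, 17)) {                 # positive rescaling
    sk <- asBinnedSeries(base * k)
    expect_equal(interdailyStability(sk), IS)
    expect_equal(intradailyVariability(sk), IV)
    expect_equal(relativeAmplitude(sk)$RA, RA)
  }
  # IV is invariant to adding a constant
  expect_equal(intradailyVariability(asBinnedSeries(base + 123)), IV)

  # IS stays in [0, 1] on arbitrary complete balanced series
  for (i in 1:20) {
    x <- rnorm(24 * sample(2:10, 1))
    v <- interdailyStability(asBinnedSeries(x))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("increasing noise does not increase median CFI", {
  medianCfi <- function(noiseSd) {
    stats::median(vapply(1:5, function(s)
      cfi(npcra(simulateRecording(mesor = 50, amplitude = 45,
                                  noiseSd = noiseSd, seed = 1000 + s))),
      numeric(1)))
  }
  m <- vapply(c(0, 15, 40, 90), medianCfi, numeric(1))
  expect_true(all(diff(m) <= 1e-9))
})
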