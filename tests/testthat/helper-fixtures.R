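# shared fixtures, built in code at test time

# recording that is `days` copies of a 24-h square wave: `high` counts for
# 10 consecutive hours starting at `onHour`, `low` elsewhere
squareWaveRecording <- function(days = 7, high = 100, low = 0, onHour = 8,
                                epochSeconds = 60L) {
  epd <- 86400L %/% epochSeconds
  hour <- floor(((seq_len(epd) - 0.5) * epochSeconds) / 3600)
  day <- ifelse(hour >= onHour & hour < onHour + 10, high, low)
  ActigraphyRecording(rep(day, days), epochSeconds = epochSeconds)
}

# independent brute-force IS/IV oracles, written directly from the formulas
bruteIS <- function(x, p) {
  d <- length(x) / p
  xbar <- mean(x)
  profile <- sapply(seq_len(p), function(h) mean(x[h + p * (seq_len(d) - 1)]))
  (sum((profile - xbar)^2) / p) / (sum((x - xbar)^2) / length(x))
}

bruteIV <- function(x) {
  n <- length(x)
  num <- sum((x[-1] - x[-n])^2) / (n - 1)
  num / (sum((x - mean(x))^2) / n)
}

# exhaustive circular window scan for M10/L5 on a p-bin average profile
bruteRA <- function(profile) {
  p <- length(profile)
  wrap <- function(idx) profile[(idx - 1) %% p + 1]
  w10 <- 10 * p / 24; w5 <- 5 * p / 24
  m10 <- max(sapply(seq_len(p), function(i) mean(wrap(i:(i + w10 - 1)))))
  l5 <- min(sapply(seq_len(p), function(i) mean(wrap(i:(i + w5 - 1)))))
  if (m10 + l5 == 0) 0 else (m10 - l5) / (m10 + l5)
}

# small valid study table for IO tests
tinyStudyTable <- function() {
  data.frame(
    study_id = c("s1", "s2"), country = c("Namibia", "USA"),
    society_scale = c("non-industrial", "industrial"),
    mean_age = c(32, 45), pct_male = c(48, 52),
    sample_size = c(30, 200), latitude = c(-22.6, 38.9),
    longitude = c(17.1, -77.0), method = c("actigraphy", "PSG"),
    duration_h = c(5.5, 7.2), stringsAsFactors = FALSE)
}

# small MCMC settings used where a test needs a fit but not fine posteriors
fastMcmc <- list(chains = 2L, iter = 1500L, warmup = 750L, adapt = 300L)
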