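#' @include hier.R
NULL

#' Moran's I spatial autocorrelation with permutation inference
#'
#' Computes \deqn{I = \frac{n}{W} \frac{\sum_i \sum_j w_{ij} z_i z_j}{\sum_i z_i^2}}
#' on centred values \eqn{z_i = x_i - \bar x}, with spatial weights derived
#' from great-circle (haversine) distances between unit coordinates: inverse
#' distance, zero diagonal, optionally row-standardized.  Pairwise distances
#' are floored at 1 km so coincident coordinates cannot produce infinite
#' weights.  The null expectation is \eqn{-1/(n-1)}; the two-sided p-value
#' comes from seeded random permutations of the values over the units.
#'
#' Typical use is screening the per-country random intercepts of a fitted
#' hierarchical sleep model (see [randomIntercepts()]) for residual spatial
#' structure.
#'
#' @param values numeric vector, one value per spatial unit (non-constant).
#' @param latitude,longitude coordinates in degrees ([-90, 90], [-180, 180]).
#' @param rowStandardize row-standardize the weight matrix (default TRUE).
#' @param nPermutations permutations for the null distribution (default 9999).
#' @param seed integer seed for the permutations.
#' @return a [MoranResult-class].
#' @export
moransI <- function(values, latitude, longitude, rowStandardize = TRUE,
                    nPermutations = 9999L, seed = 1L) {
  n <- length(values)
  if (n < 3L) stop("Moran's I needs at least 3 units")
  if (length(latitude) != n || length(longitude) != n)
    stop("values and coordinates must have equal length")
  if (any(abs(latitude) > 90) || any(abs(longitude) > 180))
    stop("coordinates out of range")
  if (stats::sd(values) == 0)
    stop("values are constant: Moran's I is undefined")
  nPermutations <- as.integer(nPermutations)

  km <- geosphere::distm(cbind(longitude, latitude),
                         fun = geosphere::distHaversine) / 1000
  km <- pmax(km, 1)                      # floor: coincident units
  w <- 1 / km
  diag(w) <- 0
  if (rowStandardize) w <- w / rowSums(w)

  stat <- function(x) {
    z <- x - mean(x)
    (n / sum(w)) * sum(w * tcrossprod(z)) / sum(z^2)
  }
  I <- stat(values)
  e <- -1 / (n - 1)
  perm <- withSeed(seed, vapply(seq_len(nPermutations),
                                function(i) stat(sample(values)), numeric(1)))
  p <- (1 + sum(abs(perm - e) >= abs(I - e) - 1e-12)) / (nPermutations + 1)

  new("MoranResult", I = I, expectedI = e, pValue = p, nUnits = as.integer(n),
      weightScheme = paste0("inverse haversine distance",
                            if (rowStandardize) ", row-standardized"),
      nPermutations = nPermutations)
}

#' Moran screen of a fitted model's country intercepts
#'
#' Convenience wrapper: extracts per-country random-intercept posterior means
#' from a [HierFit-class] and per-country coordinates (averaged over that
#' country's studies) from the model frame, then calls [moransI()].
#'
#' @param fit a [HierFit-class] with a country random effect.
#' @param ... passed to [moransI()].
#' @return a [MoranResult-class].
#' @export
moranOnRanef <- function(fit, ...) {
  stopifnot(is(fit, "HierFit"))
  if (!nrow(fit@ranef)) stop("fit has no random intercepts")
  fr <- fit@data
  lat <- tapply(fr$latitude, fr$country, mean)
  lon <- tapply(fr$longitude, fr$country, mean)
  lev <- fit@ranef$country
  moransI(fit@ranef$estimate, as.numeric(lat[lev]), as.numeric(lon[lev]), ...)
}
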