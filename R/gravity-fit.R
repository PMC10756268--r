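EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance matrix
#'
#' Haversine great-circle distances in kilometers on a sphere of radius
#' 6371.0088 km, with a distance floor: entries below `floorKm` are imputed
#' to `floorKm` (1 km by default, matching the treatment of co-located
#' organizations and airports; 0.01 km suits intra-city corpora).
#'
#' @param locations a location table as returned by [readLocations()]
#'   (needs `token`, `latitude`, `longitude`).
#' @param floorKm distance floor in km (default 1).
#' @return A [DistanceMatrix-class] with metric `"geographic_km"`.
#' @examples
#' locs <- data.frame(token = c("a", "b"), latitude = c(0, 0),
#'                    longitude = c(0, 1))
#' distanceValues(geographicDistance(locs))
#' @export
geographicDistance <- function(locations, floorKm = 1.0) {
  need <- c("token", "latitude", "longitude")
  if (!all(need %in% names(locations)))
    stopValidation("locations must have token, latitude, longitude columns")
  miss <- locations$token[is.na(locations$latitude) |
                          is.na(locations$longitude)]
  if (length(miss))
    stopValidation("missing coordinates for: ", paste(miss, collapse = ", "))
  m <- cbind(locations$longitude, locations$latitude)
  vals <- geosphere::distm(m, fun = function(a, b)
    geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM))
  vals[vals < floorKm] <- floorKm
  diag(vals) <- 0
  vals <- (vals + t(vals)) / 2
  dimnames(vals) <- list(locations$token, locations$token)
  new("DistanceMatrix", tokens = locations$token, values = vals,
      metric = "geographic_km", floor = floorKm)
}

#' Embedding distance matrix
#'
#' Pairwise dissimilarity between the in-vectors of a trained model:
#' `"cosine"` is 1 - cos(v_i, v_j) in [0, 2]; `"euclidean"` the L2
#' distance; `"dot"` is an order-reversing affine transform of the inner
#' product, max(v.v) - v_i.v_j — only its ordering is meaningful, which is
#' all the exponential gravity fit and rank-based comparisons use.
#'
#' @param model an [EmbeddingModel-class].
#' @param metric `"cosine"`, `"dot"` or `"euclidean"`.
#' @return A [DistanceMatrix-class].
#' @export
embeddingDistance <- function(model, metric = c("cosine", "dot", "euclidean")) {
  metric <- match.arg(metric)
  V <- model@inVectors
  tk <- model@vocabulary@tokens
  if (metric == "cosine") {
    nr <- sqrt(rowSums(V^2))
    zero <- nr == 0
    if (any(zero))
      stopValidation("zero-norm vector(s) under cosine: ",
                     paste(tk[zero], collapse = ", "))
    C <- tcrossprod(V / nr)
    C[C > 1] <- 1
    C[C < -1] <- -1
    vals <- 1 - C
    metricName <- "cosine"
  } else if (metric == "dot") {
    S <- tcrossprod(V)
    vals <- max(S) - S
    metricName <- "dot_dissimilarity"
  } else {
    vals <- as.matrix(stats::dist(V))
    metricName <- "euclidean"
  }
  diag(vals) <- 0
  vals <- (vals + t(vals)) / 2
  vals[vals < 0] <- 0
  dimnames(vals) <- list(tk, tk)
  new("DistanceMatrix", tokens = tk, values = vals, metric = metricName,
      floor = 0)
}

alignedPairs <- function(flux, masses, distances) {
  tk <- tokens(flux)
  if (!all(tk %in% names(masses)))
    stopValidation("masses missing for: ",
                   paste(setdiff(tk, names(masses)), collapse = ", "))
  if (!all(tk %in% distances@tokens))
    stopValidation("distances missing for: ",
                   paste(setdiff(tk, distances@tokens), collapse = ", "))
  m <- masses[tk]
  if (any(is.na(m) | m <= 0)) stopValidation("all masses must be positive")
  Tm <- if (is(flux, "FluxMatrix")) flux@counts else flux@values
  D <- distances@values[tk, tk]
  ut <- upper.tri(Tm)
  keep <- ut & Tm > 0
  list(tokens = tk, t = Tm[keep], d = D[keep],
       mm = outer(m, m)[keep], n = sum(keep))
}

#' Fit the gravity law by log-linear regression
#'
#' Ordinary least squares of ln(T_ij / (m_i m_j)) on -ln(g_ij) (power
#' family) or on -d_ij (exponential family), over unordered pairs with
#' positive flux (zero flows are excluded, following standard practice).
#' The slope is the decay exponent (alpha or beta) and exp(intercept) the
#' constant C.  The conventional pairing is the power law for geographic
#' distance and the exponential for embedding distance.
#'
#' @param flux a [FluxMatrix-class] (or [ExpectedFlux-class]) of observed
#'   flows.
#' @param masses named positive vector of location masses m_i.
#' @param distances a [DistanceMatrix-class].
#' @param family `"power"` or `"exponential"`.
#' @return A [GravityFit-class].
#' @export
fitGravity <- function(flux, masses, distances,
                       family = c("power", "exponential")) {
  family <- match.arg(family)
  ap <- alignedPairs(flux, masses, distances)
  if (ap$n < 3L)
    stopValidation("need at least 3 positive-flux pairs, have ", ap$n)
  y <- log(ap$t / ap$mm)
  x <- if (family == "power") {
    if (any(ap$d <= 0))
      stopValidation("power family needs strictly positive distances")
    -log(ap$d)
  } else -ap$d
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  resid <- stats::residuals(fit)
  r2 <- stats::cor(stats::fitted(fit), y)^2
  exponent <- unname(co["x"])
  if (exponent <= 0) {
    warning("fitted decay exponent is non-positive (flux does not decrease ",
            "with distance); clamping to a vanishing decay")
    exponent <- .Machine$double.eps
  }
  new("GravityFit",
      decay = DecaySpec(family, exponent = exponent,
                        constant = exp(unname(co["(Intercept)"]))),
      nPairs = as.integer(ap$n), rSquared = unname(r2),
      rmseLog = sqrt(mean(resid^2)),
      residuals = c(min = min(resid), q25 = unname(stats::quantile(resid, .25)),
                    median = stats::median(resid),
                    q75 = unname(stats::quantile(resid, .75)),
                    max = max(resid)))
}

#' Predict flux under a fitted gravity law
#'
#' Evaluates T-hat_ij = C m_i m_j f(r_ij) with the fitted decay over a
#' distance matrix; symmetric with zero diagonal.
#'
#' @param fit a [GravityFit-class] (or any [DecaySpec-class]).
#' @param masses named positive masses.
#' @param distances a [DistanceMatrix-class].
#' @return An [ExpectedFlux-class].
#' @export
predictFlux <- function(fit, masses, distances) {
  decay <- if (is(fit, "GravityFit")) fit@decay else fit
  tk <- distances@tokens
  if (!all(tk %in% names(masses)))
    stopValidation("masses missing for: ",
                   paste(setdiff(tk, names(masses)), collapse = ", "))
  m <- masses[tk]
  r <- distances@values
  f <- if (decay@family == "power") pmax(r, 1e-9)^(-decay@exponent)
       else exp(-decay@exponent * r)
  vals <- decay@constant * outer(m, m) * f
  diag(vals) <- 0
  dimnames(vals) <- list(tk, tk)
  new("ExpectedFlux", tokens = tk, values = vals)
}

#' Evaluate a flux prediction
#'
#' Three standard scores over unordered pairs: `r_squared_loglog`, the
#' squared Pearson correlation between log T and log T-hat over positive
#' observed flows; `rmse_log10`, the root-mean-square error between log10
#' observed and predicted flux on the same pairs; and `cpc`, the common
#' part of commuters 2 sum(min(T, T-hat)) / (sum T + sum T-hat) over all
#' pairs (a Sorensen-style overlap in [0, 1]).
#'
#' @param actual observed [FluxMatrix-class].
#' @param predicted an [ExpectedFlux-class] on the same tokens.
#' @return A list with `r_squared_loglog`, `rmse_log10`, `cpc` and `n_pairs`.
#' @export
evaluateFit <- function(actual, predicted) {
  tk <- tokens(actual)
  if (!all(tk %in% predicted@tokens))
    stopValidation("predicted flux missing tokens: ",
                   paste(setdiff(tk, predicted@tokens), collapse = ", "))
  Tm <- actual@counts
  Ph <- predicted@values[tk, tk]
  ut <- upper.tri(Tm)
  if (sum(ut & Tm > 0) < 3L)
    stopValidation("need at least 3 positive-flux pairs")
  pos <- ut & Tm > 0 & Ph > 0
  if (sum(pos) >= 3L) {
    lT <- log10(Tm[pos])
    lP <- log10(Ph[pos])
    r2 <- stats::cor(lT, lP)^2
    rmse <- sqrt(mean((lT - lP)^2))
  } else {
    # log-scale scores undefined when predictions vanish on observed flows
    r2 <- NA_real_
    rmse <- NA_real_
  }
  list(r_squared_loglog = r2, rmse_log10 = rmse,
       cpc = 2 * sum(pmin(Tm[ut], Ph[ut])) / (sum(Tm[ut]) + sum(Ph[ut])),
       n_pairs = sum(pos))
}

#' Mean flux across distance bins
#'
#' Bins positive-flux unordered pairs into `nBins` equal-width bins on the
#' chosen scale and reports the mean flux per bin with a 99% normal
#' confidence interval (mean +/- 2.576 SE) — the summary plotted as black
#' dots over flux-distance clouds.
#'
#' @param distances a [DistanceMatrix-class].
#' @param flux a [FluxMatrix-class] on the same tokens.
#' @param nBins number of bins (>= 2).
#' @param scale `"log"` (default) or `"linear"` bin spacing.
#' @return A `data.frame` with `center`, `mean_flux`, `ci_low`, `ci_high`,
#'   `n_pairs`.
#' @export
binnedFlux <- function(distances, flux, nBins = 20L, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  nBins <- as.integer(nBins)
  if (nBins < 2L) stopValidation("nBins must be >= 2")
  tk <- tokens(flux)
  D <- distances@values[tk, tk]
  Tm <- flux@counts
  keep <- upper.tri(Tm) & Tm > 0
  d <- D[keep]
  t <- Tm[keep]
  x <- if (scale == "log") {
    if (any(d <= 0)) stopValidation("log-scale bins need positive distances")
    log10(d)
  } else d
  br <- seq(min(x), max(x), length.out = nBins + 1L)
  br[1] <- br[1] - 1e-9
  bin <- cut(x, br, labels = FALSE)
  centers <- (br[-1] + br[-length(br)]) / 2
  if (scale == "log") centers <- 10^centers
  out <- do.call(rbind, lapply(seq_len(nBins), function(b) {
    tb <- t[bin == b]
    if (!length(tb))
      return(data.frame(center = centers[b], mean_flux = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, n_pairs = 0L))
    mu <- mean(tb)
    se <- if (length(tb) > 1L) stats::sd(tb) / sqrt(length(tb)) else 0
    data.frame(center = centers[b], mean_flux = mu,
               ci_low = mu - 2.576 * se, ci_high = mu + 2.576 * se,
               n_pairs = length(tb))
  }))
  rownames(out) <- NULL
  out
}
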