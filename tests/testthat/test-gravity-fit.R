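test_that("great-circle distances match closed forms and apply the floor", {
  locs <- data.frame(token = c("o", "e", "anti", "twin"),
                     latitude = c(0, 0, 0, 0),
                     longitude = c(0, 1, 180, 0))
  dm <- geographicDistance(locs, floorKm = 1)
  v <- distanceValues(dm)
  expect_equal(v["o", "e"], 111.19, tolerance = 0.01 / 111.19)
  expect_equal(v["o", "anti"], pi * 6371.0088, tolerance = 0.1 / 20015)
  # coincident locations imputed to the 1 km floor
  expect_equal(v["o", "twin"], 1.0)
  expect_equal(diag(v), rep(0, 4), ignore_attr = TRUE)

  dm2 <- geographicDistance(locs, floorKm = 0.01)
  expect_equal(distanceValues(dm2)["o", "twin"], 0.01)

  expect_error(geographicDistance(data.frame(token = "a",
                                             latitude = NA_real_,
                                             longitude = 1)), "a")
})

test_that("embedding distances satisfy the cosine anchor points", {
  tk <- c("x", "y", "opp", "orth")
  V <- rbind(c(1, 0), c(2, 0), c(-1, 0), c(0, 3))
  rownames(V) <- tk
  vocab <- new("Vocabulary", tokens = tk, counts = rep(1, 4),
               frequency = rep(.25, 4), noise = rep(.25, 4), gamma = 1,
               minCount = 0L)
  m <- new("EmbeddingModel", vocabulary = vocab, inVectors = V,
           outVectors = V * 0, hyper = Hyperparams(dim = 2, minCount = 0,
                                                   seed = 0), nPairs = 1)
  d <- distanceValues(embeddingDistance(m, "cosine"))
  expect_equal(d["x", "y"], 0)        # parallel
  expect_equal(d["x", "orth"], 1)     # orthogonal
  expect_equal(d["x", "opp"], 2)      # opposite

  # dot dissimilarity reverses the inner-product order
  dd <- distanceValues(embeddingDistance(m, "dot"))
  S <- tcrossprod(V)
  ut <- upper.tri(S)
  expect_equal(order(dd[ut]), order(-S[ut]))

  de <- distanceValues(embeddingDistance(m, "euclidean"))
  expect_equal(de["x", "y"], 1)

  mzero <- m
  mzero@inVectors[1, ] <- 0
  expect_error(embeddingDistance(mzero, "cosine"), "x")
})

mkDist <- function(tk, values, metric = "euclidean") {
  dimnames(values) <- list(tk, tk)
  new("DistanceMatrix", tokens = tk, values = values, metric = metric,
      floor = 0)
}

exactGravityFixture <- function(n = 30, beta = 2, C = 1, seed = 71) {
  withr::with_seed(seed, {
    tk <- paste0("L", seq_len(n))
    masses <- structure(rlnorm(n, 0, 1), names = tk)
    D <- as.matrix(dist(cbind(runif(n), runif(n))))
    dimnames(D) <- list(tk, tk)
    Tm <- C * outer(masses, masses) * exp(-beta * D)
    diag(Tm) <- 0
    list(tk = tk, masses = masses, D = D, Tm = Tm)
  })
}

test_that("an exact exponential gravity law is recovered to machine precision", {
  fx <- exactGravityFixture(beta = 2, C = 1)
  flux <- new("ExpectedFlux", tokens = fx$tk, values = fx$Tm)
  fit <- fitGravity(flux, fx$masses, mkDist(fx$tk, fx$D), "exponential")
  expect_equal(fit@decay@exponent, 2, tolerance = 1e-9)
  expect_equal(fit@decay@constant, 1, tolerance = 1e-9)
  expect_equal(fit@rSquared, 1, tolerance = 1e-9)
  expect_lt(fit@rmseLog, 1e-9)

  # power family round trip on its own exact data
  Tp <- outer(fx$masses, fx$masses) * pmax(fx$D, 1e-9)^(-1.5)
  diag(Tp) <- 0
  fitp <- fitGravity(new("ExpectedFlux", tokens = fx$tk, values = Tp),
                     fx$masses, mkDist(fx$tk, fx$D), "power")
  expect_equal(fitp@decay@exponent, 1.5, tolerance = 1e-9)
  expect_equal(fitp@rSquared, 1, tolerance = 1e-9)
})

test_that("noisy gravity data recover the exponent within sampling error", {
  fx <- exactGravityFixture(n = 40, beta = 2, C = 1, seed = 72)
  withr::with_seed(73, {
    noisy <- fx$Tm * exp(matrix(rnorm(length(fx$Tm), 0, 0.3), nrow(fx$Tm)))
    noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
    diag(noisy) <- 0
  })
  fit <- fitGravity(new("ExpectedFlux", tokens = fx$tk, values = noisy),
                    fx$masses, mkDist(fx$tk, fx$D), "exponential")
  # OLS sampling theory: slope SE ~ sigma / (sd(d) sqrt(n))
  n <- fit@nPairs
  se <- 0.3 / (stats::sd(fx$D[upper.tri(fx$D)]) * sqrt(n))
  expect_lt(abs(fit@decay@exponent - 2), 2 * se * 3) # generous 2-SE band
})

test_that("zero flows are excluded and mass rescaling is absorbed into C", {
  fx <- exactGravityFixture(n = 20, beta = 2, seed = 74)
  Tm <- fx$Tm
  Tm[1, 2] <- Tm[2, 1] <- 0
  flux <- new("ExpectedFlux", tokens = fx$tk, values = Tm)
  fit <- fitGravity(flux, fx$masses, mkDist(fx$tk, fx$D), "exponential")
  expect_equal(fit@nPairs, choose(20, 2) - 1L)

  # global mass rescaling: exponent invariant, C absorbs the scale
  fit2 <- fitGravity(flux, fx$masses * 10, mkDist(fx$tk, fx$D), "exponential")
  expect_equal(fit2@decay@exponent, fit@decay@exponent, tolerance = 1e-9)
  expect_equal(fit2@decay@constant, fit@decay@constant / 100,
               tolerance = 1e-6)

  expect_error(fitGravity(flux, fx$masses[-1], mkDist(fx$tk, fx$D),
                          "exponential"), "missing")
})

test_that("predicted flux is consistent, bilinear in mass and monotone in distance", {
  fx <- exactGravityFixture(beta = 2, C = 1)
  flux <- new("ExpectedFlux", tokens = fx$tk, values = fx$Tm)
  dm <- mkDist(fx$tk, fx$D)
  fit <- fitGravity(flux, fx$masses, dm, "exponential")
  pred <- predictFlux(fit, fx$masses, dm)
  expect_equal(fluxValues(pred), fx$Tm, tolerance = 1e-6)

  m2 <- fx$masses
  m2[3] <- m2[3] * 2
  pred2 <- predictFlux(fit, m2, dm)
  expect_equal(fluxValues(pred2)[3, -3], 2 * fluxValues(pred)[3, -3])
  expect_equal(fluxValues(pred2)[-3, -3], fluxValues(pred)[-3, -3])

  # monotone decreasing in distance for fixed masses
  tk <- c("a", "b", "c")
  D3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  p3 <- predictFlux(fit, structure(rep(1, 3), names = tk), mkDist(tk, D3))
  v <- fluxValues(p3)
  expect_true(v["a", "b"] > v["a", "c"] && v["a", "c"] > v["b", "c"])
})

test_that("fit evaluation matches closed-form scores", {
  fx <- exactGravityFixture(n = 15, beta = 2, seed = 75)
  Tm <- round(fx$Tm * 50) + 1
  diag(Tm) <- 0
  actual <- new("FluxMatrix", tokens = fx$tk, counts = Tm,
                selfCounts = structure(rep(0, 15), names = fx$tk))
  same <- new("ExpectedFlux", tokens = fx$tk, values = Tm)
  ev <- evaluateFit(actual, same)
  expect_equal(ev$r_squared_loglog, 1)
  expect_equal(ev$rmse_log10, 0)
  expect_equal(ev$cpc, 1)

  doubled <- new("ExpectedFlux", tokens = fx$tk, values = 2 * Tm)
  expect_equal(evaluateFit(actual, doubled)$cpc, 2 / 3)

  # disjoint supports: no common commuters, log-scores undefined
  tk3 <- letters[1:3]
  Ta <- matrix(c(0, 5, 5, 5, 0, 5, 5, 5, 0), 3, dimnames = list(tk3, tk3))
  actual3 <- new("FluxMatrix", tokens = tk3, counts = Ta,
                 selfCounts = structure(rep(0, 3), names = tk3))
  pred3 <- new("ExpectedFlux", tokens = tk3,
               values = matrix(0, 3, 3, dimnames = list(tk3, tk3)))
  ev0 <- evaluateFit(actual3, pred3)
  expect_equal(ev0$cpc, 0)
  expect_true(is.na(ev0$r_squared_loglog))
})

test_that("binned flux summarizes bins correctly and tracks the decay", {
  fx <- exactGravityFixture(n = 40, beta = 4, seed = 76)
  flux <- new("FluxMatrix", tokens = fx$tk,
              counts = round(fx$Tm * 20) + (fx$Tm > 0),
              selfCounts = structure(rep(0, 40), names = fx$tk))
  dm <- mkDist(fx$tk, fx$D)
  bt <- binnedFlux(dm, flux, nBins = 6, scale = "linear")
  expect_equal(nrow(bt), 6L)
  expect_equal(sum(bt$n_pairs), choose(40, 2))
  # global mean recovered when everything lands in one bin's worth of data
  one <- binnedFlux(dm, flux, nBins = 2, scale = "linear")
  Tv <- fluxCounts(flux)[upper.tri(fluxCounts(flux))]
  got <- sum(one$mean_flux * one$n_pairs, na.rm = TRUE) / sum(one$n_pairs)
  expect_equal(got, mean(Tv[Tv > 0]))
  # strong exponential decay: bin means decrease
  mf <- bt$mean_flux[!is.na(bt$mean_flux)]
  expect_true(all(diff(mf) < 0))
  # constant flux: zero-width confidence intervals
  cf <- flux
  cf@counts[cf@counts > 0] <- 7
  bt2 <- binnedFlux(dm, cf, nBins = 3, scale = "linear")
  expect_true(all(bt2$ci_high - bt2$ci_low < 1e-12, na.rm = TRUE))
})

test_that("embedding-based exponential fit beats a shuffled-distance control", {
  toy <- trainedToy()
  m <- toy$model
  fm <- buildFluxMatrix(toy$corpus)
  masses <- structure(toy$world@masses[tokens(m)], names = tokens(m))
  dm <- embeddingDistance(m, "cosine")
  fit <- fitGravity(fm, masses, dm, "exponential")
  withr::with_seed(77, {
    perm <- sample(length(tokens(m)))
    shuf <- mkDist(tokens(m), dm@values[perm, perm])
  })
  fitShuf <- suppressWarnings(fitGravity(fm, masses, shuf, "exponential"))
  expect_gt(fit@rSquared, fitShuf@rSquared)
})
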