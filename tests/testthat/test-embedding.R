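test_that("vocabulary filtering and noise distribution follow the contract", {
  corp <- TrajectoryCorpus(c(rep(list(c("A", "B")), 30),
                             rep(list(c("A", "C")), 10)))
  # counts: A 40, B 30, C 10
  v <- buildVocabulary(corp, minCount = 30, gamma = 1)
  expect_setequal(tokens(v), c("A", "B"))
  expect_error(buildVocabulary(corp, minCount = 100, gamma = 1), "empty")

  # gamma = 0: uniform noise over retained tokens
  v0 <- buildVocabulary(corp, minCount = 1, gamma = 0)
  expect_true(all(abs(v0@noise - 1 / 3) < 1e-12))

  # gamma = 1 with counts 30/10 -> noise (0.75, 0.25)
  corp2 <- TrajectoryCorpus(c(rep(list(c("A", "A", "A")), 10),
                              rep(list(c("B")), 10)))
  v1 <- buildVocabulary(corp2, minCount = 1, gamma = 1)
  expect_equal(unname(v1@noise[match(c("A", "B"), tokens(v1))]),
               c(0.75, 0.25))
})

test_that("training is bit-reproducible from the seed and rejects pairless corpora", {
  corp <- pairCorpus(100)
  h <- Hyperparams(dim = 8, minCount = 1, epochs = 2, seed = 11)
  m1 <- trainSGNS(corp, h)
  m2 <- trainSGNS(corp, h)
  expect_identical(inVectors(m1), inVectors(m2))
  expect_identical(outVectors(m1), outVectors(m2))
  m3 <- trainSGNS(corp, Hyperparams(dim = 8, minCount = 1, epochs = 2,
                                    seed = 12))
  expect_false(identical(inVectors(m1), inVectors(m3)))

  singles <- TrajectoryCorpus(rep(list("A"), 60))
  expect_error(trainSGNS(singles, Hyperparams(minCount = 1)),
               "no window pairs")
})

test_that("trained models separate co-occurring from non-co-occurring tokens", {
  # disjoint always-co-occurring pairs: the conditional the model optimizes
  # must put its mass on the true context
  corp <- pairCorpus(500)
  winsCond <- 0L
  for (s in 1:20) {
    m <- trainSGNS(corp, Hyperparams(dim = 8, minCount = 1, epochs = 5,
                                     seed = s))
    ic <- impliedConditional(m)$values
    if (ic["A", "B"] > ic["A", "C"]) winsCond <- winsCond + 1L
  }
  expect_gte(winsCond, 19L)

  # in-vector cosine separation needs shared contexts (second-order
  # structure): two 3-token communities of co-occurring pairs
  comm <- TrajectoryCorpus(c(
    rep(list(c("A", "B")), 250), rep(list(c("B", "E")), 250),
    rep(list(c("A", "E")), 250),
    rep(list(c("C", "D")), 250), rep(list(c("D", "F")), 250),
    rep(list(c("C", "F")), 250)))
  winsCos <- 0L
  for (s in 1:20) {
    m <- trainSGNS(comm, Hyperparams(dim = 8, minCount = 1, epochs = 5,
                                     seed = s))
    V <- inVectors(m)
    cosine <- function(a, b) sum(V[a, ] * V[b, ]) /
      sqrt(sum(V[a, ]^2) * sum(V[b, ]^2))
    if (cosine("A", "B") > cosine("A", "C")) winsCos <- winsCos + 1L
  }
  expect_gte(winsCos, 19L)
})

test_that("analytic SGNS gradient matches numerical differentiation", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      n <- 6L
      d <- 4L
      u <- matrix(rnorm(n * d, sd = 0.5), n, d)
      v <- rnorm(d, sd = 0.5)
      j <- sample(n, 1)
      negs <- sample(n, 3, replace = TRUE)
      g <- mobvec:::sgnsPairGradient(v, u, j, negs)
      eps <- 1e-6
      numV <- vapply(seq_len(d), function(q) {
        vp <- v; vp[q] <- vp[q] + eps
        vm <- v; vm[q] <- vm[q] - eps
        (mobvec:::sgnsPairObjective(vp, u, j, negs) -
         mobvec:::sgnsPairObjective(vm, u, j, negs)) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(numV - g$v)), 1e-5)
      for (t in unique(c(j, negs))) {
        numU <- vapply(seq_len(d), function(q) {
          up <- u; up[t, q] <- up[t, q] + eps
          um <- u; um[t, q] <- um[t, q] - eps
          (mobvec:::sgnsPairObjective(v, up, j, negs) -
           mobvec:::sgnsPairObjective(v, um, j, negs)) / (2 * eps)
        }, numeric(1))
        expect_lt(max(abs(numU - g$u[t, ])), 1e-5)
      }
    }
  })
})

test_that("implied conditional is the noise-weighted softmax with stochastic rows", {
  toy <- trainedToy()$model
  ic <- impliedConditional(toy)
  expect_true(all(abs(rowSums(ic$values) - 1) < 1e-9))
  expect_true(all(ic$values >= 0))

  # zero out-vectors: rows equal the noise distribution exactly
  zero <- toy
  zero@outVectors[] <- 0
  icz <- impliedConditional(zero)
  for (i in c(1, 5)) {
    expect_equal(unname(icz$values[i, ]), unname(zero@vocabulary@noise),
                 tolerance = 1e-12)
  }

  # gamma = 0 noise (uniform) with zero out-vectors: uniform rows
  unif <- zero
  unif@vocabulary@noise <- rep(1 / length(tokens(zero)), length(tokens(zero)))
  unif@vocabulary@gamma <- 0
  icu <- impliedConditional(unif)
  expect_true(all(abs(icu$values - 1 / length(tokens(zero))) < 1e-12))
})

test_that("a converged toy model reproduces the empirical conditional", {
  # 5-token world, trained well past the default schedule
  w <- sampleWorld(5, 0.5, DecaySpec("exponential", 2), seed = 201)
  corp <- sampleTrajectories(expectedFlux(w), 4000, seed = 202)
  m <- trainSGNS(corp, Hyperparams(dim = 16, minCount = 1, epochs = 40,
                                   seed = 203))
  fm <- buildFluxMatrix(corp)
  emp <- fluxCounts(fm)[tokens(m), tokens(m)]
  emp <- emp / rowSums(emp)
  ic <- impliedConditional(m)$values
  for (i in seq_len(5)) {
    off <- setdiff(seq_len(5), i)
    expect_gt(stats::cor(ic[i, off], emp[i, off]), 0.9)
  }
})

test_that("implied flux has the gravity form and matches the generator", {
  toy <- trainedToy()
  fx <- impliedFlux(toy$model)
  v <- fluxValues(fx)
  expect_identical(v, t(v))
  expect_true(all(diag(v) == 0))
  expect_equal(sum(v) / 2, toy$model@nPairs)

  # all-zero vectors: flux proportional to P(i) P(j)
  zero <- toy$model
  zero@inVectors[] <- 0
  p <- zero@vocabulary@frequency
  vz <- fluxValues(impliedFlux(zero))
  expct <- outer(p, p)
  diag(expct) <- 0
  expct <- expct * (zero@nPairs / (sum(expct) / 2))
  expect_equal(unname(vz), unname(expct), tolerance = 1e-9)

  # trained flux correlates with the generating flux in log space
  gen <- fluxValues(expectedFlux(toy$world))[tokens(toy$model),
                                             tokens(toy$model)]
  ut <- upper.tri(gen) & gen > 0
  expect_gt(stats::cor(log(fluxValues(fx)[ut]), log(gen[ut])), 0.8)
})

test_that("the SGNS equivalence holds: log(T/(P_i P_j)) is affine in v_i . v_j", {
  # gravity corpus at the scale where the equivalence is expected to bite;
  # the left-hand side uses the generating flux the trajectories realize,
  # so Poisson count noise does not blur the relation being tested
  w <- sampleWorld(200, 1, DecaySpec("exponential", 5), seed = 301)
  fl <- expectedFlux(w)
  cp <- sampleTrajectories(fl, 120000, seed = 302)
  m <- trainSGNS(cp, Hyperparams(dim = 64, minCount = 1, epochs = 5,
                                 seed = 303))
  fm <- buildFluxMatrix(cp)
  Tm <- fluxCounts(fm)[tokens(m), tokens(m)]
  G <- fluxValues(fl)[tokens(m), tokens(m)]
  p <- vocabulary(m)@frequency
  ut <- upper.tri(Tm) & Tm > 0
  lhs <- log(G[ut] / outer(p, p)[ut])
  # in-vector dots carry the gravity geometry (Eq. form T ~ P P exp(v.v))
  expect_gt(stats::cor(lhs, tcrossprod(inVectors(m))[ut]), 0.8)
  # the conditional the trainer optimizes uses in-out dots; those track the
  # realized counts even more tightly
  dio <- (inVectors(m) %*% t(outVectors(m)) +
          outVectors(m) %*% t(inVectors(m))) / 2
  expect_gt(stats::cor(log(Tm[ut] / outer(p, p)[ut]), dio[ut]), 0.8)
})

test_that("in/out vector diagnostic behaves at its fixed points", {
  toy <- trainedToy()$model
  same <- toy
  same@outVectors <- same@inVectors
  expect_true(all(abs(diagnoseInOut(same)$cosines - 1) < 1e-12))

  withr::with_seed(88, {
    n <- length(tokens(toy))
    rnd <- toy
    rnd@inVectors <- matrix(rnorm(n * 24), n, 24,
                            dimnames = dimnames(toy@inVectors))
    rnd@outVectors <- matrix(rnorm(n * 24), n, 24,
                             dimnames = dimnames(toy@outVectors))
    expect_lt(abs(diagnoseInOut(rnd)$mean), 0.25)
  })
  expect_true(is.finite(diagnoseInOut(toy)$mean))
})

test_that("SVD embedding preserves the flux geometry at full rank and rejects excess dimension", {
  tk <- c("A", "B", "C", "D")
  withr::with_seed(91, {
    A <- matrix(rpois(16, 5), 4)
    A <- A + t(A)
    diag(A) <- 0
    dimnames(A) <- list(tk, tk)
  })
  fm <- new("FluxMatrix", tokens = tk, counts = A,
            selfCounts = structure(rep(0, 4), names = tk))
  # scaled left singular vectors: tcrossprod(U S) = A A^T exactly at full rank
  m <- svdEmbed(fm, 4)
  expect_lt(max(abs(tcrossprod(inVectors(m)) - A %*% t(A))) /
            max(A %*% t(A)), 1e-8)
  expect_error(svdEmbed(fm, 10), "rank")
})

test_that("Laplacian eigenmap separates disconnected cliques", {
  tk <- paste0("T", 1:10)
  A <- matrix(0, 10, 10, dimnames = list(tk, tk))
  A[1:5, 1:5] <- 1
  A[6:10, 6:10] <- 1
  diag(A) <- 0
  # weak bridge keeps the graph connected
  A[5, 6] <- A[6, 5] <- 0.01
  fm <- new("FluxMatrix", tokens = tk, counts = A,
            selfCounts = structure(rep(0, 10), names = tk))
  # the Fiedler coordinate alone separates the cliques
  m <- laplacianEmbed(fm, 1)
  V <- inVectors(m)
  within <- as.matrix(dist(V))[1:5, 1:5]
  cross <- as.matrix(dist(V))[1:5, 6:10]
  expect_lt(max(within), min(cross))
  expect_error(laplacianEmbed(fm, 10), "<=")
})

test_that("personalized PageRank rows are stochastic and restart-dominated at low damping", {
  toy <- trainedToy()
  fm <- buildFluxMatrix(toy$corpus)
  P <- pprVectors(fm, damping = 0.85)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  Plow <- pprVectors(fm, damping = 0.01)
  expect_true(all(diag(Plow) > 0.98))
  expect_error(pprVectors(fm, damping = 1.2), "damping")
})

test_that("paper-convention defaults are wired into Hyperparams", {
  h <- Hyperparams()
  expect_equal(h@dim, 300L)
  expect_equal(h@window, 1L)
  expect_equal(h@negatives, 5L)
  expect_equal(h@gamma, 1.0)
  expect_equal(h@minCount, 50L)
  expect_equal(h@alpha0, 0.025)
  expect_equal(h@epochs, 5L)
})
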