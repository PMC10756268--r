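#' Sample a synthetic gravity-model world
#'
#' Draws a latent geometry on which the gravity law holds exactly:
#' locations uniform on the unit square and log-normal masses (log-mean 0,
#' log-sd `massSigma`), heavy-tailed like real location populations.  The
#' decay specification is attached as the world's generating truth.
#'
#' @param n number of locations (>= 2).
#' @param massSigma log-standard-deviation of the masses (0 gives all-equal
#'   masses of 1).
#' @param decay a [DecaySpec-class].
#' @param seed integer seed; worlds are fully reproducible.
#' @return A [LatentWorld-class].
#' @examples
#' sampleWorld(10, massSigma = 1, DecaySpec("exponential", 5), seed = 7)
#' @export
sampleWorld <- function(n, massSigma = 1.0,
                        decay = DecaySpec("exponential", 5), seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stopValidation("a world needs at least 2 locations")
  if (massSigma < 0) stopValidation("massSigma must be >= 0")
  tk <- sprintf("L%0*d", nchar(n), seq_len(n))
  withr::with_seed(as.integer(seed), {
    coords <- cbind(stats::runif(n), stats::runif(n))
    masses <- if (massSigma == 0) rep(1, n)
              else stats::rlnorm(n, meanlog = 0, sdlog = massSigma)
  })
  rownames(coords) <- tk
  names(masses) <- tk
  new("LatentWorld", tokens = tk, coordinates = coords, masses = masses,
      decay = decay, seed = as.integer(seed))
}

#' Expected flux of a gravity world
#'
#' Evaluates the gravity law T_ij = C m_i m_j f(r_ij) on the latent
#' Euclidean distances, with f(r) = r^-alpha (power; r floored at 1e-9 to
#' keep coincident points finite) or f(r) = exp(-beta r) (exponential).
#' The diagonal is zero.
#'
#' @param world a [LatentWorld-class].
#' @return An [ExpectedFlux-class].
#' @examples
#' w <- sampleWorld(5, 1, DecaySpec("exponential", 5), seed = 1)
#' expectedFlux(w)
#' @export
expectedFlux <- function(world) {
  r <- as.matrix(stats::dist(world@coordinates))
  f <- if (world@decay@family == "power")
    pmax(r, 1e-9)^(-world@decay@exponent)
  else
    exp(-world@decay@exponent * r)
  vals <- world@decay@constant * outer(world@masses, world@masses) * f
  diag(vals) <- 0
  dimnames(vals) <- list(world@tokens, world@tokens)
  new("ExpectedFlux", tokens = world@tokens, values = vals)
}

#' Sample trajectories from an expected flux
#'
#' Realizes the flux as a trajectory corpus.  The default `"pairs"` scheme
#' draws each trajectory as a length-2 token pair with probability
#' proportional to the flux — exactly the first-order co-occurrence
#' structure that window-1 training sees.  The `"walk"` scheme runs a
#' Markov chain with transition probability P(j | i) proportional to the
#' flux row, giving longer, more realistic trajectories.
#'
#' @param flux an [ExpectedFlux-class] with at least one positive
#'   off-diagonal entry.
#' @param nTraj number of trajectories to draw.
#' @param scheme `"pairs"` (default) or `"walk"`.
#' @param walkLength trajectory length for the walk scheme (default 10).
#' @param seed integer seed.
#' @return A year-less [TrajectoryCorpus-class].
#' @export
sampleTrajectories <- function(flux, nTraj, scheme = c("pairs", "walk"),
                               walkLength = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  nTraj <- as.integer(nTraj)
  tk <- flux@tokens
  n <- length(tk)
  vals <- flux@values
  if (all(vals <= 0)) stopValidation("flux has no positive off-diagonal entry")
  if (scheme == "pairs") {
    ut <- which(upper.tri(vals) & vals > 0)
    p <- vals[ut]
    cdf <- cumsum(p / sum(p))
    withr::with_seed(as.integer(seed), {
      draw <- findInterval(stats::runif(nTraj), cdf) + 1L
      flip <- stats::runif(nTraj) < 0.5
    })
    i <- (ut[draw] - 1L) %/% n + 1L   # column of upper.tri index
    j <- (ut[draw] - 1L) %% n + 1L    # row
    a <- ifelse(flip, i, j)
    b <- ifelse(flip, j, i)
    toks <- mapply(function(x, y) c(tk[x], tk[y]), a, b, SIMPLIFY = FALSE)
    return(TrajectoryCorpus(toks))
  }
  walkLength <- as.integer(walkLength)
  if (walkLength < 2L) stopValidation("walkLength must be >= 2")
  rs <- rowSums(vals)
  if (any(rs <= 0)) stopValidation("walk scheme needs every row positive")
  cdfs <- t(apply(vals / rs, 1L, cumsum))
  start <- rs / sum(rs)
  startCdf <- cumsum(start)
  toks <- vector("list", nTraj)
  withr::with_seed(as.integer(seed), {
    for (t in seq_len(nTraj)) {
      path <- integer(walkLength)
      path[1] <- findInterval(stats::runif(1), startCdf) + 1L
      for (s in 2:walkLength)
        path[s] <- findInterval(stats::runif(1), cdfs[path[s - 1L], ]) + 1L
      toks[[t]] <- tk[path]
    }
  })
  TrajectoryCorpus(toks)
}

#' Correlation between embedding and latent distances
#'
#' Pearson correlation, over all unordered token pairs present in the
#' model's vocabulary, between pairwise embedding dissimilarities (cosine,
#' dot-transform or Euclidean — see [embeddingDistance()]) and the latent
#' Euclidean distances of the generating world.  This is the synthetic
#' benchmark score: a high value means the embedding recovered the latent
#' gravity geometry.
#'
#' @param model an [EmbeddingModel-class] whose vocabulary is a subset of
#'   the world's tokens.
#' @param world the generating [LatentWorld-class].
#' @param metric `"cosine"`, `"dot"` or `"euclidean"`.
#' @return A list with `correlation` and `nPairs`.
#' @export
benchmarkCorrelation <- function(model, world,
                                 metric = c("cosine", "dot", "euclidean")) {
  metric <- match.arg(metric)
  tk <- intersect(tokens(model), world@tokens)
  if (length(tk) < 3L)
    stopValidation("need at least 3 tokens shared between model and world")
  emb <- embeddingDistance(model, metric)
  de <- emb@values[tk, tk]
  dl <- as.matrix(stats::dist(world@coordinates[tk, , drop = FALSE]))
  ut <- upper.tri(de)
  list(correlation = stats::cor(de[ut], dl[ut]), nPairs = sum(ut))
}

#' Persist a latent world as JSON
#'
#' @param world a [LatentWorld-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWorld <- function(world, path) {
  jsonlite::write_json(list(
    tokens = world@tokens,
    coordinates = unname(world@coordinates),
    masses = unname(world@masses),
    decay = list(family = world@decay@family,
                 exponent = world@decay@exponent,
                 constant = world@decay@constant),
    seed = world@seed), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeWorld
#' @export
readWorld <- function(path) {
  if (!file.exists(path)) stopValidation("no such file: ", path)
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  coords <- as.matrix(o$coordinates)
  if (!all(dim(coords) == c(length(o$tokens), 2L)))
    stopValidation("malformed coordinates in ", path)
  rownames(coords) <- o$tokens
  masses <- as.numeric(o$masses)
  names(masses) <- o$tokens
  new("LatentWorld", tokens = o$tokens, coordinates = coords, masses = masses,
      decay = DecaySpec(o$decay$family, o$decay$exponent, o$decay$constant),
      seed = as.integer(o$seed))
}
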