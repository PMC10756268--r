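#' @import methods
NULL

# validation errors carry a dedicated condition class so that callers (and the
# command-line driver) can distinguish bad input from runtime failure
stopValidation <- function(...) {
  msg <- paste0(...)
  stop(errorCondition(msg, class = c("mobvec_validation_error", "error")))
}

#' DecaySpec: distance-decay family of a gravity model
#'
#' Describes the deterrence function \eqn{f(r)} of a gravity model
#' \eqn{\hat T_{ij} = C m_i m_j f(r_{ij})}: either a power law
#' \eqn{f(r) = r^{-\alpha}} or an exponential \eqn{f(r) = e^{-\beta r}},
#' together with the multiplicative constant \eqn{C}.
#'
#' @slot family `"power"` or `"exponential"`.
#' @slot exponent positive decay exponent (\eqn{\alpha} for power,
#'   \eqn{\beta} for exponential).
#' @slot constant positive multiplicative constant \eqn{C}.
#' @export
setClass("DecaySpec",
  slots = c(family = "character", exponent = "numeric", constant = "numeric"),
  validity = function(object) {
    if (!object@family %in% c("power", "exponential"))
      return("family must be 'power' or 'exponential'")
    if (length(object@exponent) != 1L || !is.finite(object@exponent) ||
        object@exponent <= 0)
      return("exponent must be a single positive number")
    if (length(object@constant) != 1L || !is.finite(object@constant) ||
        object@constant <= 0)
      return("constant must be a single positive number")
    TRUE
  })

#' Construct a DecaySpec
#'
#' @param family `"power"` or `"exponential"`.
#' @param exponent positive decay exponent.
#' @param constant positive constant \eqn{C} (default 1).
#' @return A [DecaySpec-class] object.
#' @examples
#' DecaySpec("exponential", exponent = 5)
#' @export
DecaySpec <- function(family = c("power", "exponential"), exponent,
                      constant = 1) {
  family <- match.arg(family)
  new("DecaySpec", family = family, exponent = as.numeric(exponent),
      constant = as.numeric(constant))
}

#' TrajectoryCorpus: ordered location trajectories
#'
#' One trajectory per individual: an ordered sequence of location tokens,
#' optionally annotated with a (non-decreasing) year per stay.  Consecutive
#' repeats are kept; they contribute self pairs that are tracked separately
#' from between-location flux.
#'
#' @slot personId character vector, one id per trajectory.
#' @slot tokens list of character vectors (the stays, in order).
#' @slot years list of integer vectors parallel to `tokens`; `NA` where the
#'   year is unknown.
#' @slot tokenCounts named integer vector of token occurrence counts.
#' @export
setClass("TrajectoryCorpus",
  slots = c(personId = "character", tokens = "list", years = "list",
            tokenCounts = "integer"),
  validity = function(object) {
    n <- length(object@personId)
    if (length(object@tokens) != n || length(object@years) != n)
      return("personId, tokens and years must have equal length")
    lens <- lengths(object@tokens)
    if (any(lens < 1L)) return("every trajectory must have at least one stay")
    if (any(lengths(object@years) != lens))
      return("years must be parallel to tokens")
    for (i in seq_len(n)) {
      y <- object@years[[i]]
      y <- y[!is.na(y)]
      if (length(y) > 1L && any(diff(y) < 0))
        return(sprintf("years decrease within trajectory '%s'",
                       object@personId[i]))
    }
    cnt <- recountTokens(object@tokens)
    tc <- object@tokenCounts
    if (length(cnt) != length(tc) ||
        !identical(sort(names(cnt)), sort(names(tc))) ||
        any(cnt[names(tc)] != tc))
      return("tokenCounts does not match a recount over the trajectories")
    TRUE
  })

recountTokens <- function(tokens) {
  all <- unlist(tokens, use.names = FALSE)
  tab <- table(all)
  structure(as.integer(tab), names = names(tab))
}

#' Construct a TrajectoryCorpus
#'
#' @param tokens list of character vectors, one per trajectory.
#' @param years optional list of integer vectors parallel to `tokens`
#'   (`NULL` for year-less corpora).
#' @param personId optional character ids (defaults to `"t1"`, `"t2"`, ...).
#' @return A [TrajectoryCorpus-class] object.
#' @examples
#' corpus <- TrajectoryCorpus(list(c("A", "B", "C"), c("B", "A")))
#' tokenCounts(corpus)
#' @export
TrajectoryCorpus <- function(tokens, years = NULL, personId = NULL) {
  if (!is.list(tokens)) stopValidation("tokens must be a list")
  tokens <- lapply(tokens, as.character)
  if (is.null(years))
    years <- lapply(lengths(tokens), function(l) rep(NA_integer_, l))
  else
    years <- lapply(years, as.integer)
  if (is.null(personId)) personId <- paste0("t", seq_along(tokens))
  new("TrajectoryCorpus", personId = as.character(personId), tokens = tokens,
      years = years, tokenCounts = recountTokens(tokens))
}

#' FluxMatrix: symmetric co-occurrence counts between locations
#'
#' Entry \eqn{T_{ij}} counts unordered co-occurrences of locations \eqn{i}
#' and \eqn{j} within the context window across all trajectories.  Self
#' pairs (a location co-occurring with itself, from consecutive repeats)
#' are stored separately so the off-diagonal matrix stays a pure
#' between-location flux.
#'
#' @slot tokens ordered vocabulary.
#' @slot counts symmetric non-negative matrix with zero diagonal.
#' @slot selfCounts named numeric vector of within-token pair counts.
#' @export
setClass("FluxMatrix",
  slots = c(tokens = "character", counts = "matrix", selfCounts = "numeric"),
  validity = function(object) {
    n <- length(object@tokens)
    if (!all(dim(object@counts) == c(n, n)))
      return("counts dimensions do not match tokens")
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (any(abs(object@counts - t(object@counts)) > 1e-9))
      return("counts must be symmetric")
    if (any(diag(object@counts) != 0))
      return("diagonal must be zero (self pairs live in selfCounts)")
    if (length(object@selfCounts) != n)
      return("selfCounts length must match tokens")
    TRUE
  })

#' ExpectedFlux: model-predicted flux between locations
#'
#' The gravity-model prediction \eqn{\hat T_{ij}}, a symmetric non-negative
#' real matrix with zero diagonal.
#'
#' @slot tokens ordered location identifiers.
#' @slot values symmetric non-negative matrix, zero diagonal.
#' @export
setClass("ExpectedFlux",
  slots = c(tokens = "character", values = "matrix"),
  validity = function(object) {
    n <- length(object@tokens)
    if (!all(dim(object@values) == c(n, n)))
      return("values dimensions do not match tokens")
    if (any(object@values < 0)) return("values must be non-negative")
    if (max(abs(object@values - t(object@values))) >
        1e-8 * max(1, max(object@values)))
      return("values must be symmetric")
    TRUE
  })

#' LatentWorld: synthetic gravity-model geometry
#'
#' A set of locations with latent planar coordinates, positive masses, and a
#' distance-decay specification; the generating truth of the synthetic
#' gravity benchmark.
#'
#' @slot tokens location identifiers.
#' @slot coordinates n x 2 matrix of latent positions.
#' @slot masses positive masses \eqn{m_i}.
#' @slot decay a [DecaySpec-class].
#' @slot seed integer seed the world was drawn from.
#' @export
setClass("LatentWorld",
  slots = c(tokens = "character", coordinates = "matrix", masses = "numeric",
            decay = "DecaySpec", seed = "integer"),
  validity = function(object) {
    n <- length(object@tokens)
    if (n < 2L) return("a world needs at least two locations")
    if (!all(dim(object@coordinates) == c(n, 2L)))
      return("coordinates must be an n x 2 matrix")
    if (length(object@masses) != n || any(object@masses <= 0))
      return("masses must be positive, one per token")
    TRUE
  })

#' Vocabulary: token statistics for embedding training
#'
#' Retained tokens with occurrence counts, empirical frequency
#' \eqn{P(i)}, and the noise (negative-sampling) distribution
#' \eqn{P^\gamma(i) \propto \mathrm{count}_i^\gamma}.
#'
#' @slot tokens retained tokens (all with count >= minCount).
#' @slot counts occurrence counts.
#' @slot frequency \eqn{P(i)}, sums to 1.
#' @slot noise normalized \eqn{P^\gamma}, sums to 1.
#' @slot gamma noise exponent \eqn{\gamma}.
#' @slot minCount minimum occurrence threshold \eqn{f_{min}}.
#' @export
setClass("Vocabulary",
  slots = c(tokens = "character", counts = "numeric", frequency = "numeric",
            noise = "numeric", gamma = "numeric", minCount = "integer"),
  validity = function(object) {
    n <- length(object@tokens)
    if (length(object@counts) != n || length(object@frequency) != n ||
        length(object@noise) != n)
      return("counts, frequency and noise must parallel tokens")
    if (n == 0L) return("vocabulary is empty")
    if (abs(sum(object@frequency) - 1) > 1e-9) return("frequency must sum to 1")
    if (abs(sum(object@noise) - 1) > 1e-9) return("noise must sum to 1")
    if (any(object@counts < object@minCount))
      return("all retained counts must be >= minCount")
    TRUE
  })

#' Hyperparams: SGNS training hyperparameters
#'
#' Defaults follow common practice for trajectory embedding: dimension 300,
#' window 1 (first-order flux), 5 negative samples, noise exponent
#' \eqn{\gamma = 1} (the choice that ties SGNS to the gravity model),
#' minimum count 50, initial learning rate 0.025, 5 epochs.
#'
#' @slot dim embedding dimension d.
#' @slot window context window w.
#' @slot negatives negative samples per positive pair k.
#' @slot gamma noise distribution exponent.
#' @slot alpha0 initial learning rate.
#' @slot epochs training iterations over the corpus.
#' @slot minCount minimum token frequency.
#' @slot seed integer seed controlling all training randomness.
#' @export
setClass("Hyperparams",
  slots = c(dim = "integer", window = "integer", negatives = "integer",
            gamma = "numeric", alpha0 = "numeric", epochs = "integer",
            minCount = "integer", seed = "integer"),
  validity = function(object) {
    if (object@dim < 1L) return("dim must be >= 1")
    if (object@window < 1L) return("window must be >= 1")
    if (object@negatives < 1L) return("negatives must be >= 1")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@alpha0 <= 0) return("alpha0 must be positive")
    if (object@gamma < 0) return("gamma must be >= 0")
    TRUE
  })

#' Construct SGNS hyperparameters
#'
#' @param dim embedding dimension (default 300).
#' @param window context window (default 1).
#' @param negatives negative samples per pair (default 5).
#' @param gamma noise exponent (default 1.0; 0.75 recovers the original
#'   word2vec noise distribution).
#' @param alpha0 initial learning rate (default 0.025; decays linearly to
#'   `alpha0 / 1e4`).
#' @param epochs passes over the corpus (default 5).
#' @param minCount minimum token occurrence count (default 50).
#' @param seed integer seed (default 1).
#' @return A [Hyperparams-class] object.
#' @examples
#' Hyperparams(dim = 64, minCount = 1, seed = 42)
#' @export
Hyperparams <- function(dim = 300, window = 1, negatives = 5, gamma = 1.0,
                        alpha0 = 0.025, epochs = 5, minCount = 50, seed = 1) {
  new("Hyperparams", dim = as.integer(dim), window = as.integer(window),
      negatives = as.integer(negatives), gamma = as.numeric(gamma),
      alpha0 = as.numeric(alpha0), epochs = as.integer(epochs),
      minCount = as.integer(minCount), seed = as.integer(seed))
}

#' EmbeddingModel: trained location vectors
#'
#' The two vector families SGNS learns per token: in-vectors \eqn{v_i}
#' (the published embedding) and out-vectors \eqn{u_i}, together with the
#' vocabulary statistics needed to recover the implied conditional and flux.
#'
#' @slot vocabulary a [Vocabulary-class].
#' @slot inVectors |A| x d matrix of in-vectors (rownames are tokens).
#' @slot outVectors |A| x d matrix of out-vectors.
#' @slot hyper the [Hyperparams-class] used for training.
#' @slot nPairs total number of unordered window pairs in one pass over the
#'   training corpus (the scale of the implied flux).
#' @export
setClass("EmbeddingModel",
  slots = c(vocabulary = "Vocabulary", inVectors = "matrix",
            outVectors = "matrix", hyper = "Hyperparams", nPairs = "numeric"),
  validity = function(object) {
    n <- length(object@vocabulary@tokens)
    d <- object@hyper@dim
    if (!all(dim(object@inVectors) == c(n, d)))
      return("inVectors must be |A| x dim")
    if (!all(dim(object@outVectors) == c(n, d)))
      return("outVectors must be |A| x dim")
    if (any(!is.finite(object@inVectors)) || any(!is.finite(object@outVectors)))
      return("vectors must be finite")
    TRUE
  })

#' DistanceMatrix: pairwise location dissimilarities
#'
#' @slot tokens ordered identifiers.
#' @slot values symmetric non-negative matrix with zero diagonal.
#' @slot metric one of `"geographic_km"`, `"cosine"`, `"dot_dissimilarity"`,
#'   `"euclidean"`.
#' @slot floor distance floor applied (km; geographic metric only, else 0).
#' @export
setClass("DistanceMatrix",
  slots = c(tokens = "character", values = "matrix", metric = "character",
            floor = "numeric"),
  validity = function(object) {
    n <- length(object@tokens)
    if (!all(dim(object@values) == c(n, n)))
      return("values dimensions do not match tokens")
    if (max(abs(object@values - t(object@values))) > 1e-9 * max(1, max(object@values)))
      return("values must be symmetric")
    if (!object@metric %in%
        c("geographic_km", "cosine", "dot_dissimilarity", "euclidean"))
      return("unknown metric")
    if (object@metric == "cosine" &&
        (min(object@values) < -1e-12 || max(object@values) > 2 + 1e-12))
      return("cosine distances must lie in [0, 2]")
    TRUE
  })

#' GravityFit: fitted gravity law
#'
#' Result of the log-linear regression
#' \eqn{\ln(T_{ij} / (m_i m_j)) = \ln C - \alpha \ln g_{ij}} (power) or
#' \eqn{\ln C - \beta d_{ij}} (exponential), over unordered pairs with
#' positive flux.
#'
#' @slot decay fitted [DecaySpec-class] (family, exponent, constant C).
#' @slot nPairs number of positive-flux pairs used.
#' @slot rSquared squared Pearson correlation of fitted vs observed log flux.
#' @slot rmseLog root-mean-square residual in natural-log space.
#' @slot residuals summary statistics of the regression residuals.
#' @export
setClass("GravityFit",
  slots = c(decay = "DecaySpec", nPairs = "integer", rSquared = "numeric",
            rmseLog = "numeric", residuals = "numeric"),
  validity = function(object) {
    if (object@nPairs < 3L) return("need at least 3 positive-flux pairs")
    if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
      return("rSquared must lie in [0, 1]")
    TRUE
  })

#' Dendrogram: hierarchical clustering with scaled node levels
#'
#' An agglomerative clustering of elements where every cluster (internal
#' node and leaf singleton) carries a hierarchical level in [0, 1]: the
#' root sits at 0, leaves at 1, and internal nodes at their topological
#' depth divided by the maximum root-to-leaf depth.
#'
#' @slot elements leaf names.
#' @slot clusterMembers list of integer vectors: member elements per cluster
#'   (internal merges first, then leaf singletons).
#' @slot clusterLevels numeric levels in [0, 1] parallel to clusterMembers.
#' @slot hclust the underlying [stats::hclust()] object.
#' @export
setClass("Dendrogram",
  slots = c(elements = "character", clusterMembers = "list",
            clusterLevels = "numeric", hclust = "ANY"),
  validity = function(object) {
    if (length(object@clusterMembers) != length(object@clusterLevels))
      return("clusterMembers and clusterLevels must be parallel")
    if (any(object@clusterLevels < 0 | object@clusterLevels > 1))
      return("levels must lie in [0, 1]")
    root <- which(object@clusterLevels == 0)
    if (!any(lengths(object@clusterMembers[root]) ==
             length(object@elements)))
      return("the root cluster must contain every element at level 0")
    TRUE
  })

#' AffiliationGraph: bipartite element-cluster weights
#'
#' Weighted affiliation of elements to clusters, with the hierarchy weight
#' function \eqn{a_{i\beta} = e^{r l_\beta}} applied to a dendrogram's
#' levels (flat partitions affiliate each element to its single cluster).
#'
#' @slot elements element names.
#' @slot weights elements x clusters non-negative matrix.
#' @slot r the level-scaling parameter.
#' @export
setClass("AffiliationGraph",
  slots = c(elements = "character", weights = "matrix", r = "numeric"),
  validity = function(object) {
    if (nrow(object@weights) != length(object@elements))
      return("weights rows must match elements")
    if (any(object@weights < 0)) return("weights must be non-negative")
    if (any(rowSums(object@weights) <= 0))
      return("every element needs at least one positive affiliation")
    TRUE
  })

#' ElementGraph: cluster-induced element transition graph
#'
#' Row-stochastic matrix W obtained by projecting an affiliation graph onto
#' the elements; the substrate for personalized-PageRank similarity vectors.
#'
#' @slot elements element names.
#' @slot W row-stochastic matrix of induced edge weights.
#' @export
setClass("ElementGraph",
  slots = c(elements = "character", W = "matrix"),
  validity = function(object) {
    n <- length(object@elements)
    if (!all(dim(object@W) == c(n, n))) return("W must be n x n")
    if (any(object@W < 0)) return("W must be non-negative")
    if (any(abs(rowSums(object@W) - 1) > 1e-9))
      return("rows of W must sum to 1")
    TRUE
  })
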