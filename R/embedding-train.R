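#' Build a training vocabulary
#'
#' Drops tokens occurring fewer than `minCount` times (their positions are
#' removed from trajectories before pair emission) and computes the
#' empirical frequency P(i) and the noise distribution
#' P^gamma(i) proportional to count_i^gamma used for negative sampling.
#' Tokens are ordered by decreasing count (ties lexicographic).
#'
#' @param corpus a [TrajectoryCorpus-class].
#' @param minCount minimum occurrence count (default 50).
#' @param gamma noise exponent (default 1; 0 gives a uniform noise
#'   distribution, 0.75 the original word2vec choice).
#' @return A [Vocabulary-class].
#' @examples
#' corpus <- TrajectoryCorpus(list(c("A", "B"), c("A", "C"), c("A", "B")))
#' buildVocabulary(corpus, minCount = 2, gamma = 1)
#' @export
buildVocabulary <- function(corpus, minCount = 50L, gamma = 1.0) {
  cnt <- corpus@tokenCounts
  keep <- cnt >= minCount
  if (!any(keep))
    stopValidation("vocabulary is empty after minCount = ", minCount,
                   " filtering")
  cnt <- cnt[keep]
  ord <- order(-cnt, names(cnt))
  cnt <- cnt[ord]
  noiseRaw <- as.numeric(cnt)^gamma
  new("Vocabulary", tokens = names(cnt), counts = as.numeric(cnt),
      frequency = as.numeric(cnt) / sum(cnt), noise = noiseRaw / sum(noiseRaw),
      gamma = as.numeric(gamma), minCount = as.integer(minCount))
}

## corpus -> integer streams over a vocabulary (OOV positions removed),
## flattened with per-sentence lengths; indices are 0-based for the C++ core
flattenStreams <- function(tokenList, vocabTokens) {
  idx <- lapply(tokenList, function(tk) {
    m <- match(tk, vocabTokens)
    m[!is.na(m)] - 1L
  })
  list(flat = as.integer(unlist(idx, use.names = FALSE)),
       lens = lengths(idx))
}

orderedPairCount <- function(lens, window) {
  sum(vapply(seq_len(window), function(off)
    2 * sum(pmax(lens - off, 0L)), numeric(1)))
}

unorderedPairCount <- function(lens, window) {
  sum(vapply(seq_len(window), function(off)
    sum(pmax(lens - off, 0L)), numeric(1)))
}

#' Train a skip-gram negative-sampling embedding
#'
#' Streams each trajectory once per epoch (with fresh within-year shuffling,
#' seeded from `hyper@seed`), and for every center i and context j within
#' the window performs one stochastic-gradient ascent step on
#' \deqn{\log\sigma(u_j \cdot v_i) + \sum_{k} \log\sigma(-u_{j'} \cdot v_i),}
#' with the k negatives j' drawn i.i.d. from the noise distribution
#' P^gamma.  The learning rate decays linearly from `alpha0` to
#' `alpha0 / 1e4` over all scheduled pairs.  Training is single-worker and
#' bit-reproducible from `hyper@seed`.  In-vectors are initialized uniform
#' in (-0.5/d, 0.5/d), out-vectors at zero.
#'
#' @param corpus a [TrajectoryCorpus-class].
#' @param hyper a [Hyperparams-class] (defaults: d=300, w=1, k=5, gamma=1,
#'   alpha0=0.025, 5 epochs, minCount=50).
#' @return An [EmbeddingModel-class].
#' @examples
#' corpus <- TrajectoryCorpus(rep(list(c("A", "B"), c("C", "D")), 50))
#' model <- trainSGNS(corpus, Hyperparams(dim = 8, minCount = 1, seed = 1))
#' model
#' @export
trainSGNS <- function(corpus, hyper = Hyperparams()) {
  vocab <- buildVocabulary(corpus, hyper@minCount, hyper@gamma)
  n <- length(vocab@tokens)
  d <- hyper@dim
  hasYears <- any(vapply(corpus@years, function(y) any(!is.na(y)), logical(1)))
  base <- flattenStreams(corpus@tokens, vocab@tokens)
  nOrdered <- orderedPairCount(base$lens, hyper@window)
  if (nOrdered == 0)
    stopValidation("no window pairs: every trajectory has length < 2 after filtering")
  totalPairs <- nOrdered * hyper@epochs
  vin <- withr::with_seed(hyper@seed,
    matrix(stats::runif(n * d, -0.5, 0.5) / d, nrow = d, ncol = n))
  vout <- matrix(0, nrow = d, ncol = n)
  noiseCdf <- cumsum(vocab@noise)
  noiseCdf[n] <- 1.0
  processed <- 0
  for (epoch in seq_len(hyper@epochs)) {
    st <- if (hasYears) {
      toks <- epochStreams(corpus, deriveSeed(hyper@seed, epoch))
      flattenStreams(toks, vocab@tokens)
    } else base
    processed <- sgns_epoch_cpp(st$flat, st$lens, vin, vout, noiseCdf,
                                hyper@window, hyper@negatives, hyper@alpha0,
                                processed, totalPairs,
                                deriveSeed(hyper@seed, 1000L + epoch))
  }
  inV <- t(vin)
  outV <- t(vout)
  rownames(inV) <- rownames(outV) <- vocab@tokens
  new("EmbeddingModel", vocabulary = vocab, inVectors = inV,
      outVectors = outV, hyper = hyper,
      nPairs = unorderedPairCount(base$lens, hyper@window))
}

## Reference implementation of the negative-sampling objective for one
## center i with context j and fixed negative draws; used by the gradient
## tests as an independent check on the analytic update the trainer applies.
sgnsPairObjective <- function(v, u, j, negs) {
  val <- log(stats::plogis(sum(u[j, ] * v)))
  for (jp in negs) val <- val + log(stats::plogis(-sum(u[jp, ] * v)))
  val
}

sgnsPairGradient <- function(v, u, j, negs) {
  gv <- (1 - stats::plogis(sum(u[j, ] * v))) * u[j, ]
  gu <- matrix(0, nrow(u), ncol(u))
  gu[j, ] <- (1 - stats::plogis(sum(u[j, ] * v))) * v
  for (jp in negs) {
    s <- stats::plogis(sum(u[jp, ] * v))
    gv <- gv - s * u[jp, ]
    gu[jp, ] <- gu[jp, ] - s * v
  }
  list(v = gv, u = gu)
}
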