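# shared fixtures built in code

# tiny deterministic corpus with years, for shuffling / parsing tests
yearCorpus <- function() {
  TrajectoryCorpus(
    tokens = list(c("A", "B", "C"), c("B", "A")),
    years = list(c(2008L, 2008L, 2009L), c(NA_integer_, NA_integer_)),
    personId = c("p1", "p2"))
}

# always-co-occurring disjoint pairs: {A,B} and {C,D}
pairCorpus <- function(nEach = 500L) {
  TrajectoryCorpus(c(rep(list(c("A", "B")), nEach),
                     rep(list(c("C", "D")), nEach)))
}

# small trained model on a gravity world; cached per session because several
# tests interrogate the same embedding
trainedToy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- sampleWorld(60, 1, DecaySpec("exponential", 5), seed = 101)
      corp <- sampleTrajectories(expectedFlux(w), 30000, seed = 102)
      m <- trainSGNS(corp, Hyperparams(dim = 24, minCount = 1, epochs = 5,
                                       seed = 103))
      cache <<- list(world = w, corpus = corp, model = m)
    }
    cache
  }
})

# enumerate all set partitions of n elements as label vectors (restricted
# growth strings); used by the exhaustive element-centric similarity oracle
allPartitions <- function(elements) {
  n <- length(elements)
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- structure(letters[labels],
                                            names = elements)
      return(invisible())
    }
    for (lab in seq_len(k + 1L)) rec(c(labels, lab), max(k, lab))
  }
  rec(integer(0), 0L)
  out
}

# closed-form personalized-PageRank profile for a flat partition:
# p_i = (1 - damping) e_i + damping * uniform over i's cluster
partitionPprOracle <- function(labels, damping) {
  el <- names(labels)
  n <- length(el)
  P <- matrix(0, n, n, dimnames = list(el, el))
  for (i in seq_len(n)) {
    members <- which(labels == labels[i])
    P[i, members] <- damping / length(members)
    P[i, i] <- P[i, i] + (1 - damping)
  }
  P
}

ecsOracleFlat <- function(a, b, damping) {
  el <- names(a)
  PA <- partitionPprOracle(a, damping)
  PB <- partitionPprOracle(b[el], damping)
  mean(1 - 0.5 * rowSums(abs(PA - PB)))
}
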