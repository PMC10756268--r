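#' Accessor generics
#'
#' Small accessor family used across the package's S4 classes: `tokens()`
#' returns the ordered identifiers of an object, `inVectors()` /
#' `outVectors()` the two SGNS vector families, `fluxCounts()` the symmetric
#' co-occurrence matrix, `selfCounts()` the within-token pair counts,
#' `tokenCounts()` the per-token occurrence counts of a corpus, and
#' `vocabulary()` the vocabulary of a trained model.
#'
#' @param x an object of one of the package's classes.
#' @return The slot contents (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))
#' @rdname accessors
#' @export
setGeneric("tokenCounts", function(x) standardGeneric("tokenCounts"))
#' @rdname accessors
#' @export
setGeneric("fluxCounts", function(x) standardGeneric("fluxCounts"))
#' @rdname accessors
#' @export
setGeneric("selfCounts", function(x) standardGeneric("selfCounts"))
#' @rdname accessors
#' @export
setGeneric("inVectors", function(x) standardGeneric("inVectors"))
#' @rdname accessors
#' @export
setGeneric("outVectors", function(x) standardGeneric("outVectors"))
#' @rdname accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
#' @rdname accessors
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))
#' @rdname accessors
#' @export
setGeneric("fluxValues", function(x) standardGeneric("fluxValues"))

#' @rdname accessors
#' @export
setMethod("tokens", "TrajectoryCorpus", function(x) names(x@tokenCounts))
#' @rdname accessors
#' @export
setMethod("tokens", "FluxMatrix", function(x) x@tokens)
#' @rdname accessors
#' @export
setMethod("tokens", "ExpectedFlux", function(x) x@tokens)
#' @rdname accessors
#' @export
setMethod("tokens", "LatentWorld", function(x) x@tokens)
#' @rdname accessors
#' @export
setMethod("tokens", "Vocabulary", function(x) x@tokens)
#' @rdname accessors
#' @export
setMethod("tokens", "EmbeddingModel", function(x) x@vocabulary@tokens)
#' @rdname accessors
#' @export
setMethod("tokens", "DistanceMatrix", function(x) x@tokens)

#' @rdname accessors
#' @export
setMethod("tokenCounts", "TrajectoryCorpus", function(x) x@tokenCounts)
#' @rdname accessors
#' @export
setMethod("fluxCounts", "FluxMatrix", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("selfCounts", "FluxMatrix", function(x) x@selfCounts)
#' @rdname accessors
#' @export
setMethod("inVectors", "EmbeddingModel", function(x) x@inVectors)
#' @rdname accessors
#' @export
setMethod("outVectors", "EmbeddingModel", function(x) x@outVectors)
#' @rdname accessors
#' @export
setMethod("vocabulary", "EmbeddingModel", function(x) x@vocabulary)
#' @rdname accessors
#' @export
setMethod("distanceValues", "DistanceMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("fluxValues", "ExpectedFlux", function(x) x@values)

setMethod("show", "TrajectoryCorpus", function(object) {
  cat(sprintf("TrajectoryCorpus: %d trajectories, %d distinct tokens, %d stays\n",
              length(object@personId), length(object@tokenCounts),
              sum(lengths(object@tokens))))
  hasYears <- any(vapply(object@years, function(y) any(!is.na(y)), logical(1)))
  cat(if (hasYears) "  with year annotations\n" else "  year-less\n")
})

setMethod("show", "FluxMatrix", function(object) {
  cat(sprintf("FluxMatrix: %d tokens, total flux %g, self pairs %g\n",
              length(object@tokens), sum(object@counts) / 2,
              sum(object@selfCounts)))
})

setMethod("show", "ExpectedFlux", function(object) {
  cat(sprintf("ExpectedFlux: %d tokens, total %g\n",
              length(object@tokens), sum(object@values) / 2))
})

setMethod("show", "LatentWorld", function(object) {
  cat(sprintf("LatentWorld: %d locations on the unit square, %s decay (exponent %g, C %g), seed %d\n",
              length(object@tokens), object@decay@family,
              object@decay@exponent, object@decay@constant, object@seed))
})

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d tokens (minCount %d, gamma %g)\n",
              length(object@tokens), object@minCount, object@gamma))
})

setMethod("show", "Hyperparams", function(object) {
  cat(sprintf("Hyperparams: d=%d w=%d k=%d gamma=%g alpha0=%g epochs=%d minCount=%d seed=%d\n",
              object@dim, object@window, object@negatives, object@gamma,
              object@alpha0, object@epochs, object@minCount, object@seed))
})

setMethod("show", "EmbeddingModel", function(object) {
  cat(sprintf("EmbeddingModel: %d tokens x %d dimensions (window %d, gamma %g)\n",
              length(object@vocabulary@tokens), object@hyper@dim,
              object@hyper@window, object@hyper@gamma))
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix: %d tokens, metric %s\n",
              length(object@tokens), object@metric))
})

setMethod("show", "DecaySpec", function(object) {
  f <- if (object@family == "power") "r^-%g" else "exp(-%g r)"
  cat(sprintf(paste0("DecaySpec: C=%g, f(r) = ", f, "\n"),
              object@constant, object@exponent))
})

setMethod("show", "GravityFit", function(object) {
  sym <- if (object@decay@family == "power") "alpha" else "beta"
  cat(sprintf("GravityFit (%s): %s=%.4g, C=%.4g, n_pairs=%d, R2(log-log)=%.4f, RMSE(ln)=%.4g\n",
              object@decay@family, sym, object@decay@exponent,
              object@decay@constant, object@nPairs, object@rSquared,
              object@rmseLog))
})

setMethod("show", "Dendrogram", function(object) {
  cat(sprintf("Dendrogram: %d elements, %d clusters (root level 0, leaves 1)\n",
              length(object@elements), length(object@clusterMembers)))
})
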