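#' Hierarchical clustering of vectors by cosine similarity
#'
#' Agglomerative average-linkage clustering on the distance 1 - cosine
#' similarity.  Every cluster (internal node and leaf singleton) carries a
#' hierarchical level in [0, 1]: the root at 0, leaves at 1, internal
#' nodes at their topological depth divided by the maximum root-to-leaf
#' depth — the rescaling that makes levels comparable across dendrograms.
#'
#' @param vectors matrix with one row per element (rownames are element
#'   names), e.g. group centroids from [groupCentroid()].
#' @return A [Dendrogram-class].
#' @export
hclusterCosine <- function(vectors) {
  if (nrow(vectors) < 2L) stopValidation("need at least 2 elements")
  nr <- sqrt(rowSums(vectors^2))
  if (any(nr == 0))
    stopValidation("zero-norm vector(s): ",
                   paste(rownames(vectors)[nr == 0], collapse = ", "))
  C <- tcrossprod(vectors / nr)
  C[C > 1] <- 1
  C[C < -1] <- -1
  d <- stats::as.dist(1 - C)
  hc <- stats::hclust(d, method = "average")
  dendrogramFromHclust(hc, rownames(vectors))
}

## convert an hclust tree into the package's level-annotated cluster list
dendrogramFromHclust <- function(hc, elements) {
  n <- length(elements)
  merge <- hc$merge
  members <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    left <- if (merge[k, 1] < 0) -merge[k, 1] else members[[merge[k, 1]]]
    right <- if (merge[k, 2] < 0) -merge[k, 2] else members[[merge[k, 2]]]
    members[[k]] <- sort(c(left, right))
  }
  # topological depth: root (last merge) 0; children one deeper
  depth <- numeric(n - 1L)
  for (k in rev(seq_len(n - 1L))) {
    for (child in merge[k, ]) {
      if (child > 0) depth[child] <- depth[k] + 1
    }
  }
  leafDepth <- numeric(n)
  for (k in seq_len(n - 1L)) {
    for (child in merge[k, ]) {
      if (child < 0) leafDepth[-child] <- depth[k] + 1
    }
  }
  maxDepth <- max(leafDepth)
  levels <- c(depth / maxDepth, rep(1, n))
  clusters <- c(members, as.list(seq_len(n)))
  new("Dendrogram", elements = elements, clusterMembers = clusters,
      clusterLevels = levels, hclust = hc)
}

#' Export a dendrogram as Newick
#'
#' Writes the underlying tree in Newick format with the cluster levels as
#' internal node labels.
#'
#' @param dendrogram a [Dendrogram-class] built from vectors.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDendrogram <- function(dendrogram, path) {
  phy <- ape::as.phylo(dendrogram@hclust)
  n <- length(dendrogram@elements)
  # ape numbers internal phylo nodes in its own order; label by level of the
  # matching member set
  internal <- dendrogram@clusterMembers[seq_len(n - 1L)]
  key <- vapply(internal, paste, character(1), collapse = ",")
  lv <- dendrogram@clusterLevels[seq_len(n - 1L)]
  labels <- vapply(seq_len(phy$Nnode), function(i) {
    node <- n + i
    mem <- sort(match(ape::extract.clade(phy, node)$tip.label,
                      dendrogram@elements))
    sprintf("%.6g", lv[match(paste(mem, collapse = ","), key)])
  }, character(1))
  phy$node.label <- labels
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Cluster affiliation weights
#'
#' Bipartite element-cluster weights under the hierarchy weight function
#' a_i_beta = exp(r l_beta): each element affiliates with every cluster on
#' its root-to-leaf path, weighted by the cluster's level.  At r = 0 every
#' cluster counts equally; larger r emphasizes the finer (lower-level)
#' structure.  A flat partition affiliates each element with its single
#' cluster (the weight cancels under normalization).
#'
#' @param clustering a [Dendrogram-class] or a named vector of cluster
#'   labels (a flat partition).
#' @param r level-scaling parameter (>= 0 in typical use).
#' @return An [AffiliationGraph-class].
#' @export
affiliationWeights <- function(clustering, r = 1.0) {
  if (is(clustering, "Dendrogram")) {
    el <- clustering@elements
    n <- length(el)
    m <- length(clustering@clusterMembers)
    W <- matrix(0, n, m)
    for (b in seq_len(m))
      W[clustering@clusterMembers[[b]], b] <- exp(r * clustering@clusterLevels[b])
    rownames(W) <- el
    return(new("AffiliationGraph", elements = el, weights = W, r = r))
  }
  labels <- clustering
  if (is.null(names(labels)))
    stopValidation("a flat partition must be a named label vector")
  el <- names(labels)
  cl <- unique(labels)
  W <- matrix(0, length(el), length(cl), dimnames = list(el, cl))
  W[cbind(seq_along(el), match(labels, cl))] <- exp(r * 1)
  new("AffiliationGraph", elements = el, weights = W, r = r)
}

#' Cluster-induced element graph
#'
#' Projects an affiliation graph onto its elements:
#' \deqn{w_{ij} = \frac{1}{\sum_\kappa a_{i\kappa}} \sum_\gamma
#'   \frac{a_{i\gamma} a_{j\gamma}}{\sum_m a_{m\gamma}},}
#' a row-stochastic random-walk kernel through shared cluster memberships
#' (self-loops included).
#'
#' @param aff an [AffiliationGraph-class].
#' @return An [ElementGraph-class].
#' @export
inducedElementGraph <- function(aff) {
  A <- aff@weights
  colTot <- colSums(A)
  if (any(colTot <= 0)) {
    keep <- colTot > 0
    A <- A[, keep, drop = FALSE]
    colTot <- colTot[keep]
  }
  W <- (A %*% (t(A) / colTot)) / rowSums(A)
  dimnames(W) <- list(aff@elements, aff@elements)
  new("ElementGraph", elements = aff@elements, W = W)
}

#' Personalized-PageRank similarity vectors of an element graph
#'
#' Solves, per element i, p = (1 - damping) e_i + damping p W by a direct
#' dense linear solve (residuals far below the 1e-10 contract at the sizes
#' this measure is used for).  Row i of the result is the membership-aware
#' similarity profile of element i.
#'
#' @param graph an [ElementGraph-class].
#' @param damping damping factor in (0, 1); default 0.9.
#' @return A row-stochastic matrix of p_i vectors.
#' @export
elementSimilarityVectors <- function(graph, damping = 0.9) {
  if (damping <= 0 || damping >= 1)
    stopValidation("damping must lie in (0, 1)")
  n <- length(graph@elements)
  P <- (1 - damping) * solve(diag(n) - damping * graph@W)
  dimnames(P) <- list(graph@elements, graph@elements)
  P
}

## align two clusterings on the same element set, in A's element order
ecsElementOrder <- function(A, B) {
  elA <- if (is(A, "Dendrogram")) A@elements else names(A)
  elB <- if (is(B, "Dendrogram")) B@elements else names(B)
  onlyA <- setdiff(elA, elB)
  onlyB <- setdiff(elB, elA)
  if (length(onlyA) || length(onlyB))
    stopValidation("element sets differ; only in first: [",
                   paste(onlyA, collapse = ", "), "], only in second: [",
                   paste(onlyB, collapse = ", "), "]")
  elA
}

ecsSimilarityMatrix <- function(clustering, elements, r, damping) {
  aff <- affiliationWeights(clustering, r)
  P <- elementSimilarityVectors(inducedElementGraph(aff), damping)
  P[elements, elements]
}

#' Element-centric clustering similarity
#'
#' Compares two clusterings (hierarchical or flat) through the
#' personalized-PageRank profiles of their cluster-induced element graphs:
#' per element, S_i = 1 - 0.5 ||p_i^A - p_i^B||_1 in [0, 1], and the
#' overall score is the mean over elements.  The scaling parameter r
#' applies to dendrogram inputs and tunes which hierarchy levels dominate.
#'
#' @param A,B clusterings: [Dendrogram-class] objects or named label
#'   vectors (flat partitions) over the same element set.
#' @param r level-scaling parameter (default 1; ignored by flat partitions).
#' @param damping PPR damping factor (default 0.9).
#' @return A list with `score` and `perElement`.
#' @export
ecsScore <- function(A, B, r = 1.0, damping = 0.9) {
  el <- ecsElementOrder(A, B)
  PA <- ecsSimilarityMatrix(A, el, r, damping)
  PB <- ecsSimilarityMatrix(B, el, r, damping)
  si <- 1 - 0.5 * rowSums(abs(PA - PB))
  names(si) <- el
  list(score = mean(si), perElement = si)
}

#' Scan the ECS across the level-scaling parameter
#'
#' Evaluates [ecsScore()] between a dendrogram and each named flat
#' partition over a grid of r values, yielding the level-resolved profile
#' of which external factor explains which depth of the hierarchy.
#'
#' @param dendrogram a [Dendrogram-class].
#' @param partitions named list of flat partitions (named label vectors).
#' @param rGrid numeric vector of r values.
#' @param damping PPR damping factor (default 0.9).
#' @return A `data.frame` with `partition`, `r`, `score`.
#' @export
rScan <- function(dendrogram, partitions, rGrid, damping = 0.9) {
  if (is.null(names(partitions)) || any(!nzchar(names(partitions))))
    stopValidation("partitions must be a named list")
  out <- do.call(rbind, lapply(names(partitions), function(nm) {
    data.frame(partition = nm, r = rGrid,
               score = vapply(rGrid, function(r)
                 ecsScore(dendrogram, partitions[[nm]], r, damping)$score,
                 numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
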