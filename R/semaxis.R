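#' Group centroid vectors
#'
#' Unweighted mean of the member in-vectors per group label (e.g. the
#' country centroid of its organizations); groups with fewer than `minSize`
#' members are omitted, mirroring the convention of aggregating only
#' countries with at least 25 organizations.
#'
#' @param model an [EmbeddingModel-class].
#' @param labels named character vector: token -> group label.
#' @param minSize minimum group size (default 1).
#' @return A matrix, one row per retained group.
#' @export
groupCentroid <- function(model, labels, minSize = 1L) {
  tk <- intersect(names(labels), model@vocabulary@tokens)
  if (!length(tk)) stopValidation("no labeled token is in the vocabulary")
  grp <- split(tk, labels[tk])
  grp <- grp[lengths(grp) >= minSize]
  if (!length(grp))
    stopValidation("no group reaches minSize = ", minSize)
  V <- model@inVectors
  out <- t(vapply(grp, function(members)
    colMeans(V[members, , drop = FALSE]), numeric(ncol(V))))
  out
}

#' Build a semantic axis from pole sets
#'
#' The axis vector is the difference of the pole means,
#' V_axis = mean(S+) - mean(S-); token scores along the axis are cosine
#' similarities with this vector (see [projectOnAxis()]).
#'
#' @param model an [EmbeddingModel-class].
#' @param positive character vector of positive-pole tokens S+.
#' @param negative character vector of negative-pole tokens S-.
#' @return A list with `positive`, `negative` and the `axis` vector.
#' @export
makeAxis <- function(model, positive, negative) {
  if (!length(positive) || !length(negative))
    stopValidation("pole sets must be non-empty")
  if (length(intersect(positive, negative)))
    stopValidation("pole sets must be disjoint")
  tk <- model@vocabulary@tokens
  miss <- setdiff(c(positive, negative), tk)
  if (length(miss))
    stopValidation("pole token(s) not in vocabulary: ",
                   paste(miss, collapse = ", "))
  V <- model@inVectors
  axis <- colMeans(V[positive, , drop = FALSE]) -
    colMeans(V[negative, , drop = FALSE])
  if (sqrt(sum(axis^2)) == 0)
    stopValidation("pole means coincide: zero axis")
  list(positive = positive, negative = negative, axis = axis)
}

#' Project tokens on a semantic axis
#'
#' Score of token a is the cosine of its vector with the axis vector,
#' cos(v_a, V_axis) in [-1, 1]; higher means closer alignment with the
#' positive pole.  The returned table carries a dense descending-score
#' ranking with ties broken by token order (deterministic).
#'
#' @param model an [EmbeddingModel-class].
#' @param axis an axis from [makeAxis()] (or a raw numeric vector).
#' @param tokens tokens to score (default: whole vocabulary).
#' @return A `data.frame` with `token`, `score`, `rank`, sorted by rank.
#' @export
projectOnAxis <- function(model, axis, tokens = NULL) {
  a <- if (is.list(axis)) axis$axis else axis
  if (is.null(tokens)) tokens <- model@vocabulary@tokens
  miss <- setdiff(tokens, model@vocabulary@tokens)
  if (length(miss))
    stopValidation("token(s) not in vocabulary: ", paste(miss, collapse = ", "))
  V <- model@inVectors[tokens, , drop = FALSE]
  nr <- sqrt(rowSums(V^2))
  if (any(nr == 0))
    stopValidation("zero-norm vector(s): ",
                   paste(tokens[nr == 0], collapse = ", "))
  na <- sqrt(sum(a^2))
  score <- as.numeric(V %*% a) / (nr * na)
  ord <- order(-score, tokens)
  out <- data.frame(token = tokens[ord], score = score[ord],
                    rank = seq_along(tokens), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Geographically matched pole selection
#'
#' Selects the k top-ranked tokens as the positive pole, then scans from
#' the bottom of the ranking taking the worst-ranked token whose region
#' still has unmet quota, until the region composition of the positive pole
#' is matched exactly (e.g. if 2 of the top-k sit in the Northeast, the
#' bottom set will also include 2 from the Northeast).
#'
#' @param rankTable named integer vector: token -> rank (1 = best).
#' @param regions named character vector: token -> region label.
#' @param k pole size (default 5).
#' @return A list with `positive` and `negative` token vectors.
#' @export
matchedPoles <- function(rankTable, regions, k = 5L) {
  k <- as.integer(k)
  if (length(rankTable) < 2L * k)
    stopValidation("need at least 2k ranked tokens")
  miss <- setdiff(names(rankTable), names(regions))
  if (length(miss))
    stopValidation("region missing for: ", paste(miss, collapse = ", "))
  ord <- names(rankTable)[order(rankTable, names(rankTable))]
  top <- ord[seq_len(k)]
  quota <- table(regions[top])
  chosen <- character(0)
  need <- as.list(quota)
  for (tok in rev(ord)) {
    if (length(chosen) == k) break
    if (tok %in% top) next
    reg <- regions[[tok]]
    if (!is.null(need[[reg]]) && need[[reg]] > 0L) {
      chosen <- c(chosen, tok)
      need[[reg]] <- need[[reg]] - 1L
    }
  }
  unmet <- names(need)[vapply(need, function(x) x > 0L, logical(1))]
  if (length(unmet))
    stopValidation("cannot match region quota for: ",
                   paste(unmet, collapse = ", "))
  list(positive = top, negative = chosen)
}

#' Spearman rank correlation with an external ranking
#'
#' Spearman rho between axis scores and an external rank table over their
#' token intersection, with average-rank tie handling.  Note the external
#' table ranks best = 1, so scores are compared against the reversed rank.
#'
#' @param scores a score table from [projectOnAxis()].
#' @param external named numeric vector: token -> external rank (1 = best).
#' @return A list with `rho` and `n`.
#' @export
rankCorrelation <- function(scores, external) {
  common <- intersect(scores$token, names(external))
  if (length(common) < 3L)
    stopValidation("need at least 3 common tokens, have ", length(common))
  s <- scores$score[match(common, scores$token)]
  e <- -as.numeric(external[common])   # rank 1 = best -> largest value
  list(rho = stats::cor(s, e, method = "spearman"), n = length(common))
}

#' L2 norms of token vectors
#'
#' The Euclidean norm of each in-vector; vector size tracks how strongly a
#' location is tied to particular contexts, and its relation to location
#' mass is a useful diagnostic of prestige/connectedness structure.
#'
#' @param model an [EmbeddingModel-class].
#' @param tokens tokens to report (default: whole vocabulary).
#' @return A named numeric vector of norms.
#' @export
vectorNorms <- function(model, tokens = NULL) {
  if (is.null(tokens)) tokens <- model@vocabulary@tokens
  miss <- setdiff(tokens, model@vocabulary@tokens)
  if (length(miss))
    stopValidation("token(s) not in vocabulary: ", paste(miss, collapse = ", "))
  V <- model@inVectors[tokens, , drop = FALSE]
  structure(sqrt(rowSums(V^2)), names = tokens)
}
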