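#' Conditional distribution implied by a trained SGNS model
#'
#' What SGNS actually optimizes is not the softmax conditional but its
#' noise-biased version: the probability of context j given center i is
#' \deqn{P_{NS}(j \mid i) = \frac{P^\gamma(j)\, e^{u_j \cdot v_i}}{Z'_i},
#'   \qquad Z'_i = \sum_{j'} P^\gamma(j')\, e^{u_{j'} \cdot v_i},}
#' i.e. the noise distribution enters the numerator.  With gamma = 0 this
#' reduces to the plain softmax.  Rows are computed with max-subtraction so
#' they are overflow-safe and sum to 1 exactly.
#'
#' @param model an [EmbeddingModel-class].
#' @param cap refuse vocabularies larger than this (the computation is a
#'   dense |A| x |A| matrix); default 5000.
#' @return A list with `values` (row-stochastic matrix, rows = centers) and
#'   `normalizers` (the per-row Z').
#' @export
impliedConditional <- function(model, cap = 5000L) {
  n <- length(model@vocabulary@tokens)
  if (n > cap)
    stopValidation("vocabulary size ", n, " exceeds the dense cap ", cap)
  S <- model@inVectors %*% t(model@outVectors)   # S[i, j] = u_j . v_i
  logNoise <- log(model@vocabulary@noise)
  L <- sweep(S, 2L, -logNoise)                   # add log-noise per column
  mx <- apply(L, 1L, max)
  E <- exp(L - mx)
  Z <- rowSums(E)
  P <- E / Z
  dimnames(P) <- list(model@vocabulary@tokens, model@vocabulary@tokens)
  list(values = P, normalizers = exp(mx) * Z)
}

#' Gravity-form flux implied by a trained SGNS model
#'
#' At the optimum of the window-1, gamma = 1 objective the model predicts a
#' flow with the gravity form
#' \deqn{\hat T_{ij} \propto P(i)\, P(j)\, e^{v_j \cdot v_i},}
#' symmetric with zero diagonal.  The matrix is normalized so its unordered
#' pair total equals the training corpus's window-pair count, making the
#' entries comparable to observed co-occurrence counts.
#'
#' @param model an [EmbeddingModel-class].
#' @param vectors `"in"` (use v.v, the published embedding) or `"out_avg"`
#'   (use the average of in- and out-vectors).
#' @param cap dense-computation vocabulary cap.
#' @return An [ExpectedFlux-class].
#' @export
impliedFlux <- function(model, vectors = c("in", "out_avg"), cap = 5000L) {
  vectors <- match.arg(vectors)
  n <- length(model@vocabulary@tokens)
  if (n > cap)
    stopValidation("vocabulary size ", n, " exceeds the dense cap ", cap)
  V <- if (vectors == "in") model@inVectors
       else (model@inVectors + model@outVectors) / 2
  S <- V %*% t(V)
  S <- (S + t(S)) / 2                          # enforce exact symmetry
  p <- model@vocabulary@frequency
  L <- log(outer(p, p)) + S
  diag(L) <- -Inf
  vals <- exp(L - max(L[is.finite(L)]))
  scale <- if (model@nPairs > 0) model@nPairs else 1
  vals <- vals * (scale / (sum(vals) / 2))
  dimnames(vals) <- list(model@vocabulary@tokens, model@vocabulary@tokens)
  new("ExpectedFlux", tokens = model@vocabulary@tokens, values = vals)
}

#' In-vector / out-vector agreement diagnostic
#'
#' At the gamma = 1 optimum with large enough dimension there exist optimal
#' solutions with v_i = u_i; in practice the two families drift apart.
#' This reports the per-token cosine between in- and out-vector as a
#' convergence / identifiability diagnostic.
#'
#' @param model an [EmbeddingModel-class].
#' @return A list with `cosines` (named vector; `NA` where either vector has
#'   zero norm) and `mean` (over the non-`NA` entries).
#' @export
diagnoseInOut <- function(model) {
  ni <- sqrt(rowSums(model@inVectors^2))
  no <- sqrt(rowSums(model@outVectors^2))
  dots <- rowSums(model@inVectors * model@outVectors)
  cosines <- ifelse(ni > 0 & no > 0, dots / (ni * no), NA_real_)
  names(cosines) <- model@vocabulary@tokens
  list(cosines = cosines, mean = mean(cosines, na.rm = TRUE))
}

## shared scaffolding: wrap a plain embedding matrix as an EmbeddingModel
## whose vocabulary statistics come from a flux matrix
fluxVocabulary <- function(flux) {
  cnt <- rowSums(flux@counts) + flux@selfCounts * 2
  cnt[cnt <= 0] <- 1
  new("Vocabulary", tokens = flux@tokens, counts = as.numeric(cnt),
      frequency = as.numeric(cnt) / sum(cnt),
      noise = as.numeric(cnt) / sum(cnt), gamma = 1.0, minCount = 0L)
}

wrapEmbedding <- function(flux, V) {
  vocab <- fluxVocabulary(flux)
  rownames(V) <- flux@tokens
  new("EmbeddingModel", vocabulary = vocab, inVectors = V, outVectors = V,
      hyper = Hyperparams(dim = ncol(V), minCount = 0, seed = 0),
      nPairs = sum(flux@counts) / 2 + sum(flux@selfCounts))
}

#' Baseline: truncated-SVD embedding of the flux matrix
#'
#' Top-`dim` left singular vectors of the co-occurrence count matrix,
#' scaled by their singular values — the classic linear counterpart to the
#' neural embedding.
#'
#' @param flux a [FluxMatrix-class].
#' @param dim embedding dimension (must not exceed the matrix rank).
#' @return An [EmbeddingModel-class] (in- and out-vectors identical).
#' @export
svdEmbed <- function(flux, dim) {
  dim <- as.integer(dim)
  s <- svd(flux@counts)
  rank <- sum(s$d > s$d[1] * 1e-12)
  if (dim > rank)
    stopValidation("dim = ", dim, " exceeds the matrix rank ", rank)
  V <- s$u[, seq_len(dim), drop = FALSE] %*%
    diag(s$d[seq_len(dim)], nrow = dim)
  wrapEmbedding(flux, V)
}

#' Baseline: Laplacian-eigenmap embedding of the flux matrix
#'
#' Eigenvectors 2..dim+1 (smallest nonzero eigenvalues) of the symmetric
#' normalized Laplacian of the co-occurrence graph.
#'
#' @param flux a [FluxMatrix-class]; the graph should be connected
#'   (zero-degree tokens are rejected).
#' @param dim embedding dimension (<= number of tokens - 1).
#' @return An [EmbeddingModel-class].
#' @export
laplacianEmbed <- function(flux, dim) {
  dim <- as.integer(dim)
  A <- flux@counts
  n <- nrow(A)
  if (dim > n - 1L)
    stopValidation("dim must be <= number of tokens - 1")
  deg <- rowSums(A)
  if (any(deg <= 0))
    stopValidation("isolated token(s): ",
                   paste(flux@tokens[deg <= 0], collapse = ", "))
  Dhalf <- 1 / sqrt(deg)
  L <- diag(n) - A * outer(Dhalf, Dhalf)
  e <- eigen(L, symmetric = TRUE)
  # eigen returns decreasing eigenvalues; take the smallest, skip the trivial
  idx <- rev(seq_len(n))[2:(dim + 1L)]
  V <- e$vectors[, idx, drop = FALSE]
  wrapEmbedding(flux, V)
}

#' Baseline: personalized-PageRank similarity vectors
#'
#' Per-row personalized PageRank on the row-normalized flux graph with
#' restart probability 1 - damping: row i solves
#' p = (1 - damping) e_i + damping p W.  The resulting row-stochastic
#' matrix is a diffusion-based similarity profile per token.
#'
#' @param flux a [FluxMatrix-class] with positive degrees.
#' @param damping damping factor in (0, 1); default 0.85.
#' @return A row-stochastic matrix (rows = seed tokens).
#' @export
pprVectors <- function(flux, damping = 0.85) {
  if (damping <= 0 || damping >= 1)
    stopValidation("damping must lie in (0, 1)")
  A <- flux@counts
  deg <- rowSums(A)
  if (any(deg <= 0))
    stopValidation("isolated token(s): ",
                   paste(flux@tokens[deg <= 0], collapse = ", "))
  W <- A / deg
  n <- nrow(A)
  P <- (1 - damping) * solve(diag(n) - damping * W)
  dimnames(P) <- list(flux@tokens, flux@tokens)
  P
}
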