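#' Read a location metadata table
#'
#' Reads a TSV/CSV table of location records.  The header must name at least
#' `token`; recognised optional columns are `name`, `country`, `region`,
#' `latitude`, `longitude`, `mass`, `rank`, `category` — any further columns
#' are kept as free-form group labels (e.g. language, census region).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return A `data.frame`, one row per location, row order preserved; blank
#'   optional fields become `NA`.
#' @examples
#' f <- tempfile()
#' writeLines(c("token,name,latitude,longitude,mass",
#'              "MIT,Massachusetts Institute of Technology,42.36,-71.09,3500"), f)
#' readLocations(f, "csv")
#' @export
readLocations <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopValidation("no such file: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE,
                          strip.white = TRUE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  if (!"token" %in% names(df)) stopValidation("header must name a 'token' column")
  df[df == ""] <- NA
  dup <- df$token[duplicated(df$token)]
  if (length(dup))
    stopValidation("duplicate token(s) in location table: ",
                   paste(unique(dup), collapse = ", "))
  for (col in intersect(c("latitude", "longitude", "mass"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  if ("rank" %in% names(df)) df$rank <- as.integer(df$rank)
  if ("latitude" %in% names(df)) {
    bad <- which(!is.na(df$latitude) & abs(df$latitude) > 90)
    if (length(bad))
      stopValidation("latitude out of [-90, 90] at row ", bad[1])
  }
  if ("longitude" %in% names(df)) {
    bad <- which(!is.na(df$longitude) &
                 (df$longitude <= -180 | df$longitude > 180))
    if (length(bad))
      stopValidation("longitude out of (-180, 180] at row ", bad[1])
  }
  if ("mass" %in% names(df)) {
    bad <- which(!is.na(df$mass) & df$mass <= 0)
    if (length(bad)) stopValidation("non-positive mass at row ", bad[1])
  }
  rownames(df) <- NULL
  df
}

#' Read a trajectory corpus
#'
#' Two dialects: `"jsonl"` — one JSON object per line,
#' `{"person_id": str, "stays": [[year|null, token], ...]}`, years
#' non-decreasing within a trajectory; `"tokens"` — one whitespace-separated
#' token sequence per line, no years.  Empty lines are skipped; length-1
#' trajectories are retained (they contribute to token counts but emit no
#' window pairs).
#'
#' @param path file path.
#' @param dialect `"jsonl"` or `"tokens"`.
#' @return A [TrajectoryCorpus-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("A B C", "", "B A"), f)
#' readTrajectories(f, "tokens")
#' @export
readTrajectories <- function(path, dialect = c("jsonl", "tokens")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopValidation("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stopValidation("no trajectories in ", path)
  if (dialect == "tokens") {
    toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
    return(TrajectoryCorpus(toks))
  }
  ids <- character(length(keep))
  toks <- vector("list", length(keep))
  yrs <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    obj <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyVector = FALSE),
                    error = function(e)
                      stopValidation("malformed JSON at line ", ln, ": ",
                                     conditionMessage(e)))
    if (is.null(obj$person_id) || is.null(obj$stays) || !length(obj$stays))
      stopValidation("line ", ln, ": need person_id and a non-empty stays list")
    y <- vapply(obj$stays, function(s)
      if (is.null(s[[1]])) NA_integer_ else as.integer(s[[1]]), integer(1))
    tk <- vapply(obj$stays, function(s) as.character(s[[2]]), character(1))
    if (any(grepl("[[:space:]]", tk)))
      stopValidation("line ", ln, ": tokens may not contain whitespace")
    yy <- y[!is.na(y)]
    if (length(yy) > 1L && any(diff(yy) < 0))
      stopValidation("line ", ln, ": years decrease within the trajectory")
    ids[k] <- as.character(obj$person_id)
    toks[[k]] <- tk
    yrs[[k]] <- y
  }
  TrajectoryCorpus(toks, years = yrs, personId = ids)
}

#' Write a trajectory corpus
#'
#' Inverse of [readTrajectories()].  The `"tokens"` dialect drops year
#' annotations.
#'
#' @param corpus a [TrajectoryCorpus-class].
#' @param path output file path.
#' @param dialect `"jsonl"` or `"tokens"`.
#' @return `path`, invisibly.
#' @export
writeTrajectories <- function(corpus, path, dialect = c("jsonl", "tokens")) {
  dialect <- match.arg(dialect)
  if (dialect == "tokens") {
    writeLines(vapply(corpus@tokens, paste, character(1), collapse = " "), path)
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_along(corpus@personId)) {
      stays <- mapply(function(y, t) list(if (is.na(y)) NULL else y, t),
                      corpus@years[[i]], corpus@tokens[[i]],
                      SIMPLIFY = FALSE)
      writeLines(jsonlite::toJSON(
        list(person_id = corpus@personId[i], stays = stays),
        auto_unbox = TRUE, null = "null"), con)
    }
  }
  invisible(path)
}

## within-year shuffle of a single trajectory; caller controls the RNG state
shuffleWithinYears <- function(tok, yr) {
  if (all(is.na(yr))) return(tok)
  key <- as.character(yr)
  key[is.na(key)] <- paste0(".na", seq_len(sum(is.na(key))))
  grp <- factor(key, levels = unique(key))
  idx <- unlist(lapply(split(seq_along(tok), grp), function(ix)
    if (length(ix) > 1L) ix[sample.int(length(ix))] else ix),
    use.names = FALSE)
  tok[idx]
}

#' Per-epoch token stream with within-year shuffling
#'
#' Tokens grouped under the same year keep their year order, but the order
#' within each year is a uniform random permutation driven by `seed`; this is
#' re-drawn each training epoch so that simultaneous co-affiliations do not
#' impose a spurious sequential order.  Year-less trajectories are returned
#' unchanged.
#'
#' @param tokens character vector of stays, in order.
#' @param years parallel integer vector of years (`NA` = unknown), or `NULL`.
#' @param seed integer seed; the same seed always yields the same stream.
#' @return The (possibly permuted) token vector.
#' @examples
#' epochTokenStream(c("A", "B", "C"), years = c(2008, 2008, 2009), seed = 1)
#' @export
epochTokenStream <- function(tokens, years = NULL, seed = 1L) {
  if (is.null(years) || all(is.na(years))) return(tokens)
  if (length(years) != length(tokens))
    stopValidation("years must be parallel to tokens")
  withr::with_seed(as.integer(seed), shuffleWithinYears(tokens, years))
}

## epoch-specific seed derivation (kept inside 32-bit integer range)
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807 + 12345) %%
             2147483629)
}

## shuffle a whole corpus for one epoch; cheap no-op for year-less corpora
epochStreams <- function(corpus, seed) {
  hasYears <- vapply(corpus@years, function(y) any(!is.na(y)), logical(1))
  if (!any(hasYears)) return(corpus@tokens)
  out <- corpus@tokens
  withr::with_seed(as.integer(seed), {
    for (i in which(hasYears))
      out[[i]] <- shuffleWithinYears(corpus@tokens[[i]], corpus@years[[i]])
  })
  out
}

#' Build the co-occurrence flux matrix of a corpus
#'
#' For every position t and offset 1..window within a trajectory, the
#' unordered token pair (a_t, a_(t+offset)) increments the flux count
#' T_ij by one; i = j pairs (consecutive repeats) are recorded in
#' `selfCounts` instead, keeping the matrix diagonal zero.  The matrix is
#' symmetric by construction, matching the convention T_ij = T_ji.
#'
#' @param corpus a [TrajectoryCorpus-class].
#' @param window context window size (default 1, the first-order flux).
#' @param shuffleSeed optional integer; when given, within-year shuffling is
#'   applied once before counting.
#' @return A [FluxMatrix-class].
#' @examples
#' fm <- buildFluxMatrix(TrajectoryCorpus(list(c("A", "B", "C"))))
#' fluxCounts(fm)
#' @export
buildFluxMatrix <- function(corpus, window = 1L, shuffleSeed = NULL) {
  window <- as.integer(window)
  if (window < 1L) stopValidation("window must be >= 1")
  toks <- if (is.null(shuffleSeed)) corpus@tokens
          else epochStreams(corpus, as.integer(shuffleSeed))
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  n <- length(vocab)
  flat <- match(unlist(toks, use.names = FALSE), vocab)
  lens <- lengths(toks)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  counts <- matrix(0, n, n, dimnames = list(vocab, vocab))
  self <- numeric(n)
  names(self) <- vocab
  for (off in seq_len(window)) {
    m <- pmax(lens - off, 0L)
    if (!sum(m)) next
    i1 <- sequence(m) + rep(starts, m)
    a <- flat[i1]
    b <- flat[i1 + off]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    isSelf <- lo == hi
    if (any(isSelf)) {
      st <- tabulate(lo[isSelf], nbins = n)
      self <- self + st
    }
    if (any(!isSelf)) {
      key <- (lo[!isSelf] - 1) * n + hi[!isSelf]
      tab <- table(key)
      k <- as.integer(names(tab))
      v <- as.numeric(tab)
      li <- (k - 1L) %/% n + 1L
      hj <- (k - 1L) %% n + 1L
      counts[cbind(li, hj)] <- counts[cbind(li, hj)] + v
      counts[cbind(hj, li)] <- counts[cbind(hj, li)] + v
    }
  }
  new("FluxMatrix", tokens = vocab, counts = counts, selfCounts = self)
}

#' Persist embedding vectors in word2vec text format
#'
#' Writes the standard word2vec text format: a header line
#' `"<vocab_size> <dim>"` followed by one line per token with `dim`
#' whitespace-separated decimals.  Coordinates survive a round trip to
#' within 1e-6.
#'
#' @param model an [EmbeddingModel-class].
#' @param path output path.
#' @param vectors `"in"` (default, the published embedding) or `"out"`.
#' @return `path`, invisibly.
#' @export
writeEmbedding <- function(model, path, vectors = c("in", "out")) {
  vectors <- match.arg(vectors)
  V <- if (vectors == "in") model@inVectors else model@outVectors
  tk <- model@vocabulary@tokens
  if (!length(tk)) stopValidation("model has no tokens")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(V), ncol(V)), con)
  body <- vapply(seq_len(nrow(V)), function(i)
    paste(tk[i], paste(sprintf("%.9g", V[i, ]), collapse = " ")), character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read embedding vectors from word2vec text format
#'
#' Inverse of [writeEmbedding()]; only one vector family is stored in the
#' format, so the result carries the file's vectors as in-vectors, zero
#' out-vectors, and a uniform placeholder vocabulary (occurrence counts are
#' not part of the format).
#'
#' @param path file path.
#' @return An [EmbeddingModel-class] (in-vectors only).
#' @export
readEmbedding <- function(path) {
  if (!file.exists(path)) stopValidation("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(hdr) != 2L) stopValidation("malformed word2vec header")
  n <- as.integer(hdr[1])
  d <- as.integer(hdr[2])
  if (length(lines) - 1L != n)
    stopValidation("header promises ", n, " rows, file has ", length(lines) - 1L)
  parts <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  bad <- which(lengths(parts) != d + 1L)
  if (length(bad))
    stopValidation("row ", bad[1], " has ", lengths(parts)[bad[1]] - 1L,
                   " coordinates, header says ", d)
  tk <- vapply(parts, `[`, character(1), 1L)
  V <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  if (d == 1L) V <- matrix(V, ncol = 1L)
  rownames(V) <- tk
  vocab <- new("Vocabulary", tokens = tk, counts = rep(1, n),
               frequency = rep(1 / n, n), noise = rep(1 / n, n),
               gamma = 1.0, minCount = 0L)
  new("EmbeddingModel", vocabulary = vocab, inVectors = V,
      outVectors = matrix(0, n, d, dimnames = list(tk, NULL)),
      hyper = Hyperparams(dim = d, minCount = 0, seed = 0), nPairs = 0)
}

#' Flux / distance edge-list persistence
#'
#' Symmetric matrices persist as three-column TSV edge lists
#' (`token_i`, `token_j`, `value`) with one row per unordered pair
#' (`token_i < token_j`); zero entries are omitted for flux.
#'
#' @param x a [FluxMatrix-class], [ExpectedFlux-class] or
#'   [DistanceMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(x, path) {
  vals <- if (is(x, "FluxMatrix")) x@counts
          else if (is(x, "ExpectedFlux")) x@values
          else x@values
  tk <- tokens(x)
  ut <- upper.tri(vals)
  if (is(x, "FluxMatrix")) ut <- ut & vals > 0
  idx <- which(ut, arr.ind = TRUE)
  df <- data.frame(token_i = tk[idx[, 1]], token_j = tk[idx[, 2]],
                   value = vals[idx], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @param tokens optional full vocabulary (tokens absent from any edge are
#'   kept as all-zero rows).
#' @export
readFluxEdges <- function(path, tokens = NULL) {
  if (!file.exists(path)) stopValidation("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  tk <- if (is.null(tokens)) sort(unique(c(df$token_i, df$token_j)))
        else sort(unique(c(tokens, df$token_i, df$token_j)))
  n <- length(tk)
  counts <- matrix(0, n, n, dimnames = list(tk, tk))
  i <- match(df$token_i, tk)
  j <- match(df$token_j, tk)
  counts[cbind(i, j)] <- df$value
  counts[cbind(j, i)] <- df$value
  diag(counts) <- 0
  new("FluxMatrix", tokens = tk, counts = counts,
      selfCounts = structure(numeric(n), names = tk))
}
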