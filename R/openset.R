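#' Cosine similarity between two vectors
#'
#' \code{dot(a, b) / (||a|| * ||b||)}, in [-1, 1]. Zero-norm inputs are
#' rejected.
#'
#' @param a,b numeric vectors of equal length.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity undefined for a zero-norm vector")
  sum(a * b) / (na * nb)
}

#' Per-dimension standardization parameters
#'
#' Mean and population standard deviation of each dimension over the
#' enrolled vectors; standardization maps \code{x} to
#' \code{(x - mean) / max(sd, epsilon)}. Zero-variance dimensions are
#' floored at \code{epsilon} so identical vectors standardize to zero.
#'
#' @param vectors numeric matrix (rows = enrolled vectors), at least 2 rows.
#' @param epsilon variance floor.
#' @return object of class \code{standardization}.
#' @export
fit_standardization <- function(vectors, epsilon = 1e-8) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2)
    stop("at least 2 vectors are required to fit standardization")
  mu <- colMeans(vectors)
  sd <- sqrt(colMeans(sweep(vectors, 2, mu)^2))  # population convention
  structure(list(mean = mu, sd = sd, epsilon = epsilon),
            class = "standardization")
}

#' Apply standardization parameters
#' @param params a \code{standardization}.
#' @param x vector or matrix (rows = vectors).
#' @export
standardize <- function(params, x) {
  s <- pmax(params$sd, params$epsilon)
  if (is.matrix(x)) sweep(sweep(x, 2, params$mean), 2, s, "/")
  else (x - params$mean) / s
}

#' Create an empty enrollment database
#'
#' Holds authorized subjects' 64-dimensional feature vectors, the
#' standardization parameters fitted over all enrolled vectors, and a cache
#' of the standardized vectors.
#'
#' @param gallery how a query is scored against a subject:
#'   \code{"mean"} (cosine against the subject's mean standardized vector,
#'   default) or \code{"max"} (maximum cosine over the subject's vectors).
#' @param standardize standardize enrolled vectors and queries with the
#'   database parameters (default). \code{FALSE} scores raw vectors, which
#'   is useful to quantify how much standardization helps.
#' @return object of class \code{feature_db}.
#' @seealso \code{\link{enroll}}, \code{\link{identify}}
#' @export
feature_db <- function(gallery = c("mean", "max"), standardize = TRUE) {
  structure(list(vectors = matrix(numeric(0), 0, 64),
                 subject_id = integer(0),
                 meta = NULL,
                 params = NULL,
                 standardized = NULL,
                 gallery = match.arg(gallery),
                 standardize = standardize),
            class = "feature_db")
}

#' Enroll feature vectors
#'
#' Appends the vectors, refits the standardization parameters over the full
#' enrolled set, and refreshes the standardized cache.
#'
#' @param db a \code{feature_db}.
#' @param vectors matrix n x 64 of feature vectors.
#' @param subject_id subject label per vector (length n or 1).
#' @param meta optional data.frame of per-vector source metadata.
#' @return the updated \code{feature_db}.
#' @export
enroll <- function(db, vectors, subject_id, meta = NULL) {
  stopifnot(inherits(db, "feature_db"))
  vectors <- matrix(as.numeric(vectors), ncol = 64)
  stopifnot(all(is.finite(vectors)))
  n <- nrow(vectors)
  if (length(subject_id) == 1) subject_id <- rep(subject_id, n)
  stopifnot(length(subject_id) == n)
  db$vectors <- rbind(db$vectors, vectors)
  db$subject_id <- c(db$subject_id, subject_id)
  if (!is.null(meta)) db$meta <- rbind(db$meta, meta)
  if (nrow(db$vectors) >= 2) {
    db$params <- fit_standardization(db$vectors)
    db$standardized <- if (db$standardize)
      standardize(db$params, db$vectors) else db$vectors
  }
  db
}

# per-subject similarity scores for a (already standardized) query vector
gallery_scores <- function(db, q) {
  subjects <- sort(unique(db$subject_id))
  vapply(subjects, function(s) {
    V <- db$standardized[db$subject_id == s, , drop = FALSE]
    if (db$gallery == "mean") cosine_similarity(colMeans(V), q)
    else max(apply(V, 1, cosine_similarity, b = q))
  }, 0)
}

#' Identify a query vector against the enrollment database
#'
#' The query is standardized with the enrollment-time parameters, scored
#' against every enrolled subject's gallery, and accepted as the
#' best-scoring subject if the best cosine similarity reaches the
#' threshold; otherwise it is declared unknown. Ties on the best score are
#' broken toward the lowest subject id and flagged.
#'
#' @param db a non-empty \code{feature_db}.
#' @param query 64-dimensional feature vector.
#' @param threshold acceptance threshold in [-1, 1] (default 0.85).
#' @param standardize_query standardize the query with the database
#'   parameters (default) or score it raw.
#' @return object of class \code{identification}: list with
#'   \code{subject_id} (NA when unknown), \code{accepted},
#'   \code{best_similarity}, \code{threshold}, per-subject \code{scores}
#'   and a \code{tie} flag.
#' @export
identify <- function(db, query, threshold = 0.85, standardize_query = TRUE) {
  stopifnot(inherits(db, "feature_db"))
  if (nrow(db$vectors) == 0) stop("empty enrollment database")
  if (is.null(db$params)) stop("database has fewer than 2 enrolled vectors")
  stopifnot(threshold >= -1, threshold <= 1, length(query) == 64)
  q <- if (standardize_query && db$standardize)
    standardize(db$params, query) else query
  scores <- gallery_scores(db, q)
  subjects <- sort(unique(db$subject_id))
  best <- max(scores)
  hits <- which(scores == best)
  accepted <- best >= threshold
  structure(list(
    subject_id = if (accepted) subjects[hits[1]] else NA,
    accepted = accepted,
    best_similarity = best,
    threshold = threshold,
    scores = stats::setNames(scores, subjects),
    tie = length(hits) > 1), class = "identification")
}

#' @export
print.identification <- function(x, ...) {
  cat(sprintf("Identification: %s (best similarity %.4f %s threshold %.2f)%s\n",
              if (x$accepted) paste("subject", x$subject_id) else "unknown",
              x$best_similarity, if (x$accepted) ">=" else "<",
              x$threshold, if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' Score a batch of query vectors against the database
#'
#' Vectorized counterpart of \code{\link{identify}} used by the evaluation
#' sweeps: returns each query's per-subject similarities, the best-matching
#' subject and best score.
#'
#' @param db a non-empty \code{feature_db}.
#' @param queries matrix n x 64.
#' @param standardize_query as in \code{\link{identify}}.
#' @return list with \code{scores} (n x n_subjects matrix),
#'   \code{best_subject}, \code{best_similarity}.
#' @export
score_queries <- function(db, queries, standardize_query = TRUE) {
  stopifnot(inherits(db, "feature_db"), nrow(db$vectors) > 0)
  queries <- matrix(as.numeric(queries), ncol = 64)
  Q <- if (standardize_query && db$standardize)
    standardize(db$params, queries) else queries
  subjects <- sort(unique(db$subject_id))
  if (db$gallery == "mean") {
    G <- t(vapply(subjects, function(s)
      colMeans(db$standardized[db$subject_id == s, , drop = FALSE]),
      numeric(64)))
    Gn <- G / sqrt(rowSums(G^2))
    Qn <- Q / sqrt(rowSums(Q^2))
    S <- Qn %*% t(Gn)
  } else {
    Vn <- db$standardized / sqrt(rowSums(db$standardized^2))
    Qn <- Q / sqrt(rowSums(Q^2))
    all_s <- Qn %*% t(Vn)
    S <- vapply(subjects, function(s)
      apply(all_s[, db$subject_id == s, drop = FALSE], 1, max),
      numeric(nrow(Q)))
    S <- matrix(S, nrow = nrow(Q))
  }
  colnames(S) <- subjects
  best <- max.col(S, ties.method = "first")
  list(scores = S,
       best_subject = subjects[best],
       best_similarity = S[cbind(seq_len(nrow(S)), best)])
}

#' Persist / restore an enrollment database
#'
#' The database (records, standardization parameters, gallery mode) is
#' written as JSON at full double precision, so a reload reproduces
#' identification results bit for bit.
#'
#' @param db a \code{feature_db}.
#' @param path file path.
#' @export
db_save <- function(db, path) {
  stopifnot(inherits(db, "feature_db"))
  payload <- list(
    gallery = db$gallery,
    standardize = db$standardize,
    subject_id = db$subject_id,
    vectors = db$vectors,
    meta = db$meta)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname db_save
#' @export
db_load <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  db <- feature_db(gallery = payload$gallery,
                   standardize = isTRUE(payload$standardize))
  if (length(payload$subject_id) > 0)
    db <- enroll(db, matrix(payload$vectors, ncol = 64),
                 payload$subject_id,
                 meta = payload$meta)
  db
}

#' @export
print.feature_db <- function(x, ...) {
  cat(sprintf(
    "Enrollment database: %d vector(s) from %d subject(s), gallery = %s\n",
    nrow(x$vectors), length(unique(x$subject_id)), x$gallery))
  invisible(x)
}
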