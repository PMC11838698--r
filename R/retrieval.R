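# Co-embedding vector store and top-k search. The exact backend (full-scan
# matrix product) is the correctness oracle; an approximate random-hyperplane
# LSH backend implements the same query contract and reports its measured
# recall against the exact answers at build time.

#' Build an embedding index
#'
#' Cosine-metric indexes store unit-normalized vectors (classification-space
#' geometry, Eq.-1 ranking); `metric = "ip"` stores raw vectors and ranks by
#' inner product (affinity-space geometry, which orders differently).
#'
#' @param vectors n x d numeric matrix (or list of [co_embedding()]s)
#' @param ids item identifiers, unique, length n (defaults to rownames)
#' @param backend "exact" (full scan, ground truth) or "lsh" (random
#'   hyperplane approximate index)
#' @param metric "cosine" or "ip"
#' @param model_fingerprint optional checksum of the producing model, checked
#'   by [screen_matrix()]
#' @param n_planes LSH only: number of hyperplanes (default 12)
#' @param recall_sample LSH only: queries used to measure recall@10 against
#'   the exact oracle at build time (default 25)
#' @return an object of class `embedding_index`
#' @export
build_index <- function(vectors, ids = NULL, backend = c("exact", "lsh"),
                        metric = c("cosine", "ip"), model_fingerprint = NULL,
                        n_planes = 12L, recall_sample = 25L) {
  backend <- match.arg(backend)
  metric <- match.arg(metric)
  if (is.list(vectors) && !is.matrix(vectors)) {
    ids <- ids %||% vapply(vectors, function(z) z$owner_id, "")
    vectors <- do.call(rbind, lapply(vectors, co_vector))
  }
  vectors <- as.matrix(vectors)
  if (!nrow(vectors)) stop_dti("cannot index zero vectors", "dti_input_error")
  ids <- ids %||% rownames(vectors)
  if (is.null(ids)) stop_dti("ids are required (or rownames on the matrix)",
                             "dti_input_error")
  ids <- as.character(ids)
  if (length(ids) != nrow(vectors))
    stop_dti(sprintf("%d ids for %d vectors", length(ids), nrow(vectors)),
             "dti_input_error")
  if (anyDuplicated(ids))
    stop_dti(sprintf("duplicate id '%s'", ids[duplicated(ids)][1L]), "dti_input_error")
  if (any(!is.finite(vectors)))
    stop_dti("vectors must be finite", "dti_input_error")
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(vectors^2))
    if (any(nrm == 0)) stop_dti("zero vector cannot be cosine-indexed", "dti_input_error")
    vectors <- vectors / nrm
  }
  rownames(vectors) <- ids
  idx <- structure(list(vectors = vectors, ids = ids, backend = backend,
                        metric = metric, d = ncol(vectors), n = nrow(vectors),
                        model_fingerprint = model_fingerprint,
                        meta = list(normalized = metric == "cosine")),
                   class = "embedding_index")
  if (backend == "lsh") {
    planes <- with_seed(derive_seed(n_planes, "lsh_planes"),
                        matrix(rnorm(ncol(vectors) * n_planes), ncol(vectors), n_planes))
    codes <- lsh_codes(vectors, planes)
    idx$lsh <- list(planes = planes, codes = codes, n_planes = as.integer(n_planes))
    ns <- min(recall_sample, nrow(vectors))
    qs <- with_seed(derive_seed(n_planes, "lsh_recall"),
                    sample.int(nrow(vectors), ns))
    k <- min(10L, nrow(vectors))
    rec <- vapply(qs, function(i) {
      truth <- topk_scan(idx$vectors, vectors[i, ], k, ids, metric)$id
      approx <- query_topk(idx, vectors[i, ], k)$id
      length(intersect(truth, approx)) / k
    }, 0)
    idx$meta$recall_at_10 <- mean(rec)
  }
  idx
}

lsh_codes <- function(vectors, planes) {
  bits <- (vectors %*% planes) > 0
  as.integer(bits %*% 2^(seq_len(ncol(planes)) - 1L))
}

topk_scan <- function(vectors, query, k, ids, metric) {
  q <- as.numeric(query)
  if (metric == "cosine") {
    nq <- sqrt(sum(q^2))
    if (nq == 0) stop_dti("zero query vector", "dti_input_error")
    q <- q / nq
  }
  scores <- as.numeric(vectors %*% q)
  o <- order(-scores, seq_along(scores))[seq_len(min(k, length(scores)))]
  data.frame(rank = seq_along(o), id = ids[o], score = scores[o],
             stringsAsFactors = FALSE)
}

#' Query an index for the top-k most similar items
#'
#' Exact backend: true top-k by full scan (ties broken by insertion order).
#' LSH backend: candidates gathered from buckets in increasing Hamming
#' distance until at least `k` are found, then reranked exactly.
#'
#' @param index an `embedding_index`
#' @param query query vector (length d) or `co_embedding`
#' @param k number of hits; `k > n` returns all n, `k = 0` an empty table
#' @return data.frame with `rank`, `id`, `score` (cosine or inner product)
#' @export
query_topk <- function(index, query, k) {
  stopifnot(inherits(index, "embedding_index"))
  q <- co_vector(query)
  if (length(q) != index$d)
    stop_dti(sprintf("query width %d != index width %d", length(q), index$d),
             "dti_input_error")
  if (k < 0) stop_dti("k must be non-negative", "dti_config_error")
  if (k == 0) return(data.frame(rank = integer(0), id = character(0),
                                score = numeric(0), stringsAsFactors = FALSE))
  if (index$backend == "exact")
    return(topk_scan(index$vectors, q, k, index$ids, index$metric))
  # lsh: expand Hamming radius until enough candidates
  qn <- if (index$metric == "cosine") q / sqrt(sum(q^2)) else q
  qbits <- as.integer((matrix(qn, 1) %*% index$lsh$planes) > 0)
  codebits <- vapply(seq_len(index$lsh$n_planes), function(b)
    bitwAnd(index$lsh$codes %/% as.integer(2^(b - 1L)), 1L), integer(index$n))
  hamming <- as.integer(abs(sweep(codebits, 2L, qbits, "-")) %*%
                          rep(1L, index$lsh$n_planes))
  cand <- integer(0)
  r <- 0L
  while (length(cand) < min(k, index$n) && r <= index$lsh$n_planes) {
    cand <- which(hamming <= r)
    r <- r + 1L
  }
  sub <- topk_scan(index$vectors[cand, , drop = FALSE], q, k,
                   index$ids[cand], index$metric)
  sub$rank <- seq_len(nrow(sub))
  sub
}

#' Screen a list of queries against an index
#'
#' Batch evaluation with per-query results identical to [query_topk()]. When
#' both the index and the query set carry a model fingerprint they must
#' match: mixing embeddings from two different models is a hard error.
#'
#' @param index an `embedding_index` (e.g. over drugs)
#' @param queries matrix of query vectors (rows; rownames as ids) or output
#'   of [embed_entities()]'s `Zt`/`Zd`
#' @param k hits per query
#' @param query_ids optional ids (default rownames)
#' @param model_fingerprint fingerprint of the model that embedded the queries
#' @return data.frame `query_id`, `rank`, `hit_id`, `score`
#' @export
screen_matrix <- function(index, queries, k, query_ids = NULL,
                          model_fingerprint = NULL) {
  stopifnot(inherits(index, "embedding_index"))
  if (!is.null(model_fingerprint) && !is.null(index$model_fingerprint) &&
      !identical(model_fingerprint, index$model_fingerprint))
    stop_dti("model fingerprint mismatch between index and queries",
             "dti_integrity_error")
  queries <- as.matrix(queries)
  query_ids <- as.character(query_ids %||% rownames(queries) %||%
                              seq_len(nrow(queries)))
  out <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    hits <- query_topk(index, queries[i, ], k)
    if (nrow(hits))
      out[[i]] <- data.frame(query_id = query_ids[i], rank = hits$rank,
                             hit_id = hits$id, score = hits$score,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res %||% data.frame(query_id = character(0), rank = integer(0),
                      hit_id = character(0), score = numeric(0))
}

#' Persist an index to disk
#' @param index an `embedding_index`
#' @param path output path
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "embedding_index"))
  saveRDS(c(list(format = "dtiscreen_index", format_version = 1L),
            unclass(index)), path, version = 2)
  invisible(path)
}

#' Load an index saved by [save_index()]
#' @param path file path
#' @return an `embedding_index`
#' @export
load_index <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop_dti(sprintf("cannot read index '%s': %s", path, conditionMessage(e)),
             "dti_integrity_error"))
  if (!identical(obj$format, "dtiscreen_index"))
    stop_dti(sprintf("'%s' is not an index file", path), "dti_integrity_error")
  obj$format <- NULL; obj$format_version <- NULL
  structure(obj, class = "embedding_index")
}
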