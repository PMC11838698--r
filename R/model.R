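# The learnable core: multi-head attention pooling of per-residue embeddings,
# modality-specific projection MLPs Cd / Ct into a shared co-embedding space,
# and the two scoring heads:
#
#   classification:  P(Y=1 | Zd, Zt) = sigmoid(alpha * cos(Zd, Zt))
#   affinity:        pK_hat = Zd . Zt          (raw vectors, no sigmoid)
#
# alpha (default 5) saturates the sigmoid since the cosine lives in (-1, 1).

MODEL_FORMAT_VERSION <- 1L

#' Model configuration
#'
#' Collects every architectural and numerical choice so that two builds from
#' the same config and seed produce identical initial parameters, and so that
#' saved model files carry their full provenance.
#'
#' @param alpha positive scaling factor applied to the cosine before the
#'   sigmoid (default 5)
#' @param n_heads number of attention-pooling heads H (default 8)
#' @param d shared co-embedding width (default 256)
#' @param drug_depth,target_depth MLP depths for Cd / Ct, 1 or 3 (default 3)
#' @param dk,dv per-head key / value widths; default `max(4, E %/% H)` chosen
#'   at initialisation when NULL
#' @param head_merge "concat" (pooled width H*dv) or "mean" (width dv)
#' @param activation hidden activation, currently "relu"
#' @param dropout dropout rate on MLP hidden activations during training
#' @param seed weight-initialisation seed
#' @return an object of class `dti_model_config`
#' @export
model_config <- function(alpha = 5, n_heads = 8L, d = 256L,
                         drug_depth = 3L, target_depth = 3L,
                         dk = NULL, dv = NULL, head_merge = c("concat", "mean"),
                         activation = "relu", dropout = 0, seed = 0L) {
  head_merge <- match.arg(head_merge)
  if (!is_scalar_number(alpha) || alpha <= 0)
    stop_dti("alpha must be a positive number", "dti_config_error")
  if (!is_scalar_number(n_heads) || n_heads < 1)
    stop_dti("n_heads must be a positive integer", "dti_config_error")
  if (!drug_depth %in% c(1L, 3L) || !target_depth %in% c(1L, 3L))
    stop_dti("MLP depths must be 1 or 3", "dti_config_error")
  if (!identical(activation, "relu"))
    stop_dti("only 'relu' activation is implemented", "dti_config_error")
  if (!is_scalar_number(dropout) || dropout < 0 || dropout >= 1)
    stop_dti("dropout must be in [0, 1)", "dti_config_error")
  structure(list(alpha = alpha, n_heads = as.integer(n_heads), d = as.integer(d),
                 drug_depth = as.integer(drug_depth),
                 target_depth = as.integer(target_depth),
                 dk = if (is.null(dk)) NULL else as.integer(dk),
                 dv = if (is.null(dv)) NULL else as.integer(dv),
                 head_merge = head_merge, activation = activation,
                 dropout = dropout, seed = as.integer(seed)),
            class = "dti_model_config")
}

mlp_dims <- function(input, output, depth) {
  if (depth == 1L) return(c(input, output))
  hidden <- round(exp(seq(log(input), log(output), length.out = depth + 1L)))[2:depth]
  c(input, pmax(4L, as.integer(hidden)), output)
}

init_mlp <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]
    list(W = matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / fan_in)),
                    dims[l], dims[l + 1L]),
         b = numeric(dims[l + 1L]))
  })
}

#' Initialise a model
#'
#' Builds pooling parameters (per-head learned query, key/value projections)
#' and the two projection MLPs, with weights drawn from `config$seed`.
#'
#' @param config a [model_config()]
#' @param n_bits drug fingerprint length (Cd input width)
#' @param embed_dim per-residue embedding width E (pooling input width)
#' @return an object of class `dti_model`
#' @export
init_model <- function(config, n_bits, embed_dim) {
  stopifnot(inherits(config, "dti_model_config"))
  H <- config$n_heads
  dk <- config$dk %||% max(4L, as.integer(embed_dim) %/% H)
  dv <- config$dv %||% max(4L, as.integer(embed_dim) %/% H)
  config$dk <- dk; config$dv <- dv
  e_pool <- if (config$head_merge == "concat") H * dv else dv
  weights <- with_seed(config$seed, {
    w <- list(
      Wk = matrix(rnorm(embed_dim * H * dk, sd = 1 / sqrt(embed_dim)), embed_dim, H * dk),
      Wv = matrix(rnorm(embed_dim * H * dv, sd = 1 / sqrt(embed_dim)), embed_dim, H * dv),
      q  = matrix(rnorm(dk * H, sd = 1), dk, H)
    )
    w$drug_mlp <- init_mlp(mlp_dims(as.integer(n_bits), config$d, config$drug_depth))
    w$target_mlp <- init_mlp(mlp_dims(e_pool, config$d, config$target_depth))
    w
  })
  structure(list(format_version = MODEL_FORMAT_VERSION, config = config,
                 n_bits = as.integer(n_bits), embed_dim = as.integer(embed_dim),
                 e_pool = as.integer(e_pool), weights = weights),
            class = "dti_model")
}

relu <- function(x) (x + abs(x)) / 2

mlp_forward <- function(mlp, X, dropout = 0, dropout_masks = NULL) {
  acts <- list(X)
  nl <- length(mlp)
  for (l in seq_len(nl)) {
    Z <- acts[[l]] %*% mlp[[l]]$W
    Z <- sweep(Z, 2L, mlp[[l]]$b, "+")
    if (l < nl) {
      Z <- relu(Z)
      if (dropout > 0 && !is.null(dropout_masks))
        Z <- Z * dropout_masks[[l]]
    }
    acts[[l + 1L]] <- Z
  }
  acts
}

# Segment-wise softmax pooling over a stacked residue-embedding matrix.
# X: (sum L_i) x E; seg: integer segment id per row (1..n); returns per-head
# attention weights and the pooled matrix (n x e_pool).
pool_forward <- function(model, X, seg, n) {
  H <- model$config$n_heads; dk <- model$config$dk; dv <- model$config$dv
  W <- model$weights
  K <- X %*% W$Wk
  V <- X %*% W$Wv
  S <- matrix(0, nrow(X), H)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    S[, h] <- (K[, cols, drop = FALSE] %*% W$q[, h]) / sqrt(dk)
  }
  # stable softmax per segment
  mx <- apply_seg_max(S, seg, n)
  E_ <- exp(S - mx[seg, , drop = FALSE])
  denom <- rowsum(E_, seg, reorder = TRUE)
  A <- E_ / denom[seg, , drop = FALSE]
  pooled_heads <- vector("list", H)
  for (h in seq_len(H)) {
    colsv <- ((h - 1L) * dv + 1L):(h * dv)
    pooled_heads[[h]] <- rowsum(A[, h] * V[, colsv, drop = FALSE], seg, reorder = TRUE)
  }
  pooled <- if (model$config$head_merge == "concat") do.call(cbind, pooled_heads)
            else Reduce(`+`, pooled_heads) / H
  list(pooled = pooled, A = A, K = K, V = V)
}

apply_seg_max <- function(S, seg, n) {
  out <- matrix(-Inf, n, ncol(S))
  for (h in seq_len(ncol(S))) {
    o <- order(seg, S[, h])
    # last element of each run of seg in sorted order is the max
    last <- c(diff(seg[o]) != 0L, TRUE)
    out[seg[o][last], h] <- S[o, h][last]
  }
  out
}

#' Attention-pool a residue embedding matrix
#'
#' Each head holds a learned query; keys and values are linear projections of
#' the residue embeddings. Softmax attention over residues yields per-head
#' weights (each row summing to 1) and the pooled vector is the concatenation
#' (or mean, per config) of the per-head attention-weighted value sums.
#'
#' @param embeddings an L x E matrix (e.g. from [embed_residues()])
#' @param model a `dti_model`
#' @return list with `pooled` (length `e_pool` vector) and `attention`
#'   (H x L matrix, class `attention_map`, rows summing to 1)
#' @export
attention_pool <- function(embeddings, model) {
  stopifnot(inherits(model, "dti_model"))
  X <- unclass(embeddings)
  if (!is.matrix(X) || nrow(X) < 1L)
    stop_dti("embeddings must be a matrix with at least one row", "dti_input_error")
  if (ncol(X) != model$embed_dim)
    stop_dti(sprintf("embedding width %d != model embed_dim %d",
                     ncol(X), model$embed_dim), "dti_input_error")
  fw <- pool_forward(model, X, rep(1L, nrow(X)), 1L)
  attention <- t(fw$A)
  attr(attention, "target_id") <- attr(embeddings, "target_id")
  class(attention) <- c("attention_map", "matrix", "array")
  list(pooled = as.numeric(fw$pooled[1L, ]), attention = attention)
}

co_vector <- function(z) {
  if (inherits(z, "co_embedding")) z$vector else as.numeric(z)
}

#' Project a drug fingerprint into the co-embedding space
#' @param fp 0/1 fingerprint vector of length `model$n_bits`
#' @param model a `dti_model`
#' @param owner_id optional identifier carried on the result
#' @return a `co_embedding` (length-d vector Zd, unnormalized)
#' @export
co_embed_drug <- function(fp, model, owner_id = NA_character_) {
  fp <- as.numeric(fp)
  if (length(fp) != model$n_bits)
    stop_dti(sprintf("fingerprint width %d != expected %d", length(fp), model$n_bits),
             "dti_input_error")
  out <- mlp_forward(model$weights$drug_mlp, matrix(fp, 1L))
  co_embedding(as.numeric(out[[length(out)]]), owner_id)
}

#' Project a pooled target representation into the co-embedding space
#' @param pooled pooled vector of width `model$e_pool` (or an L x E residue
#'   embedding matrix, which is attention-pooled first)
#' @param model a `dti_model`
#' @param owner_id optional identifier carried on the result
#' @return a `co_embedding` (length-d vector Zt, unnormalized)
#' @export
co_embed_target <- function(pooled, model, owner_id = NA_character_) {
  if (is.matrix(pooled)) pooled <- attention_pool(pooled, model)$pooled
  pooled <- as.numeric(pooled)
  if (length(pooled) != model$e_pool)
    stop_dti(sprintf("pooled width %d != expected %d", length(pooled), model$e_pool),
             "dti_input_error")
  out <- mlp_forward(model$weights$target_mlp, matrix(pooled, 1L))
  co_embedding(as.numeric(out[[length(out)]]), owner_id)
}

#' Construct a co-embedding vector
#' @param vector numeric latent vector
#' @param owner_id identifier of the drug or target it represents
#' @param normalize if TRUE the vector is scaled to unit Euclidean norm
#' @return an object of class `co_embedding`
#' @export
co_embedding <- function(vector, owner_id = NA_character_, normalize = FALSE) {
  vector <- as.numeric(vector)
  if (normalize) {
    nrm <- sqrt(sum(vector^2))
    if (nrm == 0) stop_dti("cannot normalize a zero vector", "dti_input_error")
    vector <- vector / nrm
  }
  structure(list(owner_id = owner_id, vector = vector, normalized = normalize),
            class = "co_embedding")
}

#' Interaction probability from two co-embeddings
#'
#' The classification head: `sigmoid(alpha * cos(Zd, Zt))`. Invariant to
#' positive rescaling of either vector and strictly increasing in the cosine;
#' for the default alpha = 5 all probabilities lie in
#' [sigmoid(-5), sigmoid(5)] ~ [0.0067, 0.9933].
#'
#' @param zd,zt co-embeddings (`co_embedding` objects or plain numeric vectors)
#' @param alpha positive scaling factor (default 5)
#' @return probability in (0, 1)
#' @export
interaction_probability <- function(zd, zt, alpha = 5) {
  u <- co_vector(zd); v <- co_vector(zt)
  if (length(u) != length(v))
    stop_dti(sprintf("co-embedding widths differ: %d vs %d", length(u), length(v)),
             "dti_input_error")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop_dti("cosine undefined for a zero vector", "dti_input_error")
  plogis(alpha * sum(u * v) / (nu * nv))
}

#' Predicted binding affinity (pK) from two co-embeddings
#'
#' The regression head: the raw dot product `Zd . Zt` (no normalization, no
#' sigmoid), predicting pK = -log10(Kd). Bilinear in its arguments.
#'
#' @param zd,zt co-embeddings (unnormalized)
#' @return predicted pK (real)
#' @export
predict_affinity <- function(zd, zt) {
  u <- co_vector(zd); v <- co_vector(zt)
  if (length(u) != length(v))
    stop_dti(sprintf("co-embedding widths differ: %d vs %d", length(u), length(v)),
             "dti_input_error")
  sum(u * v)
}

#' Binary cross-entropy loss
#' @param probabilities predicted probabilities in (0, 1)
#' @param labels 0/1 labels, same length
#' @param eps clipping applied to probabilities to avoid log(0) (default 1e-7)
#' @return mean negative log-likelihood
#' @export
bce_loss <- function(probabilities, labels, eps = 1e-7) {
  if (length(probabilities) != length(labels))
    stop_dti(sprintf("length mismatch: %d probabilities vs %d labels",
                     length(probabilities), length(labels)), "dti_input_error")
  if (!all(labels %in% c(0, 1)))
    stop_dti("labels must be 0 or 1", "dti_input_error")
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Mean squared error loss
#' @param predicted,observed numeric vectors of equal length
#' @return mean of squared differences
#' @export
mse_loss <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop_dti(sprintf("length mismatch: %d predicted vs %d observed",
                     length(predicted), length(observed)), "dti_input_error")
  mean((predicted - observed)^2)
}

#' Save a model to disk
#'
#' Writes a versioned container holding the full config and all named weight
#' arrays; [load_model()] round-trips scores bitwise.
#'
#' @param model a `dti_model`
#' @param path output file path
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dti_model"))
  saveRDS(list(format = "dtiscreen_model", format_version = model$format_version,
               config = unclass(model$config), n_bits = model$n_bits,
               embed_dim = model$embed_dim, e_pool = model$e_pool,
               weights = model$weights,
               package_version = as.character(utils::packageVersion("dtiscreen"))),
          path, version = 2)
  invisible(path)
}

#' Load a model from disk
#' @param path file written by [save_model()]
#' @return a `dti_model`
#' @export
load_model <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop_dti(sprintf("cannot read model file '%s': %s (corrupt or truncated?)",
                     path, conditionMessage(e)), "dti_integrity_error"))
  if (!is.list(obj) || !identical(obj$format, "dtiscreen_model"))
    stop_dti(sprintf("'%s' is not a model file", path), "dti_integrity_error")
  if (!identical(as.integer(obj$format_version), MODEL_FORMAT_VERSION))
    stop_dti(sprintf("model format version %s, this package reads version %d",
                     obj$format_version %||% "<missing>", MODEL_FORMAT_VERSION),
             "dti_integrity_error")
  required <- c("alpha", "n_heads", "d", "head_merge", "seed")
  missing <- setdiff(required, names(obj$config))
  if (length(missing))
    stop_dti(sprintf("model file '%s' lacks config fields: %s",
                     path, paste(missing, collapse = ", ")), "dti_integrity_error")
  structure(list(format_version = as.integer(obj$format_version),
                 config = structure(obj$config, class = "dti_model_config"),
                 n_bits = obj$n_bits, embed_dim = obj$embed_dim,
                 e_pool = obj$e_pool, weights = obj$weights),
            class = "dti_model")
}

#' Content fingerprint of a model's weights
#'
#' Used to verify that both sides of a screen were embedded with the same
#' model.
#' @param model a `dti_model`
#' @return a short string checksum
#' @export
model_fingerprint <- function(model) {
  object_checksum(list(model$config, model$weights))
}
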