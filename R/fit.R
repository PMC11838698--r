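# Training engine: analytic gradients through the scoring heads, the
# projection MLPs and the attention-pooling layer, an Adam optimizer, and the
# checkpoint-best fitting loop.
#
# All entity embeddings in a batch are computed in one pass: drugs as one
# fingerprint matrix through Cd, targets as one stacked residue matrix with
# segment-wise softmax through the pooling layer and Ct. Pair gradients are
# scattered back onto entities with rowsum().

#' Assemble model-ready features for a set of drugs and targets
#'
#' Computes (or collects) fingerprints into one matrix and per-residue
#' embeddings into one stacked matrix with segment bookkeeping, which is the
#' input format [fit()], [predict_pairs()] and [embed_entities()] consume.
#'
#' @param drugs list of [drug_record()] objects
#' @param targets list of [target_record()] objects
#' @param provider embedding provider name (default "toy")
#' @return an object of class `dti_features`
#' @export
assemble_features <- function(drugs, targets, provider = "toy") {
  if (!length(drugs) || !length(targets))
    stop_dti("need at least one drug and one target", "dti_input_error")
  fp <- do.call(rbind, lapply(drugs, function(d) d$fingerprint))
  rownames(fp) <- vapply(drugs, function(d) d$drug_id, "")
  if (anyDuplicated(rownames(fp)))
    stop_dti("duplicate drug ids", "dti_input_error")
  embs <- lapply(targets, embed_residues, provider = provider)
  lens <- vapply(embs, nrow, 0L)
  X <- do.call(rbind, lapply(embs, unclass))
  target_ids <- vapply(targets, function(t) t$target_id, "")
  if (anyDuplicated(target_ids))
    stop_dti("duplicate target ids", "dti_input_error")
  structure(list(fp = fp, X = X, lens = lens,
                 ends = cumsum(lens), starts = cumsum(lens) - lens + 1L,
                 target_ids = target_ids, drug_ids = rownames(fp),
                 embed_dim = ncol(X), n_bits = ncol(fp), provider = provider),
            class = "dti_features")
}

# rows of the stacked matrix belonging to a subset of targets, plus local seg ids
target_rows <- function(features, tidx) {
  idx <- unlist(lapply(tidx, function(i) features$starts[i]:features$ends[i]),
                use.names = FALSE)
  seg <- rep(seq_along(tidx), features$lens[tidx])
  list(idx = idx, seg = seg)
}

flatten_weights <- function(w) {
  out <- list(Wk = w$Wk, Wv = w$Wv, q = w$q)
  for (l in seq_along(w$drug_mlp)) {
    out[[paste0("d", l, "W")]] <- w$drug_mlp[[l]]$W
    out[[paste0("d", l, "b")]] <- w$drug_mlp[[l]]$b
  }
  for (l in seq_along(w$target_mlp)) {
    out[[paste0("t", l, "W")]] <- w$target_mlp[[l]]$W
    out[[paste0("t", l, "b")]] <- w$target_mlp[[l]]$b
  }
  out
}

unflatten_weights <- function(flat, template) {
  w <- template
  w$Wk <- flat$Wk; w$Wv <- flat$Wv; w$q <- flat$q
  for (l in seq_along(w$drug_mlp)) {
    w$drug_mlp[[l]]$W <- flat[[paste0("d", l, "W")]]
    w$drug_mlp[[l]]$b <- flat[[paste0("d", l, "b")]]
  }
  for (l in seq_along(w$target_mlp)) {
    w$target_mlp[[l]]$W <- flat[[paste0("t", l, "W")]]
    w$target_mlp[[l]]$b <- flat[[paste0("t", l, "b")]]
  }
  w
}

mlp_backward <- function(mlp, acts, dOut, dropout_masks = NULL) {
  nl <- length(mlp)
  grads <- vector("list", nl)
  g <- dOut
  for (l in rev(seq_len(nl))) {
    if (l < nl) {
      if (!is.null(dropout_masks)) g <- g * dropout_masks[[l]]
      g <- g * (acts[[l + 1L]] > 0)
    }
    grads[[l]] <- list(W = crossprod(acts[[l]], g), b = colSums(g))
    if (l > 1L) g <- g %*% t(mlp[[l]]$W)
  }
  list(grads = grads, dInput = if (nl >= 1L) g %*% t(mlp[[1L]]$W) else dOut)
}

# Forward + loss + gradients for one batch. FP: nd x nb (batch drugs),
# X/seg: stacked residues for the nt batch targets, pairs_d/pairs_t: local
# 1-based indices per pair, y: labels (0/1 or pK).
loss_and_grads <- function(model, FP, X, seg, nt, pairs_d, pairs_t, y, task,
                           dropout_masks = NULL) {
  cfg <- model$config
  W <- model$weights
  np <- length(y)
  acts_d <- mlp_forward(W$drug_mlp, FP, cfg$dropout, dropout_masks$drug)
  Zd <- acts_d[[length(acts_d)]]
  pf <- pool_forward(model, X, seg, nt)
  acts_t <- mlp_forward(W$target_mlp, pf$pooled, cfg$dropout, dropout_masks$target)
  Zt <- acts_t[[length(acts_t)]]

  u <- Zd[pairs_d, , drop = FALSE]
  v <- Zt[pairs_t, , drop = FALSE]
  dot <- rowSums(u * v)

  if (task == "classify") {
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    if (any(nu == 0) || any(nv == 0))
      stop_dti("zero-norm co-embedding in batch (cosine undefined)", "dti_numeric_error")
    cosv <- dot / (nu * nv)
    z <- cfg$alpha * cosv
    p <- plogis(z)
    loss <- bce_loss(p, y)
    dz <- (p - y) / np
    dc <- cfg$alpha * dz
    du <- dc * (v / (nu * nv) - (dot / (nu^3 * nv)) * u)
    dv <- dc * (u / (nu * nv) - (dot / (nu * nv^3)) * v)
    preds <- p
  } else {
    loss <- mean((dot - y)^2)
    dyh <- 2 * (dot - y) / np
    du <- dyh * v
    dv <- dyh * u
    preds <- dot
  }
  if (!is.finite(loss))
    stop_dti(sprintf(
      "non-finite loss in batch of %d pairs (first pair drug=%d target=%d)",
      np, pairs_d[1L], pairs_t[1L]), "dti_numeric_error")

  dZd <- matrix(0, nrow(Zd), ncol(Zd))
  agg_d <- rowsum(du, pairs_d, reorder = TRUE)
  dZd[as.integer(rownames(agg_d)), ] <- agg_d
  dZt <- matrix(0, nrow(Zt), ncol(Zt))
  agg_t <- rowsum(dv, pairs_t, reorder = TRUE)
  dZt[as.integer(rownames(agg_t)), ] <- agg_t

  bd <- mlp_backward(W$drug_mlp, acts_d, dZd, dropout_masks$drug)
  bt <- mlp_backward(W$target_mlp, acts_t, dZt, dropout_masks$target)
  dpooled <- bt$dInput

  H <- cfg$n_heads; dk <- cfg$dk; dv_w <- cfg$dv
  A <- pf$A; K <- pf$K; V <- pf$V
  dV <- matrix(0, nrow(X), H * dv_w)
  dK <- matrix(0, nrow(X), H * dk)
  dq <- matrix(0, dk, H)
  for (h in seq_len(H)) {
    colsv <- ((h - 1L) * dv_w + 1L):(h * dv_w)
    colsk <- ((h - 1L) * dk + 1L):(h * dk)
    dP_h <- if (cfg$head_merge == "concat") dpooled[, colsv, drop = FALSE]
            else dpooled / H
    gp <- dP_h[seg, , drop = FALSE]
    dV[, colsv] <- A[, h] * gp
    a <- rowSums(V[, colsv, drop = FALSE] * gp)
    abar <- rowsum(A[, h] * a, seg, reorder = TRUE)[seg]
    ds <- A[, h] * (a - abar) / sqrt(dk)
    dq[, h] <- crossprod(K[, colsk, drop = FALSE], ds)
    dK[, colsk] <- tcrossprod(ds, W$q[, h])
  }
  grads <- list(Wk = crossprod(X, dK), Wv = crossprod(X, dV), q = dq)
  for (l in seq_along(bd$grads)) {
    grads[[paste0("d", l, "W")]] <- bd$grads[[l]]$W
    grads[[paste0("d", l, "b")]] <- bd$grads[[l]]$b
  }
  for (l in seq_along(bt$grads)) {
    grads[[paste0("t", l, "W")]] <- bt$grads[[l]]$W
    grads[[paste0("t", l, "b")]] <- bt$grads[[l]]$b
  }
  list(loss = loss, preds = preds, grads = grads)
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0), v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-4)
#' @param batch_size pairs per gradient step; `Inf` for full batch (default 256)
#' @param epochs maximum epochs (default 50)
#' @param patience early-stopping patience on the validation metric (default 10)
#' @param seed RNG seed for shuffling, balancing and dropout (default 0)
#' @param balance if TRUE, subsample the training split to equal positive and
#'   negative counts (classification only; default FALSE)
#' @param lr_decay multiplicative learning-rate decay applied when the
#'   validation metric has not improved for `lr_patience` epochs
#'   (reduce-on-plateau; default 1 = off)
#' @param lr_patience plateau length in epochs before decaying (default 20)
#' @param verbose print per-epoch progress
#' @return an object of class `dti_fit_config`
#' @export
fit_config <- function(lr = 1e-4, batch_size = 256L, epochs = 50L,
                       patience = 10L, seed = 0L, balance = FALSE,
                       lr_decay = 1, lr_patience = 20L, verbose = FALSE) {
  structure(list(lr = lr, batch_size = batch_size, epochs = as.integer(epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 balance = balance, lr_decay = lr_decay,
                 lr_patience = as.integer(lr_patience), verbose = isTRUE(verbose)),
            class = "dti_fit_config")
}

pairs_to_indices <- function(features, pairs) {
  di <- match(pairs$drug_id, features$drug_ids)
  ti <- match(pairs$target_id, features$target_ids)
  if (anyNA(di)) stop_dti(sprintf("unknown drug id '%s' in interaction table",
                                  pairs$drug_id[which(is.na(di))[1L]]), "dti_input_error")
  if (anyNA(ti)) stop_dti(sprintf("unknown target id '%s' in interaction table",
                                  pairs$target_id[which(is.na(ti))[1L]]), "dti_input_error")
  list(di = di, ti = ti)
}

label_column <- function(pairs, task) {
  col <- if (task == "classify") {
    if ("label" %in% names(pairs)) "label" else
      stop_dti("interaction table needs a 'label' column for classification",
               "dti_input_error")
  } else {
    if ("pK" %in% names(pairs)) "pK" else
      stop_dti("interaction table needs a 'pK' column for regression",
               "dti_input_error")
  }
  as.numeric(pairs[[col]])
}

#' Predict scores for drug-target pairs
#'
#' @param model a `dti_model`
#' @param features a `dti_features` (see [assemble_features()])
#' @param pairs data.frame with `drug_id`, `target_id`
#' @param task "classify" (interaction probabilities) or "regress" (pK)
#' @return numeric vector of scores, one per pair
#' @export
predict_pairs <- function(model, features, pairs,
                          task = c("classify", "regress")) {
  task <- match.arg(task)
  emb <- embed_entities(model, features)
  ix <- pairs_to_indices(features, pairs)
  u <- emb$Zd[ix$di, , drop = FALSE]
  v <- emb$Zt[ix$ti, , drop = FALSE]
  dot <- rowSums(u * v)
  if (task == "classify") {
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    plogis(model$config$alpha * dot / (nu * nv))
  } else dot
}

#' Co-embed every drug and target in a feature set
#'
#' @param model a `dti_model`
#' @param features a `dti_features`
#' @return list with matrices `Zd` (drugs x d) and `Zt` (targets x d), row
#'   names carrying the entity ids, plus the model fingerprint
#' @export
embed_entities <- function(model, features) {
  if (ncol(features$fp) != model$n_bits)
    stop_dti(sprintf("fingerprint width %d != model n_bits %d",
                     ncol(features$fp), model$n_bits), "dti_input_error")
  if (features$embed_dim != model$embed_dim)
    stop_dti(sprintf("embedding width %d != model embed_dim %d",
                     features$embed_dim, model$embed_dim), "dti_input_error")
  acts_d <- mlp_forward(model$weights$drug_mlp, features$fp)
  Zd <- acts_d[[length(acts_d)]]
  rownames(Zd) <- features$drug_ids
  seg <- rep(seq_along(features$lens), features$lens)
  pf <- pool_forward(model, features$X, seg, length(features$lens))
  acts_t <- mlp_forward(model$weights$target_mlp, pf$pooled)
  Zt <- acts_t[[length(acts_t)]]
  rownames(Zt) <- features$target_ids
  list(Zd = Zd, Zt = Zt, fingerprint = model_fingerprint(model))
}

#' Fit the co-embedding model
#'
#' Minibatch Adam on binary cross-entropy (classification head) or mean
#' squared error (affinity head). Per epoch the validation split is scored;
#' the returned model carries the weights of the best validation epoch
#' (AUPR for classification, MSE for regression), not the last. Fully
#' reproducible given the config seed.
#'
#' @param model a `dti_model` (initial weights)
#' @param features a `dti_features` covering every referenced entity
#' @param train,val interaction data.frames (`drug_id`, `target_id`, and
#'   `label` or `pK`)
#' @param task "classify" or "regress"
#' @param config a [fit_config()]
#' @return list with `model` (best checkpoint), `history` (per-epoch
#'   data.frame), `best_epoch`, `best_metric`
#' @export
fit <- function(model, features, train, val, task = c("classify", "regress"),
                config = fit_config()) {
  task <- match.arg(task)
  stopifnot(inherits(model, "dti_model"), inherits(features, "dti_features"))
  if (!nrow(train)) stop_dti("empty training set", "dti_input_error")
  y_train <- label_column(train, task)
  y_val <- label_column(val, task)
  if (task == "classify" && !all(y_train %in% c(0, 1)))
    stop_dti("classification labels must be 0/1", "dti_input_error")
  ix <- pairs_to_indices(features, train)
  di <- ix$di; ti <- ix$ti

  with_seed(derive_seed(config$seed, "fit"), {
    if (config$balance && task == "classify") {
      pos <- which(y_train == 1); neg <- which(y_train == 0)
      n <- min(length(pos), length(neg))
      keep <- c(sample(pos, n), sample(neg, n))
      di <- di[keep]; ti <- ti[keep]; y_train <- y_train[keep]
    }
    np <- length(y_train)
    bs <- if (is.finite(config$batch_size)) min(config$batch_size, np) else np
    flat <- flatten_weights(model$weights)
    state <- adam_init(flat)
    best_flat <- flat
    best_metric <- -Inf
    best_epoch <- 0L
    wait <- 0L
    lr_wait <- 0L
    lr <- config$lr
    history <- vector("list", config$epochs)
    full_seg <- rep(seq_along(features$lens), features$lens)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(np)
      nb <- ceiling(np / bs)
      epoch_loss <- 0
      for (b in seq_len(nb)) {
        sel <- ord[((b - 1L) * bs + 1L):min(b * bs, np)]
        bd <- di[sel]; bt <- ti[sel]; by <- y_train[sel]
        ud <- sort(unique(bd)); ut <- sort(unique(bt))
        FPb <- features$fp[ud, , drop = FALSE]
        tr <- target_rows(features, ut)
        masks <- NULL
        if (model$config$dropout > 0) {
          keep <- 1 - model$config$dropout
          mk <- function(mlp, nr) lapply(
            seq_len(length(mlp) - 1L), function(l)
              matrix(rbinom(nr * ncol(mlp[[l]]$W), 1, keep) / keep,
                     nr, ncol(mlp[[l]]$W)))
          masks <- list(drug = mk(model$weights$drug_mlp, length(ud)),
                        target = mk(model$weights$target_mlp, length(ut)))
        }
        model$weights <- unflatten_weights(flat, model$weights)
        lg <- loss_and_grads(model, FPb, features$X[tr$idx, , drop = FALSE],
                             tr$seg, length(ut),
                             match(bd, ud), match(bt, ut), by, task, masks)
        epoch_loss <- epoch_loss + lg$loss * length(sel)
        upd <- adam_step(flat, lg$grads, state, lr)
        flat <- upd$flat; state <- upd$state
      }
      model$weights <- unflatten_weights(flat, model$weights)
      val_pred <- predict_pairs(model, features, val, task)
      if (task == "classify") {
        val_loss <- bce_loss(val_pred, y_val)
        metric <- if (length(unique(y_val)) > 1L) auprc(val_pred, y_val) else NA_real_
      } else {
        val_loss <- mse_loss(val_pred, y_val)
        metric <- -val_loss
      }
      history[[epoch]] <- data.frame(
        epoch = epoch, train_loss = epoch_loss / np,
        val_loss = val_loss, val_metric = metric)
      if (config$verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  metric %.4f",
                        epoch, epoch_loss / np, val_loss, metric))
      if (!is.na(metric) && metric > best_metric) {
        best_metric <- metric
        best_flat <- flat
        best_epoch <- epoch
        wait <- 0L
        lr_wait <- 0L
      } else {
        wait <- wait + 1L
        lr_wait <- lr_wait + 1L
        if (wait >= config$patience) break
        if (config$lr_decay < 1 && lr_wait >= config$lr_patience) {
          lr <- lr * config$lr_decay
          lr_wait <- 0L
          if (config$verbose) message(sprintf("  lr -> %.2e", lr))
        }
      }
    }
    model$weights <- unflatten_weights(best_flat, model$weights)
    list(model = model, history = do.call(rbind, history),
         best_epoch = best_epoch, best_metric = best_metric)
  })
}
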