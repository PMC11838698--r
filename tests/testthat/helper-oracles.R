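# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package code paths they check.

# AUROC by exhaustive pair counting (ties = 1/2)
ref_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# AUPR by direct threshold enumeration: at each distinct score, count
# TP/FP with >= threshold and accumulate (delta TP / n_pos) * precision.
ref_ap <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  prev_tp <- 0
  area <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel])
    fp <- sum(sel) - tp
    area <- area + (tp - prev_tp) / n_pos * tp / (tp + fp)
    prev_tp <- tp
  }
  area
}

# BEDROC evaluated directly from the closed form on 1-based active ranks
ref_bedroc <- function(ranks, N, n, alpha) {
  denom <- n * (1 - exp(-alpha)) / (N * (exp(alpha / N) - 1))
  rie <- function(r) sum(exp(-alpha * r / N)) / denom
  (rie(ranks) - rie((N - n + 1):N)) / (rie(1:n) - rie((N - n + 1):N))
}

# full-scan top-k oracle (cosine), ties by input order
ref_topk <- function(vectors, query, k) {
  vn <- vectors / sqrt(rowSums(vectors^2))
  qn <- query / sqrt(sum(query^2))
  s <- as.numeric(vn %*% qn)
  order(-s, seq_along(s))[seq_len(min(k, length(s)))]
}

# random valid SMILES from a small fragment grammar
rand_smiles <- function(n, seed = 1) {
  frags <- c("C", "CC", "CO", "CN", "C(=O)O", "CCO", "c1ccccc1", "C(C)C",
             "CS", "CCl", "C(=O)N", "CBr")
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(frags, sample(2:4, 1), replace = TRUE), collapse = ""), "")
}
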