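# Dataset assembly machinery: Kd thresholding, uniform negative sampling,
# a k-mer containment identity estimator, and split construction (random,
# unseen-drug, unseen-target, homology-aware) with a brute-force audit.

#' Binary interaction label from a dissociation constant
#'
#' Kd strictly below the threshold is interacting (1); Kd at or above it is
#' non-interacting (0). The threshold is interpreted in the dataset's native
#' units (nM for the usual Kd benchmarks) and defaults to 30.
#'
#' @param kd positive dissociation constant(s)
#' @param threshold positive threshold (default 30)
#' @return integer 0/1 vector
#' @export
label_from_kd <- function(kd, threshold = 30) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop_dti("Kd must be positive and finite", "dti_input_error")
  if (!is_scalar_number(threshold) || threshold <= 0)
    stop_dti("threshold must be positive", "dti_config_error")
  as.integer(kd < threshold)
}

#' Sample negative drug-target pairs
#'
#' Draws `floor(ratio * n_positives)` pairs uniformly without replacement
#' from (drugs x targets) minus the positive set. Deterministic given the
#' seed.
#'
#' @param positives data.frame with `drug_id`, `target_id` (the known pairs)
#' @param drugs,targets id vectors defining the sampling universe
#' @param ratio negatives per positive (default 1)
#' @param seed RNG seed
#' @return data.frame `drug_id`, `target_id`, `label = 0`,
#'   `source = "sampled_negative"`
#' @export
sample_negatives <- function(positives, drugs, targets, ratio = 1, seed = 0L) {
  drugs <- as.character(drugs); targets <- as.character(targets)
  nd <- length(drugs); nt <- length(targets)
  di <- match(positives$drug_id, drugs)
  ti <- match(positives$target_id, targets)
  if (anyNA(di) || anyNA(ti))
    stop_dti("positives reference ids outside the drug/target universe",
             "dti_input_error")
  pos_lin <- unique((di - 1) * nt + ti)   # 1-based linear codes
  want <- floor(ratio * nrow(positives))
  avail <- nd * nt - length(pos_lin)
  if (want > avail)
    stop_dti(sprintf(
      "requested %d negatives but only %d non-positive pairs exist (%d x %d universe, %d positives)",
      want, avail, nd, nt, length(pos_lin)), "dti_input_error")
  lin <- with_seed(derive_seed(seed, "negatives"), {
    if (nd * nt <= 2e6) {
      universe <- setdiff(seq_len(nd * nt), pos_lin)
      sample(universe, want)
    } else {
      picked <- integer(0)
      taken <- pos_lin
      while (length(picked) < want) {
        cand <- unique(sample.int(nd * nt, 2L * (want - length(picked))))
        cand <- setdiff(cand, taken)
        picked <- c(picked, cand)
        taken <- c(taken, cand)
      }
      picked[seq_len(want)]
    }
  })
  data.frame(drug_id = drugs[(lin - 1) %/% nt + 1],
             target_id = targets[(lin - 1) %% nt + 1],
             label = 0L, source = "sampled_negative",
             stringsAsFactors = FALSE)
}

#' k-mer containment identity between two sequences
#'
#' Shared distinct k-mers divided by the distinct k-mers of the shorter
#' sequence: a fast stand-in for alignment-based percent identity used by the
#' homology-aware splitter, symmetric in its arguments.
#'
#' @param seq_a,seq_b sequences (length >= k)
#' @param k k-mer size (default 5)
#' @return fraction in [0, 1]
#' @export
estimate_identity <- function(seq_a, seq_b, k = 5L) {
  if (nchar(seq_a) < k || nchar(seq_b) < k)
    stop_dti(sprintf("sequences must be at least k = %d long", k), "dti_input_error")
  kmers <- function(s) unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  ka <- kmers(seq_a); kb <- kmers(seq_b)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Split specification
#'
#' @param mode "random", "unseen_drug", "unseen_target" or "homology"
#' @param fractions train/val/test fractions summing to 1 (default 70/10/20)
#' @param identity_thresholds homology mode: maximum allowed identity for
#'   (train-val, train-test) target pairs, default c(0.90, 0.70)
#' @param k k-mer size for the identity estimator
#' @param seed RNG seed
#' @return an object of class `split_spec`
#' @export
split_spec <- function(mode = c("random", "unseen_drug", "unseen_target", "homology"),
                       fractions = c(0.7, 0.1, 0.2),
                       identity_thresholds = c(0.90, 0.70), k = 5L, seed = 0L) {
  mode <- match.arg(mode)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0))
    stop_dti("fractions must be three non-negative numbers summing to 1",
             "dti_config_error")
  if (any(identity_thresholds <= 0) || any(identity_thresholds > 1))
    stop_dti("identity thresholds must lie in (0, 1]", "dti_config_error")
  structure(list(mode = mode, fractions = fractions,
                 identity_thresholds = identity_thresholds,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "split_spec")
}

# union-find single-linkage clustering of sequences at an identity threshold:
# any pair with identity > threshold is linked.
identity_clusters <- function(seqs, threshold, k) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (estimate_identity(seqs[i], seqs[j], k) > threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' Partition interaction records into train/validation/test
#'
#' Modes: `random` splits records by the stated fractions; `unseen_drug` /
#' `unseen_target` sample entities (not records) so that no entity appears on
#' both sides; `homology` single-linkage clusters targets at the train-test
#' identity threshold, assigns whole clusters to the test side, then
#' re-clusters the remainder at the train-val threshold. Every produced split
#' is audited by brute force ([audit_split()]); an audit failure is a hard
#' error, not a warning.
#'
#' @param records data.frame with `drug_id`, `target_id` (plus label columns)
#' @param spec a [split_spec()]
#' @param target_seqs named character vector (id -> sequence); required for
#'   homology mode
#' @return list of integer record-index vectors `train`, `val`, `test`
#' @export
make_splits <- function(records, spec, target_seqs = NULL) {
  stopifnot(inherits(spec, "split_spec"))
  n <- nrow(records)
  if (!n) stop_dti("no records to split", "dti_input_error")
  fr <- spec$fractions
  out <- with_seed(derive_seed(spec$seed, paste0("split_", spec$mode)), {
    if (spec$mode == "random") {
      o <- sample.int(n)
      n_train <- round(fr[1] * n)
      n_val <- round(fr[2] * n)
      list(train = sort(o[seq_len(n_train)]),
           val = sort(o[n_train + seq_len(n_val)]),
           test = sort(o[(n_train + n_val + 1L):n]))
    } else if (spec$mode %in% c("unseen_drug", "unseen_target")) {
      col <- if (spec$mode == "unseen_drug") "drug_id" else "target_id"
      ents <- unique(records[[col]])
      ne <- length(ents)
      o <- sample(ents)
      n_test <- max(1L, round(fr[3] * ne))
      n_val <- max(1L, round(fr[2] * ne))
      test_e <- o[seq_len(n_test)]
      val_e <- o[n_test + seq_len(n_val)]
      grp <- ifelse(records[[col]] %in% test_e, "test",
                    ifelse(records[[col]] %in% val_e, "val", "train"))
      list(train = which(grp == "train"), val = which(grp == "val"),
           test = which(grp == "test"))
    } else {
      if (is.null(target_seqs))
        stop_dti("homology mode requires target_seqs", "dti_config_error")
      tids <- unique(records$target_id)
      if (!all(tids %in% names(target_seqs)))
        stop_dti("target_seqs must cover every target in records", "dti_input_error")
      seqs <- target_seqs[tids]
      counts <- table(records$target_id)[tids]
      # clusters at the looser (train-test) bound; assign whole clusters
      cl_test <- identity_clusters(seqs, spec$identity_thresholds[2], spec$k)
      cl_ids <- sample(unique(cl_test))
      csize <- vapply(cl_ids, function(c) sum(counts[cl_test == c]), 0)
      take <- cumsum(csize) <= max(min(csize), fr[3] * n) | seq_along(cl_ids) == 1L
      test_t <- tids[cl_test %in% cl_ids[take]]
      rest_t <- setdiff(tids, test_t)
      # re-cluster the remainder at the (train-val) bound
      cl_val <- identity_clusters(target_seqs[rest_t], spec$identity_thresholds[1], spec$k)
      vids <- sample(unique(cl_val))
      vsize <- vapply(vids, function(c) sum(counts[rest_t][cl_val == c]), 0)
      takev <- cumsum(vsize) <= max(min(vsize), fr[2] * n) | seq_along(vids) == 1L
      val_t <- rest_t[cl_val %in% vids[takev]]
      train_t <- setdiff(rest_t, val_t)
      list(train = which(records$target_id %in% train_t),
           val = which(records$target_id %in% val_t),
           test = which(records$target_id %in% test_t))
    }
  })
  audit_split(records, out, spec, target_seqs)
  out
}

#' Verify a split's guarantee by brute force
#'
#' Checks disjoint, exhaustive cover of the records for every mode; entity
#' disjointness for unseen-drug/unseen-target; and, for homology mode, that
#' every train-val target pair has estimated identity at or below the first
#' threshold and every train-test pair at or below the second. Violations
#' raise a hard error.
#'
#' @param records the record table the split indexes into
#' @param splits list with `train`, `val`, `test` index vectors
#' @param spec the [split_spec()] used
#' @param target_seqs named sequences (homology mode)
#' @return TRUE, invisibly
#' @export
audit_split <- function(records, splits, spec, target_seqs = NULL) {
  all_idx <- sort(c(splits$train, splits$val, splits$test))
  if (!identical(all_idx, seq_len(nrow(records))))
    stop_dti("split audit failed: not a disjoint exhaustive cover", "dti_audit_error")
  if (spec$mode %in% c("unseen_drug", "unseen_target")) {
    col <- if (spec$mode == "unseen_drug") "drug_id" else "target_id"
    tr <- unique(records[[col]][splits$train])
    te <- unique(records[[col]][splits$test])
    va <- unique(records[[col]][splits$val])
    if (length(intersect(tr, te)) || length(intersect(tr, va)) ||
        length(intersect(va, te)))
      stop_dti("split audit failed: entity overlap across splits", "dti_audit_error")
  }
  if (spec$mode == "homology") {
    tr <- unique(records$target_id[splits$train])
    va <- unique(records$target_id[splits$val])
    te <- unique(records$target_id[splits$test])
    chk <- function(a, b, thr, what) {
      for (x in a) for (y in b) {
        idv <- estimate_identity(target_seqs[[x]], target_seqs[[y]], spec$k)
        if (idv > thr + 1e-12)
          stop_dti(sprintf(
            "split audit failed: %s pair (%s, %s) identity %.3f > %.2f",
            what, x, y, idv, thr), "dti_audit_error")
      }
    }
    chk(tr, va, spec$identity_thresholds[1], "train-val")
    chk(tr, te, spec$identity_thresholds[2], "train-test")
    chk(va, te, spec$identity_thresholds[2], "val-test")
  }
  invisible(TRUE)
}
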