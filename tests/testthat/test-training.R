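# Labels, negative sampling, identity estimation, splits, and the fit loop.

test_that("Kd labelling uses a strict threshold", {
  expect_identical(label_from_kd(29.9), 1L)
  expect_identical(label_from_kd(30), 0L)
  expect_identical(label_from_kd(1e6), 0L)
  expect_identical(label_from_kd(c(1, 30, 29.999, 1000)), c(1L, 0L, 1L, 0L))
  expect_identical(label_from_kd(45, threshold = 100), 1L)
  expect_error(label_from_kd(0), class = "dti_input_error")
  expect_error(label_from_kd(-3), class = "dti_input_error")
})

test_that("negative sampling is exact, disjoint from positives, deterministic", {
  drugs <- sprintf("d%d", 1:10)
  targets <- sprintf("t%d", 1:10)
  pos <- expand.grid(drug_id = drugs[1:5], target_id = targets[1:5],
                     stringsAsFactors = FALSE)   # 25 positives
  neg <- sample_negatives(pos, drugs, targets, ratio = 1, seed = 1)
  expect_identical(nrow(neg), 25L)
  expect_identical(unique(neg$label), 0L)
  expect_identical(unique(neg$source), "sampled_negative")
  key <- function(df) paste(df$drug_id, df$target_id)
  expect_length(intersect(key(neg), key(pos)), 0L)
  expect_false(anyDuplicated(key(neg)) > 0)
  expect_identical(sample_negatives(pos, drugs, targets, ratio = 1, seed = 1), neg)
  expect_false(identical(sample_negatives(pos, drugs, targets, ratio = 1, seed = 2), neg))
  # ratio scales the count (floor)
  expect_identical(nrow(sample_negatives(pos, drugs, targets, ratio = 2.5, seed = 1)), 62L)
  # exhausted universe
  pos_all <- expand.grid(drug_id = drugs[1:2], target_id = targets[1:2],
                         stringsAsFactors = FALSE)
  expect_error(sample_negatives(pos_all, drugs[1:2], targets[1:2], 1, 1),
               "non-positive pairs", class = "dti_input_error")
})

test_that("negative sampling is uniform over the eligible universe", {
  drugs <- sprintf("d%d", 1:5); targets <- sprintf("t%d", 1:5)
  pos <- data.frame(drug_id = drugs[c(1, 2, 3, 4, 5)],
                    target_id = targets[c(1, 2, 3, 4, 5)])  # diagonal
  counts <- new.env()
  n_seeds <- 1000
  for (s in seq_len(n_seeds)) {
    neg <- sample_negatives(pos, drugs, targets, ratio = 1, seed = s)
    for (k in paste(neg$drug_id, neg$target_id)) {
      prev <- if (is.null(counts[[k]])) 0 else counts[[k]]
      counts[[k]] <- prev + 1
    }
  }
  freq <- unlist(as.list(counts))
  expect_length(freq, 20L)                     # every eligible pair seen
  p_hit <- 5 / 20                              # 5 draws from 20 eligible
  se <- sqrt(p_hit * (1 - p_hit) / n_seeds) * n_seeds
  expect_true(all(abs(freq - n_seeds * p_hit) < 5 * se))
})

test_that("identity estimator matches hand-enumerated k-mer counts", {
  expect_identical(estimate_identity("ABCDEFGH", "ABCDEFGH"), 1)
  expect_identical(estimate_identity(strrep("A", 20), strrep("G", 20)), 0)
  # "ABCDEFGH" vs "ABCDEXYZ": 4 distinct 5-mers each, one shared (ABCDE)
  expect_identical(estimate_identity("ABCDEFGH", "ABCDEXYZ"), 0.25)
  expect_identical(estimate_identity("ABCDEXYZ", "ABCDEFGH"), 0.25)
  expect_error(estimate_identity("ABC", "ABCDEFGH"), class = "dti_input_error")
})

test_that("random split hits exact 70/10/20 sizes and covers all records", {
  recs <- data.frame(drug_id = sprintf("d%d", rep(1:50, each = 20)),
                     target_id = sprintf("t%d", rep(1:20, 50)),
                     label = rbinom(1000, 1, 0.5))
  sp <- split_spec("random", seed = 3)
  s <- make_splits(recs, sp)
  expect_identical(lengths(s[c("train", "val", "test")]),
                   c(train = 700L, val = 100L, test = 200L))
  expect_identical(sort(unname(unlist(s))), 1:1000)
  expect_identical(make_splits(recs, sp), s)   # deterministic
})

test_that("unseen-entity splits have zero entity overlap", {
  set.seed(4)
  recs <- data.frame(drug_id = sprintf("d%02d", sample(30, 600, TRUE)),
                     target_id = sprintf("t%02d", sample(25, 600, TRUE)),
                     label = rbinom(600, 1, 0.5))
  recs <- recs[!duplicated(recs[1:2]), ]
  for (mode in c("unseen_drug", "unseen_target")) {
    col <- if (mode == "unseen_drug") "drug_id" else "target_id"
    s <- make_splits(recs, split_spec(mode, seed = 5))
    expect_length(intersect(recs[[col]][s$train], recs[[col]][s$test]), 0L)
    expect_length(intersect(recs[[col]][s$train], recs[[col]][s$val]), 0L)
    expect_identical(sort(unname(unlist(s))), seq_len(nrow(recs)))
  }
})

test_that("homology split keeps families together and passes its audit", {
  seqs <- family_sequences(fam = 8, members = 3)
  tids <- names(seqs)
  set.seed(6)
  recs <- data.frame(drug_id = sprintf("d%d", sample(10, 240, TRUE)),
                     target_id = sample(tids, 240, TRUE),
                     label = rbinom(240, 1, 0.5))
  recs <- recs[!duplicated(recs[1:2]), ]
  s <- make_splits(recs, split_spec("homology", seed = 7), target_seqs = seqs)
  fam_of <- substr(recs$target_id, 1, 3)
  expect_length(intersect(fam_of[s$train], fam_of[s$test]), 0L)
  # brute-force bound check (the audit already ran inside make_splits)
  for (a in unique(recs$target_id[s$train]))
    for (b in unique(recs$target_id[s$test]))
      expect_lte(estimate_identity(seqs[[a]], seqs[[b]]), 0.70)
})

test_that("the split audit catches violated guarantees", {
  recs <- data.frame(drug_id = c("d1", "d2", "d3", "d4"),
                     target_id = c("t1", "t1", "t2", "t2"),
                     label = c(1, 0, 1, 0))
  sp <- split_spec("unseen_target", seed = 1)
  bad <- list(train = c(1L, 3L), val = integer(0), test = c(2L, 4L))
  expect_error(audit_split(recs, bad, sp), "entity overlap",
               class = "dti_audit_error")
  expect_error(audit_split(recs, list(train = 1:2, val = 3L, test = 3:4), sp),
               "cover", class = "dti_audit_error")
})

test_that("fit runs, logs history, checkpoints best, and is reproducible", {
  tf <- tiny_features()
  splits <- make_splits(tf$ds$interactions, split_spec("random", seed = 1))
  train <- tf$ds$interactions[splits$train, ]
  val <- tf$ds$interactions[splits$val, ]
  m <- tiny_model(tf$feats)
  fc <- fit_config(lr = 1e-3, batch_size = Inf, epochs = 1, patience = 5, seed = 1)
  r1 <- fit(m, tf$feats, train, val, "classify", fc)
  expect_identical(nrow(r1$history), 1L)
  expect_true(all(is.finite(unlist(r1$history))))
  fc5 <- fit_config(lr = 1e-3, batch_size = Inf, epochs = 5, patience = 10, seed = 1)
  r5a <- fit(m, tf$feats, train, val, "classify", fc5)
  r5b <- fit(m, tf$feats, train, val, "classify", fc5)
  expect_identical(r5a$model$weights, r5b$model$weights)
  expect_identical(r5a$history, r5b$history)
  expect_error(fit(m, tf$feats, train[0, ], val, "classify", fc),
               class = "dti_input_error")
})

test_that("training loss decreases monotonically on a separable set", {
  # drugs and targets share the same 4-dim one-hot-ish structure: label 1
  # iff they point the same way -> linearly separable in the cosine
  set.seed(8)
  drugs <- lapply(1:8, function(i)
    drug_record(sprintf("d%d", i), "*", n_bits = 8L,
                fingerprint = as.integer(rep(c(i %% 2, 1 - i %% 2), each = 4))))
  targets <- lapply(1:8, function(i)
    target_record(sprintf("t%d", i),
                  strrep(if (i %% 2) "AG" else "LV", 10)))
  feats <- assemble_features(drugs, targets)
  pairs <- expand.grid(drug_id = sprintf("d%d", 1:8),
                       target_id = sprintf("t%d", 1:8),
                       stringsAsFactors = FALSE)
  di <- as.integer(sub("d", "", pairs$drug_id))
  ti <- as.integer(sub("t", "", pairs$target_id))
  pairs$label <- as.integer((di %% 2) == (ti %% 2))
  m <- init_model(model_config(n_heads = 2L, d = 8L, drug_depth = 1L,
                               target_depth = 1L, seed = 2L),
                  feats$n_bits, feats$embed_dim)
  r <- fit(m, feats, pairs, pairs, "classify",
           fit_config(lr = 5e-3, batch_size = Inf, epochs = 5, patience = 10,
                      seed = 2))
  expect_true(all(diff(r$history$train_loss) < 0))
})

test_that("balance flag equalizes training classes", {
  tf <- tiny_features()
  inter <- tf$ds$interactions
  # skew the training labels, then fit with balancing on; the model sees a
  # 50/50 set, which we verify through the exposed history length only
  # (behavioural check: no error and prevalence-insensitive loss at epoch 1)
  m <- tiny_model(tf$feats)
  r <- fit(m, tf$feats, inter, inter[1:50, ], "classify",
           fit_config(lr = 1e-3, batch_size = Inf, epochs = 1, patience = 2,
                      seed = 3, balance = TRUE))
  expect_identical(nrow(r$history), 1L)
  expect_true(is.finite(r$history$train_loss[1]))
  expect_lt(r$history$train_loss[1], 1.5)
})

test_that("interaction tables with kd columns convert on read", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("drug_id\ttarget_id\tkd", "d1\tt1\t5", "d1\tt2\t30",
               "d2\tt1\t1000"), path)
  tab <- read_interactions(path)
  expect_identical(tab$label, c(1L, 0L, 0L))
})
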