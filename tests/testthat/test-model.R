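# Attention pooling, the two scoring heads, losses, persistence, gradients.

make_model <- function(...) init_model(model_config(...), n_bits = 64L,
                                        embed_dim = 32L)

test_that("attention rows sum to 1 for L in {1, 2, 10, 500}", {
  m <- make_model(n_heads = 4L, d = 16L, seed = 1L)
  set.seed(1)
  for (L in c(1L, 2L, 10L, 500L)) {
    ap <- attention_pool(matrix(rnorm(L * 32), L), m)
    expect_equal(rowSums(ap$attention), rep(1, 4), tolerance = 1e-6)
    expect_identical(ncol(ap$attention), L)
  }
})

test_that("degenerate pooling inputs behave as softmax dictates", {
  m <- make_model(n_heads = 3L, d = 16L, seed = 2L)
  # single residue: every head puts weight exactly 1 on it
  ap <- attention_pool(matrix(rnorm(32), 1), m)
  expect_equal(as.numeric(ap$attention), rep(1, 3))
  # identical residues: uniform attention 1/L
  X <- matrix(rep(rnorm(32), 8), nrow = 8, byrow = TRUE)
  ap <- attention_pool(X, m)
  expect_equal(as.numeric(ap$attention), rep(1 / 8, 3 * 8), tolerance = 1e-12)
  expect_error(attention_pool(matrix(0, 0, 32), m), class = "dti_input_error")
  expect_error(attention_pool(matrix(0, 3, 16), m), class = "dti_input_error")
})

test_that("pooling is permutation-equivariant with an invariant pooled vector", {
  m <- make_model(n_heads = 4L, d = 16L, seed = 3L)
  set.seed(4)
  X <- matrix(rnorm(20 * 32), 20)
  perm <- sample(20)
  a1 <- attention_pool(X, m)
  a2 <- attention_pool(X[perm, ], m)
  expect_equal(a1$pooled, a2$pooled, tolerance = 1e-12)
  expect_equal(a1$attention[, perm], unclass(a2$attention), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("interaction probability implements the scaled-cosine sigmoid", {
  zd <- co_embedding(c(1, 0, 0))
  zt <- co_embedding(c(0, 1, 0))
  expect_identical(interaction_probability(zd, zt), 0.5)
  expect_equal(interaction_probability(zd, zd), 1 / (1 + exp(-5)),
               tolerance = 1e-12)
  p_anti <- interaction_probability(zd, co_embedding(c(-1, 0, 0)))
  expect_equal(p_anti, 1 / (1 + exp(5)), tolerance = 1e-12)
  expect_equal(interaction_probability(zd, zd) + p_anti, 1, tolerance = 1e-12)
  # scale invariance
  set.seed(5)
  u <- rnorm(8); v <- rnorm(8)
  expect_equal(interaction_probability(2 * u, v),
               interaction_probability(u, v), tolerance = 1e-12)
  expect_equal(interaction_probability(u, 0.1 * v),
               interaction_probability(u, v), tolerance = 1e-12)
  expect_error(interaction_probability(c(0, 0), c(1, 0)), class = "dti_input_error")
  expect_error(interaction_probability(c(1, 0), c(1, 0, 0)), class = "dti_input_error")
})

test_that("probabilities are bounded and monotone in the cosine", {
  set.seed(6)
  lo <- plogis(-5); hi <- plogis(5)
  cosines <- numeric(1000); probs <- numeric(1000)
  for (i in 1:1000) {
    u <- rnorm(16); v <- rnorm(16)
    cosines[i] <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    probs[i] <- interaction_probability(u, v)
    expect_gte(probs[i], lo); expect_lte(probs[i], hi)
  }
  expect_identical(order(cosines), order(probs))
})

test_that("affinity head is the bilinear dot product", {
  expect_identical(predict_affinity(c(0, 0), c(3, -1)), 0)
  expect_identical(predict_affinity(c(1, 2), c(3, -1)), 1)
  expect_identical(predict_affinity(2 * c(1, 2), c(3, -1)),
                   2 * predict_affinity(c(1, 2), c(3, -1)))
  expect_error(predict_affinity(c(1, 2), c(1, 2, 3)), class = "dti_input_error")
})

test_that("losses match hand-evaluated values", {
  expect_equal(bce_loss(rep(0.5, 7), c(1, 0, 1, 0, 1, 1, 0)), log(2),
               tolerance = 1e-12)
  expect_lte(bce_loss(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  expect_equal(bce_loss(0.25, 1), -log(0.25), tolerance = 1e-12)
  expect_error(bce_loss(c(0.5, 0.5), 1), class = "dti_input_error")
  expect_error(bce_loss(0.5, 2), class = "dti_input_error")
  expect_identical(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_identical(mse_loss(c(0, 0), c(1, 1)), 1)
  expect_identical(mse_loss(3, 1), 4)
  expect_error(mse_loss(1:3, 1:2), class = "dti_input_error")
})

test_that("co-embedding projections validate widths and are deterministic", {
  m <- make_model(n_heads = 2L, d = 8L, seed = 7L)
  fp <- rbinom(64, 1, 0.5)
  z1 <- co_embed_drug(fp, m)
  z2 <- co_embed_drug(fp, m)
  expect_identical(z1$vector, z2$vector)
  expect_length(z1$vector, 8L)
  expect_error(co_embed_drug(fp[1:10], m), "width", class = "dti_input_error")
  pooled <- rnorm(m$e_pool)
  zt <- co_embed_target(pooled, m)
  expect_length(zt$vector, 8L)
  expect_error(co_embed_target(rnorm(3), m), class = "dti_input_error")
  # a residue matrix is pooled on the way in
  set.seed(8)
  X <- matrix(rnorm(6 * 32), 6)
  zt2 <- co_embed_target(X, m)
  expect_equal(zt2$vector, co_embed_target(attention_pool(X, m)$pooled, m)$vector)
})

test_that("model files round-trip scores bitwise and fail loudly otherwise", {
  m <- make_model(n_heads = 2L, d = 8L, seed = 9L)
  set.seed(10)
  fps <- matrix(rbinom(10 * 64, 1, 0.5), 10)
  Xs <- lapply(1:10, function(i) matrix(rnorm(5 * 32), 5))
  score <- function(mm) vapply(1:10, function(i)
    interaction_probability(co_embed_drug(fps[i, ], mm),
                            co_embed_target(Xs[[i]], mm)), 0)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(score(m), score(m2))
  # truncated file -> integrity error
  raw <- readBin(path, "raw", file.size(path))
  trunc_path <- tempfile(fileext = ".rds")
  writeBin(raw[seq_len(min(50, length(raw)))], trunc_path)
  expect_error(load_model(trunc_path), class = "dti_integrity_error")
  # missing alpha -> explicit error, not a silent default
  obj <- readRDS(path)
  obj$config$alpha <- NULL
  noalpha <- tempfile(fileext = ".rds")
  saveRDS(obj, noalpha)
  expect_error(load_model(noalpha), "alpha", class = "dti_integrity_error")
  # wrong format version
  obj2 <- readRDS(path)
  obj2$format_version <- 99L
  vpath <- tempfile(fileext = ".rds")
  saveRDS(obj2, vpath)
  expect_error(load_model(vpath), "version", class = "dti_integrity_error")
})

test_that("analytic gradients match finite differences on a 5-pair batch", {
  m <- make_model(n_heads = 2L, d = 8L, drug_depth = 3L, target_depth = 3L,
                  seed = 11L)
  set.seed(12)
  FP <- matrix(rbinom(4 * 64, 1, 0.5), 4)
  X <- matrix(rnorm(3 * 6 * 32), 18)
  seg <- rep(1:3, each = 6)
  pd <- c(1, 2, 3, 4, 1); pt <- c(1, 2, 3, 1, 2); y <- c(1, 0, 1, 0, 1)
  for (task in c("classify", "regress")) {
    yy <- if (task == "classify") y else y + 0.3
    lg <- dtiscreen:::loss_and_grads(m, FP, X, seg, 3L, pd, pt, yy, task)
    flat <- dtiscreen:::flatten_weights(m$weights)
    eps <- 1e-6
    for (nm in names(flat)) {
      i <- which.max(abs(lg$grads[[nm]]))
      loss_at <- function(delta) {
        f <- flat; f[[nm]][i] <- f[[nm]][i] + delta
        mm <- m; mm$weights <- dtiscreen:::unflatten_weights(f, m$weights)
        dtiscreen:::loss_and_grads(mm, FP, X, seg, 3L, pd, pt, yy, task)$loss
      }
      num <- (loss_at(eps) - loss_at(-eps)) / (2 * eps)
      expect_equal(as.numeric(lg$grads[[nm]][i]), num, tolerance = 1e-4,
                   label = sprintf("%s gradient (%s)", nm, task))
    }
  }
})

test_that("same seed gives identical initial weights", {
  m1 <- make_model(n_heads = 2L, d = 8L, seed = 42L)
  m2 <- make_model(n_heads = 2L, d = 8L, seed = 42L)
  expect_identical(m1$weights, m2$weights)
  m3 <- make_model(n_heads = 2L, d = 8L, seed = 43L)
  expect_false(identical(m1$weights, m3$weights))
})
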