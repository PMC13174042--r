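test_that("sdpa matches a by-hand softmax computation", {
  Q <- matrix(c(1, 0, 2, 1, 0, 1), 3, 2, byrow = TRUE)
  K <- matrix(c(1, 1, 0, 2, 1, 0), 3, 2, byrow = TRUE)
  V <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  out <- sdpa(Q, K, V)
  # oracle: brute-force softmax of QK'/sqrt(2), row by row
  S <- Q %*% t(K) / sqrt(2)
  A <- matrix(0, 3, 3)
  for (i in 1:3) A[i, ] <- exp(S[i, ]) / sum(exp(S[i, ]))
  expect_equal(out$attention, A, tolerance = 1e-6)
  expect_equal(out$output, A %*% V, tolerance = 1e-6)
  expect_equal(rowSums(out$attention), rep(1, 3), tolerance = 1e-12)
})

test_that("sdpa handles identical keys, masks, and degenerate masks", {
  Q <- matrix(rnorm(6), 3, 2)
  K <- matrix(1, 3, 2)          # identical keys -> uniform attention
  V <- matrix(rnorm(6), 3, 2)
  expect_equal(sdpa(Q, K, V)$attention, matrix(1 / 3, 3, 3))
  m <- c(TRUE, FALSE, FALSE)    # single unmasked position -> weight 1
  expect_equal(sdpa(Q, K, V, m)$attention[, 1], rep(1, 3))
  expect_error(sdpa(Q, K, V, rep(FALSE, 3)), "all positions masked")
})

test_that("embedding layer sums the active channel embeddings", {
  ds <- fixture_cohort(n = 4)
  cfgm <- fixture_model_config()
  p <- gestureEF:::init_params(cfgm, ds$vocabularies, 1L)
  cfg <- gestureEF:::cpp_config(cfgm, ds$vocabularies)
  r <- ds$records[[1]]
  ids <- encode_sequence(r, ds$vocabularies)$ids
  out <- gestureEF:::tf_forward_case(p, cfg, ids, numeric(0))
  L1 <- nrow(ids)
  expect_identical(dim(out$attention[[1]]), c(L1, L1, 2L))
  # d = 1 and d = 3 give the same representation width
  cfg1 <- fixture_model_config(channels = "gesture")
  p1 <- gestureEF:::init_params(cfg1, ds$vocabularies, 1L)
  out1 <- gestureEF:::tf_forward_case(
    p1, gestureEF:::cpp_config(cfg1, ds$vocabularies),
    encode_sequence(r, ds$vocabularies, "gesture")$ids, numeric(0))
  expect_identical(length(out1$cls_representation),
                   length(out$cls_representation))
})

test_that("attention rows sum to 1 in every layer and head", {
  ds <- fixture_cohort(n = 4)
  cfgm <- fixture_model_config(n_layers = 2L)
  m <- train_outcome_model(ds, cfgm)
  fw <- forward_pass(m, ds$records[[2]])
  for (a in fw$attention) {
    for (h in seq_len(dim(a)[3])) {
      expect_equal(rowSums(a[, , h]), rep(1, nrow(a[, , h])),
                   tolerance = 1e-5)
    }
  }
  expect_gte(fw$probability, 0)
  expect_lte(fw$probability, 1)
})

test_that("analytic gradients match central finite differences", {
  ds <- fixture_cohort(n = 4)
  cfgm <- model_config(embed_dim = 4L, n_layers = 2L, n_heads = 2L,
                       ffn_dim = 8L, dropout = 0, max_len = 32L,
                       use_clinical = TRUE, clinical_hidden = 3L)
  cfg <- gestureEF:::cpp_config(cfgm, ds$vocabularies)
  set.seed(4)
  n <- gestureEF:::tf_param_count(cfg)
  p <- rnorm(n, 0, 0.3)
  ids <- lapply(ds$records[1:3], function(r)
    encode_sequence(r, ds$vocabularies)$ids)
  clin <- matrix(rnorm(18), 3, 6)
  y <- c(1, 0, 1)
  lg <- gestureEF:::tf_loss_grad(p, cfg, unname(ids), clin, y, 1.0, 0L)
  eps <- 1e-5
  idx <- sort(sample.int(n, 80))
  num <- vapply(idx, function(i) {
    pp <- p; pp[i] <- p[i] + eps
    up <- gestureEF:::tf_loss_grad(pp, cfg, unname(ids), clin, y, 1.0, 0L)$loss
    pp[i] <- p[i] - eps
    dn <- gestureEF:::tf_loss_grad(pp, cfg, unname(ids), clin, y, 1.0, 0L)$loss
    (up - dn) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - lg$grad[idx]) / pmax(1e-6, abs(num) + abs(lg$grad[idx]))
  expect_lt(max(rel), 1e-3)
})

test_that("forward is deterministic and invariant to PAD stripping", {
  ds <- fixture_cohort(n = 4)
  m <- train_outcome_model(ds, fixture_model_config())
  f1 <- forward_pass(m, ds$records[[1]])
  f2 <- forward_pass(m, ds$records[[1]])
  expect_identical(f1$probability, f2$probability)
  expect_identical(f1$attention, f2$attention)
})

test_that("training is bit-reproducible from the seed", {
  ds <- fixture_cohort(n = 8)
  m1 <- train_outcome_model(ds, fixture_model_config(seed = 11L))
  m2 <- train_outcome_model(ds, fixture_model_config(seed = 11L))
  expect_identical(m1$params, m2$params)
  m3 <- train_outcome_model(ds, fixture_model_config(seed = 12L))
  expect_false(identical(m1$params, m3$params))
})

test_that("training refuses a single-class dataset", {
  ds <- fixture_cohort(n = 8)
  pos <- subset_cohort(ds, which(outcomes(ds) == 1L))
  expect_error(train_outcome_model(pos, fixture_model_config()),
               "both outcome classes")
})

test_that("a separable toy cohort is fit to training AUC 1", {
  ds <- fixture_cohort(n = 16, seed = 3)
  cfgm <- fixture_model_config(max_epochs = 40L, early_stop_patience = 40L)
  m <- train_outcome_model(ds, cfgm)
  sc <- score_cases(m, ds)
  expect_identical(auc(sc$probability, outcomes(ds)), 1)
})

test_that("zero classifier weights give probability exactly 0.5", {
  ds <- fixture_cohort(n = 4)
  cfgm <- fixture_model_config()
  p <- gestureEF:::init_params(cfgm, ds$vocabularies, 1L)
  # output layer is zero-initialized by construction
  out <- gestureEF:::tf_forward_case(
    p, gestureEF:::cpp_config(cfgm, ds$vocabularies),
    encode_sequence(ds$records[[1]], ds$vocabularies)$ids, numeric(0))
  expect_identical(out$probability, 0.5)
})

test_that("clinical fusion requires clinical features and changes output", {
  ds <- fixture_cohort(n = 8)
  cfgm <- fixture_model_config(use_clinical = TRUE, clinical_hidden = 4L)
  m <- train_outcome_model(ds, cfgm)
  expect_false(is.null(m$scaler))
  r <- ds$records[[1]]
  p1 <- forward_pass(m, r)$probability
  r2 <- r
  r2$clinical <- clinical_features(80, 75, 35, 9, 20, 50)
  p2 <- forward_pass(m, r2)$probability
  expect_false(identical(p1, p2))
})

test_that("scored attention weights are renormalized over content tokens", {
  ds <- fixture_cohort(n = 6)
  m <- train_outcome_model(ds, fixture_model_config())
  sc <- score_cases(m, ds)
  for (id in names(ds$records)) {
    w <- sc$cls_attention[[id]]
    expect_identical(length(w), nrow(ds$records[[id]]$sequence))
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w >= 0))
  }
})
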