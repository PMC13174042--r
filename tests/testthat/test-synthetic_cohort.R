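test_that("simulation config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(positive_rate = 0), "positive_rate")
  expect_error(sim_config(positive_rate = 1), "positive_rate")
  expect_error(sim_config(planted_bigrams = data.frame(
    from = 1L, to = 2L, ratio = -1, class = 1L)), "ratio")
  st <- default_cg_states()
  st$weight[1] <- st$weight[1] + 0.01
  expect_error(sim_config(states = st), "sum to 1")
})

test_that("base transition-matrix rows sum to 1 within 1e-9", {
  cfg <- sim_config()
  expect_true(all(abs(rowSums(cfg$base_transition_matrix) - 1) < 1e-9))
})

test_that("class matrices differ only through planted enrichment", {
  cfg1 <- sim_config(planted_bigrams = data.frame(from = 2L, to = 3L,
                                                  ratio = 1, class = 1L))
  m1 <- build_class_matrices(cfg1)
  expect_equal(m1$matrix_pos, m1$matrix_neg)

  cfg2 <- sim_config(planted_bigrams = data.frame(from = 2L, to = 3L,
                                                  ratio = 2, class = 1L))
  m2 <- build_class_matrices(cfg2)
  # edited entry doubles before renormalization
  base <- cfg2$base_transition_matrix
  expect_equal(m2$matrix_pos[2, 3] / m2$matrix_pos[2, 1],
               2 * base[2, 3] / base[2, 1])
  expect_equal(m2$matrix_neg, base)
  expect_true(all(abs(rowSums(m2$matrix_pos) - 1) < 1e-12))
})

test_that("realized bigram frequency matches the stationary analytic value", {
  # uniform-ish 3-state chain with one boosted transition; oracle =
  # stationary eigen-decomposition of the edited matrix
  P <- matrix(1 / 3, 3, 3)
  P[1, 2] <- P[1, 2] * 3
  P <- P / rowSums(P)
  pi_ <- stationary_distribution(P)
  expected <- pi_[1] * P[1, 2]          # long-run frequency of pair 1 -> 2
  chain <- gestureEF:::markov_sample_cpp(P, pi_, 2e5, 42L)
  pair_rate <- mean(chain[-length(chain)] == 1L & chain[-1L] == 2L)
  se <- sqrt(expected * (1 - expected) / 2e5)
  expect_lt(abs(pair_rate - expected), 3 * se)
})

test_that("cohort generation is exactly reproducible from the seed", {
  cfg <- sim_config(n_cases = 12L, seed = 9L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(
    lapply(a$dataset$records, `[[`, "sequence"),
    lapply(b$dataset$records, `[[`, "sequence"))
  expect_identical(outcomes(a$dataset), outcomes(b$dataset))
  expect_equal(clinical_matrix(a$dataset), clinical_matrix(b$dataset))
  c <- generate_cohort(sim_config(n_cases = 12L, seed = 10L))
  expect_false(identical(outcomes(a$dataset), outcomes(c$dataset)))
})

test_that("generated records satisfy the case-record invariants", {
  sim <- generate_cohort(sim_config(n_cases = 20L, seed = 2L))
  ds <- sim$dataset
  for (r in ds$records) {
    expect_gte(nrow(r$sequence), 1L)
    expect_identical(r$sequence$ordinal, seq_len(nrow(r$sequence)) - 1L)
    expect_identical(r$ef_outcome,
                     classify_ef_outcome(r$shim_total, r$shim_q2))
    # every token in vocabulary (token_id errors otherwise)
    for (ch in c("gesture", "anatomy", "function")) {
      expect_silent(gestureEF:::token_id(ds$vocabularies[[ch]],
                                         r$sequence[[ch]]))
    }
  }
})

test_that("positive count is consistent with the configured 35% rate", {
  sim <- generate_cohort(sim_config(n_cases = 147L, seed = 5L))
  npos <- sum(outcomes(sim$dataset))
  # binomial 99% interval around 147 * 0.35 = 51.45
  bounds <- qbinom(c(0.005, 0.995), 147, 0.35)
  expect_gte(npos, bounds[1])
  expect_lte(npos, bounds[2])
})

test_that("sequence-length distribution hits the calibrated median", {
  sim <- generate_cohort(sim_config(n_cases = 1000L, seed = 3L))
  lens <- vapply(sim$dataset$records, function(r) nrow(r$sequence), integer(1))
  expect_gte(median(lens), 400)
  expect_lte(median(lens), 500)
  expect_true(all(lens >= 50 & lens <= 2000))
})

test_that("zero clinical effects leave the covariates label-free", {
  # two-sample t-test per feature should reject at about its nominal rate
  pvals <- replicate(60, {
    cfg <- sim_config(n_cases = 60L,
                      clinical_effects = c(prostate_volume = 0, age = 0,
                                           bmi = 0, log_psa = 0,
                                           postop_gleason = 0),
                      planted_bigrams = data.frame(from = integer(0),
                                                   to = integer(0),
                                                   ratio = numeric(0),
                                                   class = integer(0)),
                      seed = sample.int(1e6, 1))
    sim <- generate_cohort(cfg)
    y <- outcomes(sim$dataset)
    cm <- clinical_matrix(sim$dataset)
    vapply(c("age", "bmi", "prostate_volume", "psa"), function(f) {
      t.test(cm[y == 1, f], cm[y == 0, f])$p.value
    }, numeric(1))
  })
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("realized enrichment follows its conventions", {
  ds <- fixture_cohort(n = 8)
  st <- default_cg_states()
  # a pair absent from every sequence -> ratio 1 by convention
  expect_identical(
    realized_enrichment(ds,
                        from = c("coagulate", "prostatic pedicle", "hemostasis"),
                        to = c("coagulate", "prostatic pedicle", "hemostasis")),
    1)
  # marker pair occurs only in positive cases -> Inf sentinel
  r <- realized_enrichment(ds,
                           from = c("hot cut", "prostatic pedicle", "hemostasis"),
                           to = c("hot cut", "prostatic pedicle", "hemostasis"))
  expect_true(is.infinite(r) || r > 1)  # adjacent marker pair may or may not occur
  # single-class dataset errors
  ds_pos <- subset_cohort(ds, which(outcomes(ds) == 1L))
  expect_error(realized_enrichment(ds_pos, 2L, 3L, st), "both outcome classes")
})

test_that("a 4.3x planted pair is recovered from a large cohort", {
  cfg <- sim_config(n_cases = 800L, seed = 21L)
  sim <- generate_cohort(cfg)
  r <- realized_enrichment(sim$dataset, 2L, 3L, cfg$states)
  expect_gte(r, 4.3 * 0.75)
  expect_lte(r, 4.3 * 1.25)
  # ground-truth bookkeeping agrees with an independent recount
  gt <- sim$ground_truth$realized
  expect_equal(gt$freq_pos / gt$freq_neg, r, tolerance = 1e-12)
})

test_that("null cohorts carry no label signal for bigram frequencies", {
  cfg <- sim_config(n_cases = 80L,
                    planted_bigrams = data.frame(from = 2L, to = 3L,
                                                 ratio = 1, class = 1L),
                    clinical_effects = c(prostate_volume = 0, age = 0,
                                         bmi = 0, log_psa = 0,
                                         postop_gleason = 0),
                    seed = 31L)
  sim <- generate_cohort(cfg)
  y <- outcomes(sim$dataset)
  f <- gestureEF:::bigram_case_frequencies(sim$dataset, cfg$states, 2L, 3L)
  obs <- abs(mean(f[y == 1]) - mean(f[y == 0]))
  set.seed(99)
  null <- replicate(499, {
    yp <- sample(y)
    abs(mean(f[yp == 1]) - mean(f[yp == 0]))
  })
  p <- (1 + sum(null >= obs)) / 500
  expect_gt(p, 0.01)
})
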