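test_that("bag-of-words features obey the counting identities", {
  r1 <- fixture_record(gestures = "spread")
  b1 <- bag_of_cg_features(r1)
  expect_identical(sum(b1$type == "unigram"), 1L)
  expect_identical(sum(b1$type == "pair"), 0L)

  ds <- fixture_cohort(n = 5)
  for (r in ds$records) {
    b <- bag_of_cg_features(r)
    L <- nrow(r$sequence)
    expect_identical(sum(b$count[b$type == "unigram"]), L)
    expect_identical(sum(b$count[b$type == "pair"]), L - 1L)
  }
})

test_that("pair multiset of an alternating sequence is counted by hand", {
  r <- fixture_record(gestures = c("spread", "cold cut", "spread", "cold cut"),
                      anatomies = rep("lateral fascia", 4),
                      functions_ = rep("exposure", 4))
  b <- bag_of_cg_features(r)
  pairs <- b[b$type == "pair", ]
  ab <- "spread|lateral fascia|exposure -> cold cut|lateral fascia|exposure"
  ba <- "cold cut|lateral fascia|exposure -> spread|lateral fascia|exposure"
  expect_identical(pairs$count[pairs$feature == ab], 2L)
  expect_identical(pairs$count[pairs$feature == ba], 1L)
})

test_that("attention aggregation averages the CLS rows it is given", {
  # two fake iterations with hand-set weights for overlapping case sets
  it1 <- list(caseA = c(0.5, 0.25, 0.25), caseB = c(0.9, 0.1))
  it2 <- list(caseA = c(0.1, 0.45, 0.45))
  agg <- aggregate_attention(list(it1, it2))
  expect_equal(agg$weights$caseA, c(0.3, 0.35, 0.35))
  expect_equal(agg$weights$caseB, c(0.9, 0.1))
  expect_identical(agg$provenance$iterations, 2L)
  expect_error(aggregate_attention(list()), "no attention")
})

test_that("uniform attention gives every token weight 1/L", {
  ds <- fixture_cohort(n = 3)
  ua <- uniform_attention(ds)
  for (id in names(ds$records)) {
    L <- nrow(ds$records[[id]]$sequence)
    expect_equal(ua$weights[[id]], rep(1 / L, L))
  }
})

test_that("weighted frequencies match a hand computation on a 3-case toy", {
  mk <- function(id, g, pos) case_record(
    id, data.frame(gesture = g, anatomy = "lateral fascia",
                   `function` = "exposure", check.names = FALSE),
    fixture_clinical(), shim_total = if (pos) 20 else 8,
    shim_q2 = if (pos) 4 else 1)
  ds <- cohort_dataset(list(
    mk("c1", c("spread", "cold cut"), TRUE),
    mk("c2", c("spread", "spread"), TRUE),
    mk("c3", c("cold cut", "spread"), FALSE)
  ), vocabularies = default_vocabularies())
  att <- structure(list(weights = list(c1 = c(0.6, 0.4),
                                       c2 = c(0.5, 0.5),
                                       c3 = c(0.3, 0.7)),
                        provenance = list(policy = "handset")),
                   class = "token_attention")
  fs <- weighted_frequencies(ds, att)
  s <- fs$stats
  sp <- "spread|lateral fascia|exposure"
  cc <- "cold cut|lateral fascia|exposure"
  pair_sc <- paste(sp, "->", cc)
  # unigram spread: pos (0.6 + 0.5 + 0.5)/2 = 0.8 ; neg 0.7/1
  expect_equal(s$weighted_freq_pos[s$feature == sp], 0.8, tolerance = 1e-9)
  expect_equal(s$weighted_freq_neg[s$feature == sp], 0.7, tolerance = 1e-9)
  # pair spread->cold cut: pos mean(0.6,0.4)/2 cases = 0.25; absent in neg
  expect_equal(s$weighted_freq_pos[s$feature == pair_sc], 0.25,
               tolerance = 1e-9)
  expect_identical(s$weighted_freq_neg[s$feature == pair_sc], 0)
  expect_identical(s$ratio[s$feature == pair_sc], Inf)
  # raw counts
  expect_identical(s$count_pos[s$feature == sp], 3)
  expect_identical(s$count_neg[s$feature == cc], 1)
})

test_that("uniform attention reduces weighted to plain relative frequency", {
  ds <- fixture_cohort(n = 8, seed = 4)
  fs <- weighted_frequencies(ds, uniform_attention(ds))
  expect_equal(fs$stats$weighted_freq_pos, fs$stats$raw_freq_pos,
               tolerance = 1e-12)
  expect_equal(fs$stats$weighted_freq_neg, fs$stats$raw_freq_neg,
               tolerance = 1e-12)
})

test_that("permutation p-values respect the add-one bound and seed", {
  ds <- fixture_cohort(n = 8, seed = 4)
  fs <- weighted_frequencies(ds, uniform_attention(ds))
  p1 <- permutation_pvalues(fs, n_perm = 99L, seed = 5L)
  p2 <- permutation_pvalues(fs, n_perm = 99L, seed = 5L)
  expect_identical(p1$stats$p_value, p2$stats$p_value)
  expect_true(all(p1$stats$p_value >= 1 / 100))
  expect_true(all(p1$stats$p_value <= 1))
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration", {
  # 5-case toy: enumerate all label assignments with the observed class
  # sizes (choose(5, 2) = 10 permutation-distinct relabellings)
  mk <- function(id, g, pos) case_record(
    id, data.frame(gesture = g, anatomy = "lateral fascia",
                   `function` = "exposure", check.names = FALSE),
    fixture_clinical(), shim_total = if (pos) 20 else 8,
    shim_q2 = if (pos) 4 else 1)
  ds <- cohort_dataset(list(
    mk("c1", c("spread", "cold cut", "spread"), TRUE),
    mk("c2", c("spread", "spread", "cold cut"), TRUE),
    mk("c3", c("cold cut", "cold cut", "spread"), FALSE),
    mk("c4", c("peel/push", "spread", "peel/push"), FALSE),
    mk("c5", c("cold cut", "peel/push", "peel/push"), FALSE)
  ), vocabularies = default_vocabularies())
  fs <- weighted_frequencies(ds, uniform_attention(ds))
  y <- fs$y
  C <- fs$contrib
  n_pos <- sum(y)
  obs <- abs(C %*% (y / n_pos) - C %*% ((1 - y) / (length(y) - n_pos)))

  combs <- combn(5, 2)
  exact <- rep(0, nrow(C))
  for (k in seq_len(ncol(combs))) {
    yp <- rep(0, 5); yp[combs[, k]] <- 1
    d <- abs(C %*% (yp / 2) - C %*% ((1 - yp) / 3))
    exact <- exact + (d >= obs - 1e-12)
  }
  exact_p <- exact / ncol(combs)

  mc <- permutation_pvalues(fs, n_perm = 2000L, seed = 9L)$stats$p_value
  se <- sqrt(exact_p * (1 - exact_p) / 2000)
  expect_true(all(abs(mc - exact_p) <= 2 * se + 2 / 2001))
})

test_that("feature ranking is deterministic with documented tie-breaks", {
  ds <- fixture_cohort(n = 10, seed = 2)
  fs <- permutation_pvalues(
    weighted_frequencies(ds, uniform_attention(ds)), n_perm = 99L, seed = 1L)
  r1 <- rank_features(fs, top_k = 5L, min_cases = 2L)
  r2 <- rank_features(fs, top_k = 5L, min_cases = 2L)
  expect_identical(r1$all, r2$all)
  expect_identical(r1$all$rank, seq_len(nrow(r1$all)))
  # sorted by p, then |difference| descending, then label
  s <- r1$all
  expect_true(all(diff(s$p_value) >= 0))
  # top_k larger than the feature count returns everything enriched
  rall <- rank_features(fs, top_k = 1e6L, min_cases = 1L)
  expect_identical(nrow(rall$recovery) + nrow(rall$non_recovery),
                   sum(rall$all$diff != 0))
  # min_cases filter drops rare features
  expect_true(all(r1$all$n_cases_present >= 2L))
})

test_that("marker features of the toy cohort rank as recovery-enriched", {
  ds <- fixture_cohort(n = 12, seed = 6)
  fs <- permutation_pvalues(
    weighted_frequencies(ds, uniform_attention(ds)), n_perm = 199L, seed = 2L)
  rk <- rank_features(fs, top_k = 3L, min_cases = 3L, type = "unigram")
  marker <- "hot cut|prostatic pedicle|hemostasis"
  expect_true(marker %in% rk$recovery$feature)
})
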