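# small in-code fixtures shared across test files

fixture_clinical <- function() {
  clinical_features(prostate_volume = 42.5, age = 61, bmi = 27.1,
                    postop_gleason = 7, psa = 5.4, surgeon_caseload = 850)
}

# deterministic little case: tokens drawn from the default vocabularies
fixture_record <- function(case_id = "caseA",
                           gestures = c("peel/push", "cold cut", "spread"),
                           anatomies = rep("lateral fascia", length(gestures)),
                           functions_ = rep("release neurovascular bundle",
                                            length(gestures)),
                           shim_total = 20, shim_q2 = 4) {
  case_record(
    case_id = case_id,
    sequence = data.frame(gesture = gestures, anatomy = anatomies,
                          `function` = functions_, check.names = FALSE),
    clinical = fixture_clinical(),
    shim_total = shim_total, shim_q2 = shim_q2
  )
}

# two-class toy cohort over the default vocabularies; positives carry a
# marker token so toy models can separate the classes
fixture_cohort <- function(n = 10, seed = 1) {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i) {
    pos <- i <= n / 2
    L <- sample(5:9, 1)
    g <- sample(c("peel/push", "cold cut", "spread"), L, replace = TRUE)
    a <- sample(c("lateral fascia", "posterior plane"), L, replace = TRUE)
    f <- sample(c("release neurovascular bundle",
                  "extension of posterior plane"), L, replace = TRUE)
    if (pos) {
      j <- sample(seq_len(L), 2)
      g[j] <- "hot cut"; a[j] <- "prostatic pedicle"; f[j] <- "hemostasis"
    }
    case_record(
      case_id = sprintf("case%02d", i),
      sequence = data.frame(gesture = g, anatomy = a, `function` = f,
                            check.names = FALSE),
      clinical = clinical_features(
        prostate_volume = 30 + 2 * i, age = 55 + i, bmi = 24 + 0.3 * i,
        postop_gleason = 6 + i %% 3, psa = 3 + 0.4 * i,
        surgeon_caseload = 200 + 10 * i),
      shim_total = if (pos) 21 else 9,
      shim_q2 = if (pos) 5 else 2
    )
  })
  cohort_dataset(recs, vocabularies = default_vocabularies())
}

# compact model configuration used in tests that need a trained model
fixture_model_config <- function(...) {
  args <- list(channels = c("gesture", "anatomy", "function"),
               embed_dim = 8L, n_layers = 1L, n_heads = 2L, ffn_dim = 16L,
               dropout = 0, max_len = 64L, learning_rate = 3e-3,
               max_epochs = 15L, early_stop_patience = 15L,
               val_fraction = 0, batch_size = 8L, seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}
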