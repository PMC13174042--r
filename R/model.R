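#' Configuration of the transformer outcome model
#'
#' Architecture and training hyperparameters of the multimodal EF-outcome
#' predictor. The sequence branch is a pre-norm transformer encoder over the
#' selected contextualized-gesture channels with summed per-channel
#' embeddings, sinusoidal positional encodings and a learnable CLS token
#' whose final representation feeds the classifier head. When
#' `use_clinical` is TRUE, a small fully connected network over the six
#' z-scored clinical features is fused with the CLS representation by
#' concatenation before the final fully connected output layer.
#'
#' @param channels character subset of `c("gesture", "anatomy",
#'   "function")`; the number of active channels is the input dimension d.
#' @param embed_dim embedding width (must be divisible by `n_heads`).
#' @param n_layers,n_heads,ffn_dim encoder depth, attention heads, and
#'   feed-forward width.
#' @param dropout dropout probability applied to the attention and
#'   feed-forward residual branches during training only.
#' @param max_len maximum content sequence length; longer sequences are
#'   truncated from the end (the start of the nerve-sparing step is
#'   retained) with a warning.
#' @param use_clinical fuse clinical features.
#' @param clinical_hidden width of the clinical hidden layer.
#' @param learning_rate,weight_decay,batch_size,max_epochs AdamW settings.
#' @param early_stop_patience epochs without improvement of the monitored
#'   loss before stopping ("trained until convergence").
#' @param val_fraction fraction of the training cases held aside to monitor
#'   early stopping; 0 monitors training loss instead.
#' @param swa tail-average the parameters over the second half of training
#'   (stochastic weight averaging) instead of keeping the best-epoch
#'   parameters; disables early stopping.
#' @param embed_init_sd standard deviation of the token-embedding
#'   initialization. Content embeddings must be comparable in scale to the
#'   unit-amplitude sinusoidal positional encodings, otherwise every
#'   learned feature is dominated by position rather than token identity.
#' @param pos_weight loss weight of the positive class (1 = none).
#' @param pretrain_epochs number of masked-token self-supervised
#'   pretraining epochs run on the (unlabeled) training sequences before
#'   classifier training; 0 disables pretraining. Pretraining teaches the
#'   encoder the local transition structure of the gesture sequences,
#'   which stabilizes the supervised fit at small cohort sizes.
#' @param pretrain_mask_prob fraction of content positions masked per
#'   sequence during pretraining.
#' @param seed seed governing initialization, batching and dropout.
#' @return object of class `ef_model_config`.
#' @export
model_config <- function(channels = c("gesture", "anatomy", "function"),
                         embed_dim = 64L, n_layers = 2L, n_heads = 4L,
                         ffn_dim = 128L, dropout = 0.1, max_len = 1024L,
                         use_clinical = FALSE, clinical_hidden = 16L,
                         learning_rate = 1e-3, weight_decay = 1e-2,
                         batch_size = 16L, max_epochs = 200L,
                         early_stop_patience = 20L, val_fraction = 0.15,
                         pos_weight = 1, swa = FALSE, embed_init_sd = 0.5,
                         pretrain_epochs = 0L, pretrain_mask_prob = 0.15,
                         seed = 1L) {
  channels <- match.arg(channels, CHANNELS, several.ok = TRUE)
  if (embed_dim %% n_heads != 0L) {
    stop("embed_dim must be divisible by n_heads")
  }
  structure(
    list(channels = channels, embed_dim = as.integer(embed_dim),
         n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
         ffn_dim = as.integer(ffn_dim), dropout = dropout,
         max_len = as.integer(max_len), use_clinical = isTRUE(use_clinical),
         clinical_hidden = as.integer(clinical_hidden),
         learning_rate = learning_rate, weight_decay = weight_decay,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         early_stop_patience = as.integer(early_stop_patience),
         val_fraction = val_fraction, pos_weight = pos_weight,
         swa = isTRUE(swa), embed_init_sd = embed_init_sd,
         pretrain_epochs = as.integer(pretrain_epochs),
         pretrain_mask_prob = pretrain_mask_prob,
         seed = as.integer(seed)),
    class = "ef_model_config"
  )
}

# C++-facing config list
cpp_config <- function(config, vocabularies) {
  list(d = length(config$channels),
       embed_dim = config$embed_dim, n_heads = config$n_heads,
       n_layers = config$n_layers, ffn_dim = config$ffn_dim,
       use_clinical = config$use_clinical,
       n_clinical = length(CLINICAL_FEATURES),
       clinical_hidden = config$clinical_hidden,
       dropout = config$dropout,
       max_len = config$max_len,
       vocab_sizes = vapply(config$channels,
                            function(ch) vocab_size(vocabularies[[ch]]),
                            integer(1)))
}

# encode all cases as id matrices; at inference content is truncated to
# max_len (training instead re-crops long sequences randomly each epoch)
encode_for_model <- function(dataset, config, truncate = TRUE) {
  truncated <- 0L
  ids <- lapply(dataset$records, function(r) {
    m <- encode_sequence(r, dataset$vocabularies, config$channels)$ids
    if (truncate && nrow(m) - 1L > config$max_len) {
      truncated <<- truncated + 1L
      m <- m[seq_len(config$max_len + 1L), , drop = FALSE]
    }
    m
  })
  if (truncated > 0L) {
    warning(truncated, " sequence(s) longer than max_len = ", config$max_len,
            " truncated from the end", call. = FALSE)
  }
  ids
}

# z-score scaler fitted on the cases used for fitting only
fit_scaler <- function(clin) {
  mu <- colMeans(clin)
  sdv <- apply(clin, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(clin, scaler) {
  scale(clin, center = scaler$mean, scale = scaler$sd)[, , drop = FALSE]
}

# Attention-head initialization that seeds a "previous-token" pattern.
# Sinusoidal encodings satisfy a shift identity: rotating each
# (sin, cos) frequency pair of PE(j) by its own angle theta_k yields
# PE(j+1), so with Q = x[1:dk] and K = R x[1:dk] the logits
# Q_i K_j' = s^2 sum_k cos((i-1-j) theta_k) peak at j = i-1. One head per
# layer starts with this structure (the rest are Xavier-random), which
# makes consecutive-pair composition available from the first epoch
# instead of having to be discovered from scratch.
prev_token_head <- function(m, dk, head_scale = 2) {
  Wq <- matrix(0, m, dk)
  Wk <- matrix(0, m, dk)
  for (j in seq_len(dk)) {
    k <- (j - 1L) %/% 2L
    theta <- 1 / 10000^((2 * k) / m)
    if ((j - 1L) %% 2L == 0L) {       # sin column of pair k
      Wq[j, j] <- head_scale
      Wk[2L * k + 1L, j] <- head_scale * cos(theta)
      Wk[2L * k + 2L, j] <- head_scale * sin(theta)
    } else {                          # cos column of pair k
      Wq[j, j] <- head_scale
      Wk[2L * k + 1L, j] <- -head_scale * sin(theta)
      Wk[2L * k + 2L, j] <- head_scale * cos(theta)
    }
  }
  list(Wq = Wq, Wk = Wk)
}

# parameter initialization: Xavier weights (with the first head of every
# layer seeded as a previous-token head), unit LayerNorm gains, zero
# biases and zero output layer (initial probability exactly 0.5)
init_params <- function(config, vocabularies, seed) {
  cfg <- cpp_config(config, vocabularies)
  n <- tf_param_count(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- config$embed_dim; f <- config$ffn_dim
  dk <- m %/% config$n_heads
  xav <- function(r, co) rnorm(r * co, 0, sqrt(2 / (r + co)))
  p <- c()
  esd <- if (is.null(config$embed_init_sd)) 0.5 else config$embed_init_sd
  for (v in cfg$vocab_sizes) p <- c(p, rnorm(v * m, 0, esd))  # embeddings
  p <- c(p, rnorm(m, 0, esd))                                 # CLS
  pth <- if (config$n_heads >= 2L && dk >= 2L) prev_token_head(m, dk) else NULL
  for (l in seq_len(config$n_layers)) {
    Wq <- matrix(xav(m, m), m, m)
    Wk <- matrix(xav(m, m), m, m)
    if (!is.null(pth)) {
      Wq[, seq_len(dk)] <- pth$Wq
      Wk[, seq_len(dk)] <- pth$Wk
    }
    p <- c(p, as.numeric(Wq), numeric(m), as.numeric(Wk), numeric(m))
    for (k in 1:2) p <- c(p, xav(m, m), numeric(m))           # Wv, Wo
    p <- c(p, rep(1, m), numeric(m))                          # LN1
    p <- c(p, xav(m, f), numeric(f), xav(f, m), numeric(m))   # FFN
    p <- c(p, rep(1, m), numeric(m))                          # LN2
  }
  p <- c(p, rep(1, m), numeric(m))                            # final LN
  if (config$use_clinical) {
    p <- c(p, xav(cfg$n_clinical, cfg$clinical_hidden),
           numeric(cfg$clinical_hidden))
  }
  mm <- m + if (config$use_clinical) config$clinical_hidden else 0L
  p <- c(p, numeric(mm + 1L))                                 # output layer
  stopifnot(length(p) == n)
  p
}

#' Train the transformer outcome model on a cohort
#'
#' Fits the sequence (+ clinical) model end-to-end with AdamW and binary
#' cross-entropy, stopping early when the monitored loss stops improving.
#' Clinical features are standardized with statistics of the supplied
#' training cohort only, so held-out cases scored later never leak into the
#' scaler. Fully reproducible from `config$seed`.
#'
#' @param dataset a [cohort_dataset()]; must contain both outcome classes.
#' @param config an [model_config()].
#' @return object of class `ef_model`: learned parameters, configuration,
#'   vocabularies, clinical scaler, per-epoch loss history and seed.
#' @export
train_outcome_model <- function(dataset, config = model_config()) {
  y <- outcomes(dataset)
  if (length(unique(y)) < 2L) {
    stop("training requires both outcome classes to be present")
  }
  ids <- encode_for_model(dataset, config, truncate = FALSE)
  clin <- matrix(0, length(y), 0L)
  scaler <- NULL
  if (config$use_clinical) {
    raw <- clinical_matrix(dataset)
    if (anyNA(raw)) stop("missing clinical features with use_clinical = TRUE")
    scaler <- fit_scaler(raw)
    clin <- apply_scaler(raw, scaler)
  }
  cfg <- cpp_config(config, dataset$vocabularies)
  params0 <- init_params(config, dataset$vocabularies, config$seed)
  n <- length(y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n_val <- floor(n * config$val_fraction)
  val_idx <- if (n_val >= 2L) sort(sample.int(n, n_val)) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (!is.null(config$pretrain_epochs) && config$pretrain_epochs > 0L) {
    pre <- tf_pretrain(params0, cfg, unname(ids), config$pretrain_mask_prob,
                       config$learning_rate, config$weight_decay,
                       config$batch_size, config$pretrain_epochs,
                       config$seed + 1L)
    params0 <- as.numeric(pre$params)
  }
  swa_start <- if (config$swa) as.integer(ceiling(config$max_epochs / 2)) else -1L
  fit <- tf_train(params0, cfg, unname(ids), clin, as.numeric(y),
                  train_idx - 1L, val_idx - 1L,
                  config$learning_rate, config$weight_decay,
                  config$batch_size, config$max_epochs,
                  config$early_stop_patience, config$pos_weight,
                  config$seed, swa_start)
  structure(
    list(params = as.numeric(fit$params), config = config,
         vocabularies = dataset$vocabularies, scaler = scaler,
         history = list(train_loss = fit$train_loss,
                        val_loss = fit$val_loss,
                        best_epoch = fit$best_epoch,
                        epochs_run = fit$epochs_run),
         seed = config$seed),
    class = "ef_model"
  )
}

#' @export
print.ef_model <- function(x, ...) {
  cat(sprintf(paste0("<ef_model: d=%d channels (%s)%s, %d layers x %d heads,",
                     " embed %d; %d epochs, best %d>\n"),
              length(x$config$channels),
              paste(x$config$channels, collapse = "+"),
              if (x$config$use_clinical) " + clinical" else "",
              x$config$n_layers, x$config$n_heads, x$config$embed_dim,
              x$history$epochs_run, x$history$best_epoch))
  invisible(x)
}

#' Forward pass of a trained model on one case
#'
#' Inference is deterministic (dropout disabled). Returns the predicted
#' probability, logit, the per-layer per-head attention matrices of shape
#' (L+1) x (L+1) (position 1 is the CLS token), and the CLS representation.
#'
#' @param model an `ef_model`.
#' @param record a [case_record()].
#' @return list with elements `probability`, `logit`, `attention` (list of
#'   `n_layers` arrays, each (L+1) x (L+1) x n_heads), `cls_representation`.
#' @export
forward_pass <- function(model, record) {
  config <- model$config
  ids <- encode_sequence(record, model$vocabularies, config$channels)$ids
  if (nrow(ids) - 1L > config$max_len) {
    warning("sequence truncated from the end to max_len = ", config$max_len,
            call. = FALSE)
    ids <- ids[seq_len(config$max_len + 1L), , drop = FALSE]
  }
  clin <- numeric(0)
  if (config$use_clinical) {
    if (is.null(record$clinical)) stop("missing clinical features for fusion model")
    clin <- as.numeric(apply_scaler(
      matrix(as.numeric(record$clinical[CLINICAL_FEATURES]), 1L), model$scaler))
  }
  out <- tf_forward_case(model$params, cpp_config(config, model$vocabularies),
                         ids, clin)
  out$attention <- lapply(out$attention, function(a) a)
  out
}

#' Score a cohort with a trained model
#'
#' Batch inference: predicted probabilities plus, per case, the token
#' attention weights used by the explainability stage (final-layer CLS row,
#' averaged over heads, CLS/PAD entries dropped and renormalized over
#' content positions).
#'
#' @param model an `ef_model`.
#' @param dataset a [cohort_dataset()].
#' @return list with `probability` (named vector), `logit`, and
#'   `cls_attention` (named list of per-token weight vectors summing to 1).
#' @export
score_cases <- function(model, dataset) {
  config <- model$config
  ids <- suppressWarnings(encode_for_model(dataset, config))
  clin <- matrix(0, length(dataset$records), 0L)
  if (config$use_clinical) {
    clin <- apply_scaler(clinical_matrix(dataset), model$scaler)
  }
  out <- tf_score(model$params, cpp_config(config, model$vocabularies),
                  unname(ids), clin)
  attn <- lapply(out$cls_attention, function(w) w / sum(w))
  names(attn) <- names(dataset$records)
  list(probability = setNames(as.numeric(out$probability),
                              names(dataset$records)),
       logit = setNames(as.numeric(out$logit), names(dataset$records)),
       cls_attention = attn)
}

#' @export
predict.ef_model <- function(object, newdata, ...) {
  score_cases(object, newdata)$probability
}

#' Scaled dot-product attention
#'
#' Reference implementation of the attention primitive the encoder uses:
#' row-softmax of `Q K' / sqrt(d_k)` with masked positions held at
#' `-Inf`, applied to `V`. Rows sum to 1 over unmasked positions.
#'
#' @param Q,K,V query, key, value matrices (n x d_k, n x d_k, n x d_v).
#' @param mask logical vector of length n, TRUE = attendable position.
#' @return list with `output` (attention %*% V) and `attention` (n x n).
#' @export
sdpa <- function(Q, K, V, mask = rep(TRUE, nrow(K))) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V), length(mask) == nrow(K))
  if (!any(mask)) stop("cannot normalize attention: all positions masked")
  S <- Q %*% t(K) / sqrt(ncol(K))
  S[, !mask] <- -Inf
  A <- t(apply(S, 1L, function(r) {
    r <- r - max(r)
    e <- exp(r)
    e / sum(e)
  }))
  list(output = A %*% V, attention = A)
}
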