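#' Area under the ROC curve (Mann-Whitney form)
#'
#' The fraction of (positive, negative) case pairs in which the positive
#' case receives the higher score, ties counted one half. Computed from
#' ranks in O(n log n); identical to the trapezoidal ROC area.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1: perfect separation
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Monte-Carlo cross-validation plan
#'
#' The evaluation design: one seed-deterministic outer split into
#' train+validation and test parts (80/20; 147 cases give 118 and 29), then
#' repeated random inner splits of the train+validation pool into a
#' training set and a hold-out set (118 cases give 94 and 24). Per-iteration
#' AUC on the inner hold-out forms the performance distribution; the outer
#' test set is scored by every iteration's model as a secondary aggregate.
#'
#' @param n_iterations number of inner Monte-Carlo iterations (the
#'   original-scale analysis uses 5000; the desk default is 200).
#' @param outer_test_fraction fraction of cases in the outer test set;
#'   test size is `floor(n * fraction)`, remainder to train+validation.
#' @param inner_train_size,inner_holdout_size explicit inner sizes, or NULL
#'   to derive them from the train+validation count by the same
#'   80/20 rounding rule (118 -> 94/24).
#' @param master_seed seed from which every iteration's seed is derived.
#' @param stratify stratify splits by outcome class (off by default).
#' @param max_redraws bound on re-draws of an inner split whose hold-out
#'   happens to contain a single class.
#' @return object of class `cv_plan`.
#' @export
cv_plan <- function(n_iterations = 200L, outer_test_fraction = 0.2,
                    inner_train_size = NULL, inner_holdout_size = NULL,
                    master_seed = 1L, stratify = FALSE, max_redraws = 100L) {
  structure(
    list(n_iterations = as.integer(n_iterations),
         outer_test_fraction = outer_test_fraction,
         inner_train_size = inner_train_size,
         inner_holdout_size = inner_holdout_size,
         master_seed = as.integer(master_seed),
         stratify = isTRUE(stratify),
         max_redraws = as.integer(max_redraws)),
    class = "cv_plan"
  )
}

inner_sizes <- function(plan, n_trainval) {
  tr <- plan$inner_train_size
  ho <- plan$inner_holdout_size
  if (is.null(tr)) {
    tr <- round(n_trainval * (1 - plan$outer_test_fraction))
    if (!is.null(ho)) tr <- n_trainval - ho
  }
  if (is.null(ho)) ho <- n_trainval - tr
  if (tr + ho > n_trainval) {
    stop("inner_train_size + inner_holdout_size exceed the train+validation count")
  }
  c(train = as.integer(tr), holdout = as.integer(ho))
}

#' Outer train+validation / test split
#'
#' Seed-deterministic partition with test size `floor(n * fraction)`;
#' 147 cases at fraction 0.20 give 118 train+validation and 29 test cases.
#' Errors if either part lacks an outcome class (re-seed or stratify).
#'
#' @param dataset a [cohort_dataset()].
#' @param plan a [cv_plan()].
#' @return list with `trainval` and `test` cohort subsets and the index
#'   vectors `trainval_idx`, `test_idx`.
#' @export
outer_split <- function(dataset, plan = cv_plan()) {
  n <- length(dataset$records)
  if (n < 2L) stop("dataset too small to split")
  n_test <- floor(n * plan$outer_test_fraction)
  y <- outcomes(dataset)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(plan$master_seed)
  if (plan$stratify) {
    n_test_pos <- round(n_test * mean(y))
    test_idx <- sort(c(sample(which(y == 1L), n_test_pos),
                       sample(which(y == 0L), n_test - n_test_pos)))
  } else {
    test_idx <- sort(sample.int(n, n_test))
  }
  trainval_idx <- setdiff(seq_len(n), test_idx)
  if (length(unique(y[trainval_idx])) < 2L ||
      (n_test > 0L && length(unique(y[test_idx])) < 2L)) {
    stop("an outcome class is missing from one split part; ",
         "use another master_seed or stratify = TRUE")
  }
  list(trainval = subset_cohort(dataset, trainval_idx),
       test = subset_cohort(dataset, test_idx),
       trainval_idx = trainval_idx, test_idx = test_idx)
}

#' Monte-Carlo cross-validated AUC of the outcome model
#'
#' For each iteration, samples the inner training set from the
#' train+validation pool without replacement (re-drawing, up to a bound, if
#' the hold-out is single-class), trains the model, and scores the
#' remaining hold-out cases; the per-iteration hold-out AUCs form the
#' report's distribution. The outer test set is scored by every iteration's
#' model as a secondary aggregate. Identical `master_seed` gives an
#' identical AUC vector.
#'
#' @param dataset a [cohort_dataset()].
#' @param config an [model_config()].
#' @param plan a [cv_plan()].
#' @param collect_attention also return per-case attention weights and
#'   hold-out probabilities per iteration (input to the explainability
#'   stage).
#' @param label configuration label stored in the report.
#' @return object of class `auc_report`: per-iteration AUCs, point estimate
#'   (mean), percentile 95% CI, secondary outer-test AUC summary, and
#'   optionally attention artifacts.
#' @export
monte_carlo_cv <- function(dataset, config = model_config(),
                           plan = cv_plan(), collect_attention = FALSE,
                           label = NULL) {
  sp <- outer_split(dataset, plan)
  trainval <- sp$trainval
  y_tv <- outcomes(trainval)
  n_tv <- length(y_tv)
  sz <- inner_sizes(plan, n_tv)
  if (is.null(label)) {
    label <- paste0(paste(config$channels, collapse = "+"),
                    if (config$use_clinical) "+clinical" else "")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(plan$master_seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, plan$n_iterations)
  auc_holdout <- auc_test <- numeric(plan$n_iterations)
  attn <- if (collect_attention) list() else NULL
  hold_probs <- if (collect_attention) list() else NULL
  for (it in seq_len(plan$n_iterations)) {
    set.seed(iter_seeds[it])
    ok <- FALSE
    for (try in seq_len(plan$max_redraws)) {
      if (plan$stratify) {
        n_tr_pos <- round(sz["train"] * mean(y_tv))
        tr_idx <- sort(c(sample(which(y_tv == 1L), n_tr_pos),
                         sample(which(y_tv == 0L), sz["train"] - n_tr_pos)))
      } else {
        tr_idx <- sort(sample.int(n_tv, sz["train"]))
      }
      ho_idx <- setdiff(seq_len(n_tv), tr_idx)
      if (sz["holdout"] < n_tv - sz["train"]) {
        ho_idx <- ho_idx[seq_len(sz["holdout"])]
      }
      if (length(unique(y_tv[tr_idx])) == 2L &&
          length(unique(y_tv[ho_idx])) == 2L) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not draw a two-class inner split after ",
           plan$max_redraws, " attempts")
    }
    cfg_it <- config
    cfg_it$seed <- iter_seeds[it]
    model <- train_outcome_model(subset_cohort(trainval, tr_idx), cfg_it)
    sc_ho <- score_cases(model, subset_cohort(trainval, ho_idx))
    auc_holdout[it] <- auc(sc_ho$probability, y_tv[ho_idx])
    has_test <- length(sp$test$records) > 1L &&
      length(unique(outcomes(sp$test))) == 2L
    sc_te <- if (has_test) score_cases(model, sp$test) else NULL
    auc_test[it] <- if (has_test) auc(sc_te$probability, outcomes(sp$test)) else NA_real_
    if (collect_attention) {
      w <- c(sc_ho$cls_attention, sc_te$cls_attention)
      attn[[it]] <- w
      hold_probs[[it]] <- sc_ho$probability
    }
  }
  structure(
    list(label = label, auc = auc_holdout,
         point = mean(auc_holdout),
         ci = unname(quantile(auc_holdout, c(0.025, 0.975), type = 7)),
         outer_test = list(auc = auc_test, point = mean(auc_test),
                           ci = unname(quantile(auc_test, c(0.025, 0.975),
                                                type = 7))),
         plan = plan, n_train = unname(sz["train"]),
         n_holdout = unname(sz["holdout"]),
         split = list(trainval_idx = sp$trainval_idx,
                      test_idx = sp$test_idx),
         iter_seeds = iter_seeds,
         attention = attn, holdout_probability = hold_probs),
    class = "auc_report"
  )
}

#' @export
print.auc_report <- function(x, ...) {
  cat(sprintf("<auc_report %s: AUC %.3f [95%% CI %.3f, %.3f] over %d iterations>\n",
              x$label, x$point, x$ci[1], x$ci[2], length(x$auc)))
  invisible(x)
}

#' Input-channel ablation table
#'
#' Re-runs the Monte-Carlo cross-validation for the four nested input
#' configurations — gesture sequence only; + anatomic location;
#' + anatomic location + function; + clinical features — reusing identical
#' outer splits and iteration seeds across rows so the comparison is
#' paired. Reports each row's AUC summary and the AUC difference to the
#' gesture-only reference row.
#'
#' @param dataset a [cohort_dataset()].
#' @param base_config an [model_config()]; its `channels`/`use_clinical`
#'   are overridden per row.
#' @param plan a [cv_plan()].
#' @return object of class `ablation_table`: data.frame summary plus the
#'   full `auc_report` per row.
#' @export
ablation_table <- function(dataset, base_config = model_config(),
                           plan = cv_plan()) {
  rows <- list(
    list(label = "gesture", channels = "gesture", clinical = FALSE),
    list(label = "gesture+anatomy", channels = c("gesture", "anatomy"),
         clinical = FALSE),
    list(label = "gesture+anatomy+function",
         channels = c("gesture", "anatomy", "function"), clinical = FALSE),
    list(label = "gesture+anatomy+function+clinical",
         channels = c("gesture", "anatomy", "function"), clinical = TRUE)
  )
  reports <- lapply(rows, function(r) {
    cfg <- base_config
    cfg$channels <- r$channels
    cfg$use_clinical <- r$clinical
    monte_carlo_cv(dataset, cfg, plan, label = r$label)
  })
  # paired design: identical splits in every row
  h <- vapply(reports, function(r) {
    paste(c(r$split$trainval_idx, 0L, r$split$test_idx), collapse = ",")
  }, character(1))
  stopifnot(all(h == h[1L]))
  summary <- data.frame(
    label = vapply(reports, `[[`, character(1), "label"),
    auc = vapply(reports, `[[`, numeric(1), "point"),
    ci_lower = vapply(reports, function(r) r$ci[1], numeric(1)),
    ci_upper = vapply(reports, function(r) r$ci[2], numeric(1)),
    stringsAsFactors = FALSE
  )
  summary$delta_auc <- summary$auc - summary$auc[1L]
  structure(list(summary = summary, reports = reports),
            class = "ablation_table")
}

#' @export
print.ablation_table <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}

med_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7)
  c(q1 = unname(q[1]), median = unname(q[2]), q3 = unname(q[3]))
}

#' Descriptive cohort statistics
#'
#' Per-channel usage tables (median per-case count with IQR and proportion
#' of all gestures, per gesture / anatomy / function token), the
#' (gesture, function, anatomy) triple-count table suitable for a Sankey
#' diagram, total gesture count, and the per-case sequence-length summary.
#'
#' @param dataset a non-empty [cohort_dataset()].
#' @return object of class `cohort_summary`.
#' @export
cohort_summary <- function(dataset) {
  if (length(dataset$records) == 0L) stop("empty dataset")
  seqs <- lapply(dataset$records, `[[`, "sequence")
  lens <- vapply(seqs, nrow, integer(1))
  all_rows <- do.call(rbind, seqs)
  total <- nrow(all_rows)
  per_channel <- lapply(CHANNELS, function(ch) {
    toks <- dataset$vocabularies[[ch]]$tokens
    counts <- vapply(seqs, function(s) {
      tabulate(match(s[[ch]], toks), nbins = length(toks))
    }, integer(length(toks)))
    counts <- matrix(counts, nrow = length(toks))
    stats <- t(apply(counts, 1, med_iqr))
    data.frame(token = toks,
               median = stats[, "median"], q1 = stats[, "q1"],
               q3 = stats[, "q3"],
               proportion = rowSums(counts) / total,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(per_channel) <- CHANNELS
  triples <- aggregate(
    list(count = rep(1L, total)),
    by = list(gesture = all_rows$gesture, `function` = all_rows[["function"]],
              anatomy = all_rows$anatomy),
    FUN = sum
  )
  triples <- triples[order(-triples$count), , drop = FALSE]
  rownames(triples) <- NULL
  structure(
    list(per_channel = per_channel, triples = triples,
         total_gestures = total, length_summary = med_iqr(lens),
         n_cases = length(seqs)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary: %d cases, %d gestures; length median %d (IQR %d-%d)>\n",
              x$n_cases, x$total_gestures, round(x$length_summary["median"]),
              round(x$length_summary["q1"]), round(x$length_summary["q3"])))
  invisible(x)
}
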