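cg_labels <- function(seq_df) {
  paste(seq_df$gesture, seq_df$anatomy, seq_df[["function"]], sep = "|")
}

#' Bag-of-words features of one case
#'
#' The order-insensitive feature multiset of a case: every contextualized
#' gesture (CG) triple as a unigram, and every ordered pair of consecutive
#' CG triples as a bigram. A length-L sequence yields L unigrams and L-1
#' pairs, with multiplicity preserved.
#'
#' @param record a [case_record()].
#' @return data.frame with columns `feature` (label: `"g|a|f"` for
#'   unigrams, `"g|a|f -> g|a|f"` for pairs), `type`, `count`.
#' @export
bag_of_cg_features <- function(record) {
  labs <- cg_labels(record$sequence)
  L <- length(labs)
  uni <- table(labs)
  pairs <- if (L >= 2L) {
    table(paste(labs[-L], labs[-1L], sep = " -> "))
  } else table(character(0))
  data.frame(
    feature = c(names(uni), names(pairs)),
    type = rep(c("unigram", "pair"), c(length(uni), length(pairs))),
    count = as.integer(c(uni, pairs)),
    stringsAsFactors = FALSE
  )
}

#' Uniform token attention (unweighted baseline)
#'
#' Assigns every observed token of each case the same weight 1/L. With
#' uniform attention the weighted frequencies reduce to plain per-case
#' relative frequencies, so weighted and unweighted rankings coincide.
#'
#' @param dataset a [cohort_dataset()].
#' @param max_len cap on the number of observed positions per case
#'   (mirror of the model's truncation policy); default unlimited.
#' @return object of class `token_attention` (named list of per-case
#'   weight vectors summing to 1, plus provenance).
#' @export
uniform_attention <- function(dataset, max_len = Inf) {
  w <- lapply(dataset$records, function(r) {
    L <- min(nrow(r$sequence), max_len)
    rep(1 / L, L)
  })
  structure(list(weights = w,
                 provenance = list(layer = "none", heads = "none",
                                   iterations = 0L, policy = "uniform")),
            class = "token_attention")
}

#' Aggregate attention over Monte-Carlo CV iterations
#'
#' Collects each case's token attention (final-layer CLS row, head-averaged,
#' renormalized over content positions — as produced by [score_cases()])
#' from every CV iteration in which the case was scored, and averages the
#' per-iteration weight vectors with equal weight. Cases never scored in
#' any iteration are excluded with a warning.
#'
#' @param report an `auc_report` from [monte_carlo_cv()] run with
#'   `collect_attention = TRUE`; alternatively a plain list of iterations,
#'   each a named list of per-case weight vectors.
#' @return object of class `token_attention`: `weights` (named list of
#'   per-case weight vectors summing to 1) and aggregation `provenance`.
#' @export
aggregate_attention <- function(report) {
  iters <- if (inherits(report, "auc_report")) report$attention else report
  if (is.null(iters) || length(iters) == 0L) {
    stop("no attention artifacts; run monte_carlo_cv(collect_attention = TRUE)")
  }
  acc <- list(); n_seen <- list()
  for (it in iters) {
    for (id in names(it)) {
      w <- it[[id]]
      if (is.null(acc[[id]])) {
        acc[[id]] <- w
        n_seen[[id]] <- 1L
      } else {
        k <- min(length(acc[[id]]), length(w))  # differing truncation depths
        acc[[id]] <- acc[[id]][seq_len(k)] + w[seq_len(k)]
        n_seen[[id]] <- n_seen[[id]] + 1L
      }
    }
  }
  weights <- lapply(names(acc), function(id) {
    w <- acc[[id]] / n_seen[[id]]
    w / sum(w)
  })
  names(weights) <- names(acc)
  structure(list(weights = weights,
                 provenance = list(layer = "final", heads = "mean",
                                   iterations = length(iters),
                                   per_case = unlist(n_seen),
                                   policy = "cls_row")),
            class = "token_attention")
}

#' @export
print.token_attention <- function(x, ...) {
  cat(sprintf("<token_attention: %d cases, policy %s>\n",
              length(x$weights), x$provenance$policy))
  invisible(x)
}

#' Class-conditional attention-weighted feature frequencies
#'
#' For every bag-of-words feature (CG unigram or ordered consecutive CG
#' pair), each occurrence contributes its attention mass: the token's
#' weight for a unigram, the mean of the two tokens' weights for a pair.
#' Contributions are summed per outcome class and divided by the number of
#' cases in that class. Raw (attention-free) per-case relative frequencies
#' and occurrence counts are attached alongside. The ratio column follows
#' the enrichment conventions: 1 when a feature occurs in neither class,
#' `Inf` when only in the EF-intact class.
#'
#' @param dataset a [cohort_dataset()] with both classes present.
#' @param attention a `token_attention` covering every included case;
#'   cases without attention are dropped (they were never scored).
#' @return object of class `cg_feature_stats`: `stats` data.frame (one row
#'   per feature) plus the per-case contribution matrices reused by
#'   [permutation_pvalues()].
#' @export
weighted_frequencies <- function(dataset, attention) {
  ids <- intersect(names(dataset$records), names(attention$weights))
  if (length(ids) < length(dataset$records)) {
    warning(length(dataset$records) - length(ids),
            " case(s) without attention excluded", call. = FALSE)
  }
  y <- outcomes(dataset)[ids]
  if (!any(y == 1L) || !any(y == 0L)) {
    stop("both outcome classes must be present among attention-covered cases")
  }
  feat <- list(); contrib <- list(); rawfreq <- list(); cnt <- list(); case <- list()
  for (id in ids) {
    w <- attention$weights[[id]]
    L <- length(w)
    labs <- cg_labels(dataset$records[[id]]$sequence)[seq_len(L)]
    f_uni <- labs
    c_uni <- w
    if (L >= 2L) {
      f_pair <- paste(labs[-L], labs[-1L], sep = " -> ")
      c_pair <- (w[-L] + w[-1L]) / 2
    } else {
      f_pair <- character(0); c_pair <- numeric(0)
    }
    f <- c(f_uni, f_pair)
    contrib_case <- tapply(c(c_uni, c_pair), f, sum)
    count_case <- tapply(rep(1L, length(f)), f, sum)
    feat[[id]] <- names(contrib_case)
    contrib[[id]] <- as.numeric(contrib_case)
    rawfreq[[id]] <- as.numeric(count_case) / L
    cnt[[id]] <- as.integer(count_case)
    case[[id]] <- rep(id, length(contrib_case))
  }
  long_feat <- unlist(feat, use.names = FALSE)
  long_case <- factor(unlist(case, use.names = FALSE), levels = ids)
  features <- sort(unique(long_feat), method = "radix")
  fi <- match(long_feat, features)
  ci <- as.integer(long_case)
  C <- matrix(0, length(features), length(ids),
              dimnames = list(features, ids))
  C[cbind(fi, ci)] <- unlist(contrib, use.names = FALSE)
  Rw <- matrix(0, length(features), length(ids),
               dimnames = list(features, ids))
  Rw[cbind(fi, ci)] <- unlist(rawfreq, use.names = FALSE)
  Cn <- matrix(0L, length(features), length(ids),
               dimnames = list(features, ids))
  Cn[cbind(fi, ci)] <- unlist(cnt, use.names = FALSE)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  wf_pos <- rowSums(C[, y == 1L, drop = FALSE]) / n_pos
  wf_neg <- rowSums(C[, y == 0L, drop = FALSE]) / n_neg
  ratio <- ifelse(wf_pos == 0 & wf_neg == 0, 1,
                  ifelse(wf_neg == 0, Inf, wf_pos / wf_neg))
  stats <- data.frame(
    feature = features,
    type = ifelse(grepl(" -> ", features, fixed = TRUE), "pair", "unigram"),
    weighted_freq_pos = unname(wf_pos),
    weighted_freq_neg = unname(wf_neg),
    ratio = unname(ratio),
    raw_freq_pos = rowSums(Rw[, y == 1L, drop = FALSE]) / n_pos,
    raw_freq_neg = rowSums(Rw[, y == 0L, drop = FALSE]) / n_neg,
    count_pos = rowSums(Cn[, y == 1L, drop = FALSE]),
    count_neg = rowSums(Cn[, y == 0L, drop = FALSE]),
    n_cases_present = rowSums(Cn > 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(stats = stats, contrib = C, counts = Cn,
                 case_ids = ids, y = y),
            class = "cg_feature_stats")
}

#' @export
print.cg_feature_stats <- function(x, ...) {
  cat(sprintf("<cg_feature_stats: %d features over %d cases (%d EF-intact)>\n",
              nrow(x$stats), length(x$case_ids), sum(x$y)))
  invisible(x)
}

#' Label-permutation p-values for weighted frequency differences
#'
#' The null distribution is built by permuting case outcome labels
#' `n_perm` times and recomputing the absolute difference of
#' class-conditional weighted frequencies per feature; the p-value uses the
#' add-one estimator `(1 + #\{null >= observed\}) / (n_perm + 1)`, so
#' `p >= 1/(n_perm+1)` always. Seed-reproducible.
#'
#' @param fstats a `cg_feature_stats` from [weighted_frequencies()].
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return the `cg_feature_stats` with columns `p_value` and `fdr`
#'   (Benjamini-Hochberg) added to `stats`.
#' @export
permutation_pvalues <- function(fstats, n_perm = 999L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  C <- fstats$contrib
  y <- fstats$y
  n <- length(y); n_pos <- sum(y == 1L); n_neg <- n - n_pos
  obs <- abs(C %*% (y / n_pos) - C %*% ((1 - y) / n_neg))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) sample(y), integer(n))
  wfp <- C %*% P / n_pos
  wfn <- C %*% (1L - P) / n_neg
  exceed <- rowSums(abs(wfp - wfn) >= matrix(obs - 1e-12, nrow(C), n_perm))
  fstats$stats$p_value <- (1 + exceed) / (n_perm + 1)
  fstats$stats$fdr <- p.adjust(fstats$stats$p_value, method = "BH")
  fstats$n_perm <- n_perm
  fstats$perm_seed <- seed
  fstats
}

#' Ranked explainability report
#'
#' Sorts features by (p-value ascending, absolute weighted-frequency
#' difference descending, feature label) — a deterministic total order —
#' and returns the top features enriched in each outcome direction.
#' Features present in fewer than `min_cases` cases are excluded to avoid
#' degenerate ratios.
#'
#' @param fstats a `cg_feature_stats` with p-values
#'   (see [permutation_pvalues()]).
#' @param top_k features to report per direction.
#' @param alpha significance threshold recorded in the output.
#' @param min_cases minimum number of cases a feature must appear in.
#' @param type restrict to `"pair"`, `"unigram"`, or `"both"`.
#' @return object of class `cg_feature_ranking` with data.frames
#'   `recovery` (EF-intact-enriched) and `non_recovery`, and the full
#'   ranked table `all`.
#' @export
rank_features <- function(fstats, top_k = 10L, alpha = 0.05,
                          min_cases = 5L, type = "both") {
  if (is.null(fstats$stats$p_value)) {
    stop("p-values missing; run permutation_pvalues() first")
  }
  s <- fstats$stats
  if (type != "both") s <- s[s$type == type, , drop = FALSE]
  s <- s[s$n_cases_present >= min_cases, , drop = FALSE]
  s$diff <- s$weighted_freq_pos - s$weighted_freq_neg
  s <- s[order(s$p_value, -abs(s$diff), s$feature, method = "radix"), ,
         drop = FALSE]
  s$rank <- seq_len(nrow(s))
  rownames(s) <- NULL
  rec <- s[s$diff > 0, , drop = FALSE]
  non <- s[s$diff < 0, , drop = FALSE]
  structure(
    list(recovery = head(rec, top_k), non_recovery = head(non, top_k),
         all = s, alpha = alpha, min_cases = min_cases,
         n_perm = fstats$n_perm),
    class = "cg_feature_ranking"
  )
}

#' @export
print.cg_feature_ranking <- function(x, ...) {
  cat("Top features enriched in EF recovery:\n")
  print(x$recovery[c("feature", "weighted_freq_pos", "weighted_freq_neg",
                     "ratio", "p_value")], row.names = FALSE)
  cat("\nTop features enriched in EF non-recovery:\n")
  print(x$non_recovery[c("feature", "weighted_freq_pos", "weighted_freq_neg",
                         "ratio", "p_value")], row.names = FALSE)
  invisible(x)
}
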