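#' Classify the one-year erectile function outcome from SHIM responses
#'
#' Intact erectile function one year after surgery is defined as a total
#' Sexual Health Inventory for Men (SHIM) score of at least 17, or a score
#' of at least 4 on SHIM question 2 (erection firmness). The rule is
#' monotone non-decreasing in both arguments.
#'
#' @param shim_total integer vector, total SHIM score, 1-25.
#' @param shim_q2 integer vector, SHIM question-2 score, 0-5.
#' @return integer vector of 0/1; 1 means intact EF.
#' @export
#' @examples
#' classify_ef_outcome(17, 2)  # 1: total threshold met
#' classify_ef_outcome(16, 4)  # 1: question-2 threshold met
#' classify_ef_outcome(16, 3)  # 0: neither met
classify_ef_outcome <- function(shim_total, shim_q2) {
  if (length(shim_total) != length(shim_q2)) {
    stop("shim_total and shim_q2 must have equal length")
  }
  if (any(!is.finite(shim_total)) || any(shim_total < 1 | shim_total > 25)) {
    stop("shim_total out of range: values must lie in 1..25")
  }
  if (any(!is.finite(shim_q2)) || any(shim_q2 < 0 | shim_q2 > 5)) {
    stop("shim_q2 out of range: values must lie in 0..5")
  }
  as.integer(shim_total >= 17 | shim_q2 >= 4)
}

CLINICAL_FEATURES <- c("prostate_volume", "age", "bmi", "postop_gleason",
                       "psa", "surgeon_caseload")

#' Construct the clinical feature set of one case
#'
#' The six pre/post-operative covariates the multimodal model can fuse with
#' the gesture sequence: prostate volume (mL), age (years), body mass index
#' (kg/m^2), post-operative Gleason score (ordinal grade), PSA (ng/mL), and
#' the operating surgeon's prior caseload (count of previous cases).
#'
#' @param prostate_volume,age,bmi,postop_gleason,psa,surgeon_caseload
#'   single finite, strictly positive numbers.
#' @return named numeric vector of class `clinical_features`.
#' @export
clinical_features <- function(prostate_volume, age, bmi, postop_gleason,
                              psa, surgeon_caseload) {
  x <- c(prostate_volume = prostate_volume, age = age, bmi = bmi,
         postop_gleason = postop_gleason, psa = psa,
         surgeon_caseload = surgeon_caseload)
  if (any(!is.finite(x))) {
    stop("clinical feature '", names(x)[!is.finite(x)][1L], "' is not finite")
  }
  if (any(x <= 0)) {
    stop("clinical feature '", names(x)[x <= 0][1L],
         "' must be strictly positive")
  }
  structure(x, class = c("clinical_features", "numeric"))
}

#' Construct a single case record
#'
#' One surgery: the ordered contextualized-gesture sequence of its
#' nerve-sparing step, clinical covariates, SHIM responses, and derived
#' binary EF outcome.
#'
#' @param case_id,site_id,surgeon_id identifier strings.
#' @param sequence data.frame with character columns `gesture`, `anatomy`,
#'   `function` (one row per gesture, in temporal order). An optional
#'   `ordinal` column (0-based, contiguous) is validated if present.
#' @param clinical a [clinical_features()] vector.
#' @param shim_total,shim_q2 SHIM responses used to derive the outcome.
#' @return an object of class `case_record`.
#' @export
case_record <- function(case_id, sequence, clinical, shim_total, shim_q2,
                        site_id = "site1", surgeon_id = "surg1") {
  stopifnot(is.data.frame(sequence))
  need <- c("gesture", "anatomy", "function")
  if (!all(need %in% names(sequence))) {
    stop("sequence must have columns gesture, anatomy, function")
  }
  if (nrow(sequence) < 1L) stop("sequence must contain at least one gesture")
  if ("ordinal" %in% names(sequence)) {
    if (!identical(as.integer(sequence$ordinal), seq_len(nrow(sequence)) - 1L)) {
      stop("ordinals of case '", case_id,
           "' must be 0..len-1 with no gaps, in order")
    }
  }
  seq_df <- data.frame(
    gesture    = normalize_token(sequence$gesture),
    anatomy    = normalize_token(sequence$anatomy),
    `function` = normalize_token(sequence[["function"]]),
    ordinal    = seq_len(nrow(sequence)) - 1L,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (!inherits(clinical, "clinical_features")) {
    clinical <- do.call(clinical_features, as.list(clinical[CLINICAL_FEATURES]))
  }
  structure(
    list(case_id = as.character(case_id),
         sequence = seq_df,
         clinical = clinical,
         shim_total = as.integer(shim_total),
         shim_q2 = as.integer(shim_q2),
         ef_outcome = classify_ef_outcome(shim_total, shim_q2),
         site_id = as.character(site_id),
         surgeon_id = as.character(surgeon_id)),
    class = "case_record"
  )
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record %s: %d gestures, EF outcome %d>\n",
              x$case_id, nrow(x$sequence), x$ef_outcome))
  invisible(x)
}

#' Bundle case records and vocabularies into a cohort dataset
#'
#' The unit every stage of the pipeline consumes. Vocabularies default to
#' those built from the records themselves; every sequence token must be a
#' member of its channel vocabulary.
#'
#' @param records list of `case_record` objects with unique `case_id`s.
#' @param vocabularies optional named list of the three channel
#'   vocabularies (see [build_vocabulary()]).
#' @return an object of class `cohort_dataset` with elements `records` and
#'   `vocabularies`.
#' @export
cohort_dataset <- function(records, vocabularies = NULL) {
  stopifnot(is.list(records))
  if (length(records) > 0L) {
    ids <- vapply(records, function(r) r$case_id, character(1))
    if (anyDuplicated(ids)) {
      stop("duplicate case_id: ", ids[duplicated(ids)][1L])
    }
    names(records) <- ids
    if (is.null(vocabularies)) vocabularies <- build_vocabulary(records)
    for (r in records) {
      for (ch in CHANNELS) token_id(vocabularies[[ch]], r$sequence[[ch]])
    }
  } else if (is.null(vocabularies)) {
    vocabularies <- default_vocabularies()
  }
  structure(list(records = records, vocabularies = vocabularies),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  n <- length(x$records)
  pos <- if (n) sum(outcomes(x)) else 0L
  cat(sprintf("<cohort_dataset: %d cases (%d EF-intact), vocab %d/%d/%d>\n",
              n, pos,
              length(x$vocabularies$gesture),
              length(x$vocabularies$anatomy),
              length(x$vocabularies$`function`)))
  invisible(x)
}

#' @export
length.cohort_dataset <- function(x) length(x$records)

#' Outcome labels of a cohort
#' @param dataset a `cohort_dataset`.
#' @return named integer vector of 0/1 EF outcomes.
#' @export
outcomes <- function(dataset) {
  vapply(dataset$records, function(r) r$ef_outcome, integer(1))
}

#' Clinical feature matrix of a cohort
#' @param dataset a `cohort_dataset`.
#' @return numeric matrix, one row per case, columns in the canonical
#'   clinical-feature order.
#' @export
clinical_matrix <- function(dataset) {
  m <- t(vapply(dataset$records,
                function(r) as.numeric(r$clinical[CLINICAL_FEATURES]),
                numeric(length(CLINICAL_FEATURES))))
  colnames(m) <- CLINICAL_FEATURES
  m
}

#' Subset a cohort by case index or id
#' @param dataset a `cohort_dataset`.
#' @param i integer or character index of cases.
#' @return a `cohort_dataset` sharing the parent's vocabularies.
#' @export
subset_cohort <- function(dataset, i) {
  structure(list(records = dataset$records[i],
                 vocabularies = dataset$vocabularies),
            class = "cohort_dataset")
}
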