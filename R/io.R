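ANNOT_COLS <- c("case_id", "ordinal", "gesture", "anatomy", "function")
CASE_COLS <- c("case_id", "site_id", "surgeon_id", CLINICAL_FEATURES,
               "shim_total", "shim_q2")

#' Write a cohort dataset to an annotation directory
#'
#' Serializes a cohort to three plain-text files inside `path`:
#' `annotations.csv` (one row per gesture: case_id, ordinal, gesture,
#' anatomy, function), `cases.csv` (one row per case: identifiers, clinical
#' features, SHIM responses), and `vocabularies.json` (the three channel
#' token lists). The serialization is canonical — writing, reading and
#' re-writing a dataset yields byte-identical files.
#'
#' @param dataset a [cohort_dataset()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  recs <- dataset$records
  if (length(recs) > 0L) {
    ann <- do.call(rbind, lapply(recs, function(r) {
      data.frame(case_id = r$case_id,
                 ordinal = r$sequence$ordinal,
                 gesture = r$sequence$gesture,
                 anatomy = r$sequence$anatomy,
                 `function` = r$sequence[["function"]],
                 check.names = FALSE, stringsAsFactors = FALSE)
    }))
    cases <- do.call(rbind, lapply(recs, function(r) {
      cbind(data.frame(case_id = r$case_id, site_id = r$site_id,
                       surgeon_id = r$surgeon_id, stringsAsFactors = FALSE),
            as.data.frame(as.list(r$clinical[CLINICAL_FEATURES])),
            data.frame(shim_total = r$shim_total, shim_q2 = r$shim_q2))
    }))
  } else {
    ann <- as.data.frame(setNames(rep(list(character(0)), 5), ANNOT_COLS),
                         check.names = FALSE)
    cases <- as.data.frame(setNames(rep(list(character(0)), length(CASE_COLS)),
                                    CASE_COLS), check.names = FALSE)
  }
  write.csv(ann, file.path(path, "annotations.csv"),
            row.names = FALSE, quote = TRUE)
  write.csv(cases, file.path(path, "cases.csv"),
            row.names = FALSE, quote = TRUE)
  vocabs <- lapply(dataset$vocabularies, function(v) v$tokens)
  jsonlite::write_json(vocabs, file.path(path, "vocabularies.json"),
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort dataset from an annotation directory
#'
#' Inverse of [write_annotations()]. Validates the tabular dialect: required
#' columns present, no duplicate (case_id, ordinal) pairs, ordinals
#' contiguous from 0 within each case. Parse errors name the offending row.
#'
#' @param path directory containing `annotations.csv`, `cases.csv` and
#'   (optionally) `vocabularies.json`.
#' @return a [cohort_dataset()].
#' @export
read_annotations <- function(path) {
  ann_file <- file.path(path, "annotations.csv")
  case_file <- file.path(path, "cases.csv")
  if (!file.exists(ann_file)) stop("missing annotation file: ", ann_file)
  if (!file.exists(case_file)) stop("missing case file: ", case_file)
  ann <- read.csv(ann_file, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = c(case_id = "character"))
  cases <- read.csv(case_file, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = c(case_id = "character",
                                   site_id = "character",
                                   surgeon_id = "character"))
  miss <- setdiff(ANNOT_COLS, names(ann))
  if (length(miss)) stop("annotations.csv is missing required column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(CASE_COLS, names(cases))
  if (length(miss)) stop("cases.csv is missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(ann) > 0L) {
    dup <- duplicated(ann[c("case_id", "ordinal")])
    if (any(dup)) {
      stop("duplicate (case_id, ordinal) pair at annotations.csv row ",
           which(dup)[1L] + 1L)  # +1 for header line
    }
  }
  vocab_file <- file.path(path, "vocabularies.json")
  vocabularies <- NULL
  if (file.exists(vocab_file)) {
    toks <- jsonlite::read_json(vocab_file, simplifyVector = TRUE)
    vocabularies <- list(
      gesture = vocabulary(toks$gesture, "gesture"),
      anatomy = vocabulary(toks$anatomy, "anatomy"),
      `function` = vocabulary(toks$`function`, "function")
    )
  }
  if (nrow(cases) == 0L) {
    return(cohort_dataset(list(), vocabularies = vocabularies))
  }
  ann_by_case <- split(ann, factor(ann$case_id, levels = cases$case_id))
  records <- lapply(seq_len(nrow(cases)), function(i) {
    row <- cases[i, ]
    seq_df <- ann_by_case[[row$case_id]]
    if (is.null(seq_df) || nrow(seq_df) == 0L) {
      stop("case '", row$case_id, "' (cases.csv row ", i + 1L,
           ") has no annotation rows")
    }
    seq_df <- seq_df[order(seq_df$ordinal), , drop = FALSE]
    if (!identical(as.integer(seq_df$ordinal), seq_len(nrow(seq_df)) - 1L)) {
      stop("non-contiguous ordinals for case '", row$case_id,
           "' near annotations.csv row ",
           as.integer(rownames(seq_df)[1L]) + 1L)
    }
    case_record(
      case_id = row$case_id,
      sequence = seq_df[c("gesture", "anatomy", "function", "ordinal")],
      clinical = do.call(clinical_features, as.list(row[CLINICAL_FEATURES])),
      shim_total = row$shim_total, shim_q2 = row$shim_q2,
      site_id = row$site_id, surgeon_id = row$surgeon_id
    )
  })
  cohort_dataset(records, vocabularies = vocabularies)
}
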