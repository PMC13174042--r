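#' Token normalization for annotation files
#'
#' Annotation tables are hand-generated upstream; tokens are lower-cased,
#' trimmed, and internal whitespace is collapsed to a single space.
#' Compound tokens such as `"peel/push"` are kept as single tokens.
#'
#' @param x character vector of raw tokens.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_token(c("  Cold  Cut ", "Peel/Push"))
normalize_token <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

CHANNELS <- c("gesture", "anatomy", "function")

#' Construct a channel vocabulary
#'
#' A vocabulary maps token strings of one annotation channel (gesture,
#' anatomy, or function) to contiguous integer ids. Ids 0 and 1 are reserved
#' for the PAD and CLS tokens; content tokens start at id 2. Tokens are
#' stored sorted lexicographically so that vocabulary construction is
#' deterministic and independent of record order.
#'
#' @param tokens character vector of (possibly repeated) content tokens.
#' @param channel one of `"gesture"`, `"anatomy"`, `"function"`.
#' @return an object of class `cg_vocabulary` with elements `channel`,
#'   `tokens` (sorted unique content tokens), `index` (named integer vector
#'   token -> id), `pad_id` (0) and `cls_id` (1).
#' @export
vocabulary <- function(tokens, channel) {
  channel <- match.arg(channel, CHANNELS)
  if (length(tokens) == 0L) {
    stop("cannot build a '", channel, "' vocabulary from zero tokens")
  }
  tokens <- sort(unique(normalize_token(tokens)), method = "radix")
  if (any(tokens %in% RESERVED_TOKENS)) {
    stop("content tokens may not use the reserved names ",
         paste(RESERVED_TOKENS, collapse = ", "))
  }
  index <- setNames(seq_along(tokens) + 1L, tokens)  # content ids start at 2
  structure(
    list(channel = channel, tokens = tokens, index = index,
         pad_id = PAD_ID, cls_id = CLS_ID),
    class = "cg_vocabulary"
  )
}

#' @export
print.cg_vocabulary <- function(x, ...) {
  cat(sprintf("<cg_vocabulary: %s, %d tokens (+PAD,+CLS)>\n",
              x$channel, length(x$tokens)))
  invisible(x)
}

#' @export
length.cg_vocabulary <- function(x) length(x$tokens)

#' Number of embedding rows needed for a vocabulary (content tokens only)
#' @param vocab a `cg_vocabulary`.
#' @return integer count of content tokens.
#' @keywords internal
vocab_size <- function(vocab) length(vocab$tokens)

#' Look up token ids in a vocabulary
#' @param vocab a `cg_vocabulary`.
#' @param tokens character vector.
#' @return integer ids.
#' @keywords internal
token_id <- function(vocab, tokens) {
  ids <- unname(vocab$index[normalize_token(tokens)])
  if (anyNA(ids)) {
    bad <- tokens[is.na(ids)][1L]
    stop("token '", bad, "' is not in the ", vocab$channel, " vocabulary")
  }
  ids
}

#' Recover token strings from ids
#' @param vocab a `cg_vocabulary`.
#' @param ids integer ids (content ids only, >= 2).
#' @return character tokens.
#' @keywords internal
id_token <- function(vocab, ids) {
  if (any(ids < 2L | ids > length(vocab$tokens) + 1L)) {
    stop("id out of content range for ", vocab$channel, " vocabulary")
  }
  vocab$tokens[ids - 1L]
}

#' Build the three channel vocabularies from a list of case records
#'
#' Scans every record's sequence and returns deterministic, lexicographically
#' sorted vocabularies. Permuting the input records yields identical
#' vocabularies.
#'
#' @param records list of `case_record` objects.
#' @param channel one of `"gesture"`, `"anatomy"`, `"function"`; or
#'   `"all"` (default) for a named list of all three.
#' @return a `cg_vocabulary`, or a named list of the three.
#' @export
build_vocabulary <- function(records, channel = "all") {
  if (length(records) == 0L) stop("cannot build vocabularies from an empty record list")
  if (identical(channel, "all")) {
    out <- lapply(CHANNELS, function(ch) build_vocabulary(records, ch))
    names(out) <- CHANNELS
    return(out)
  }
  channel <- match.arg(channel, CHANNELS)
  toks <- unlist(lapply(records, function(r) r$sequence[[channel]]),
                 use.names = FALSE)
  vocabulary(toks, channel)
}

#' Default vocabularies for the nerve-sparing gesture annotation scheme
#'
#' Gesture, anatomy and function token sets covering the actions named in
#' the annotation scheme this package models: discrete surgical gestures
#' (peel/push, cold cut, hot cut, spread, retraction, coagulate, camera
#' move, assistant move), the anatomic structures of the nerve-sparing
#' dissection, and the functional purposes of gestures. Assistant actions
#' are a single `"assistant move"` token without sub-typing. All token sets
#' are fully configurable; these defaults are what [default_sim_config()]
#' simulates over.
#'
#' @return named list of three `cg_vocabulary` objects.
#' @export
default_vocabularies <- function() {
  list(
    gesture  = vocabulary(c("peel/push", "cold cut", "hot cut", "spread",
                            "retraction", "coagulate", "camera move",
                            "assistant move"), "gesture"),
    anatomy  = vocabulary(c("lateral fascia", "prostatic pedicle",
                            "posterior plane", "neurovascular bundle"),
                          "anatomy"),
    `function` = vocabulary(c("release neurovascular bundle",
                              "extension of posterior plane",
                              "hemostasis", "exposure"), "function")
  )
}
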