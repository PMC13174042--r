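#' Encode a case record as an id matrix for the sequence model
#'
#' Builds the (L+1) x d token-id matrix the transformer consumes: row 1 is
#' the CLS token (id 1 in every channel), row i+1 holds the ids of the i-th
#' contextualized gesture for each active channel. `d` equals the number of
#' active channels; with `channels = "gesture"` only, d = 1; with all three
#' channels, d = 3.
#'
#' @param record a [case_record()].
#' @param vocabularies named list of channel vocabularies.
#' @param channels character subset of `c("gesture", "anatomy", "function")`.
#' @return an object of class `token_sequence`: list with `ids`
#'   ((L+1) x d integer matrix), `channels`, and `attention_mask` (logical,
#'   TRUE for content and CLS positions; all TRUE here, PAD appears only
#'   when sequences are padded to a common length).
#' @export
encode_sequence <- function(record, vocabularies,
                            channels = c("gesture", "anatomy", "function")) {
  channels <- match.arg(channels, CHANNELS, several.ok = TRUE)
  L <- nrow(record$sequence)
  ids <- matrix(CLS_ID, nrow = L + 1L, ncol = length(channels),
                dimnames = list(NULL, channels))
  for (ch in channels) {
    toks <- record$sequence[[ch]]
    ok <- normalize_token(toks) %in% names(vocabularies[[ch]]$index)
    if (!all(ok)) {
      pos <- which(!ok)[1L]
      stop("unknown token '", toks[pos], "' in channel '", ch,
           "' at position ", pos - 1L, " of case '", record$case_id, "'")
    }
    ids[-1L, ch] <- token_id(vocabularies[[ch]], toks)
  }
  structure(list(ids = ids, channels = channels,
                 attention_mask = rep(TRUE, L + 1L)),
            class = "token_sequence")
}

#' Decode a token-sequence back to token strings
#'
#' Inverse of [encode_sequence()] on the content rows: recovers the original
#' token strings for every active channel. PAD rows (id 0) are dropped.
#'
#' @param tokens a `token_sequence`.
#' @param vocabularies named list of channel vocabularies.
#' @return data.frame with one column per active channel.
#' @export
decode_sequence <- function(tokens, vocabularies) {
  ids <- tokens$ids
  content <- ids[, 1L] != CLS_ID | seq_len(nrow(ids)) > 1L
  content <- content & ids[, 1L] != PAD_ID
  content[1L] <- FALSE  # CLS row
  out <- lapply(tokens$channels, function(ch) {
    id_token(vocabularies[[ch]], ids[content, ch])
  })
  names(out) <- tokens$channels
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Pad a token sequence to a fixed length
#'
#' Appends PAD rows (id 0 in every channel) and extends the attention mask
#' with FALSE. Model forward passes are invariant to padding.
#'
#' @param tokens a `token_sequence`.
#' @param total_len target number of rows (including CLS).
#' @return a `token_sequence` of `total_len` rows.
#' @export
pad_sequence <- function(tokens, total_len) {
  n <- nrow(tokens$ids)
  if (total_len < n) stop("total_len shorter than the sequence")
  if (total_len == n) return(tokens)
  extra <- total_len - n
  tokens$ids <- rbind(tokens$ids,
                      matrix(PAD_ID, nrow = extra, ncol = ncol(tokens$ids)))
  tokens$attention_mask <- c(tokens$attention_mask, rep(FALSE, extra))
  tokens
}
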