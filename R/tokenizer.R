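# Minimal whitespace/punctuation tokenizer for structured variant captions.
# Punctuation (JSON braces, quotes, commas, colons) acts as a delimiter and is
# not emitted; word characters, underscores, dots and hyphens stay inside one
# token, so consequence labels like "missense_variant" are single tokens.

#' Tokenize caption text
#'
#' @param text character scalar.
#' @return character vector of tokens (possibly empty).
#' @export
vq_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(text, "[^A-Za-z0-9_.-]+")[[1]]
  toks[nzchar(toks)]
}

#' Build a vocabulary over a token corpus
#'
#' Ids 1..4 are reserved for `<pad>`, `<bos>`, `<eos>`, `<unk>`; remaining
#' tokens are sorted for determinism.
#'
#' @param corpus character vector of raw texts (tokenized internally).
#' @return a `vq_vocab` object (named integer vector token -> id).
#' @export
vq_vocab <- function(corpus) {
  # radix = C-locale byte order, so the vocabulary (and hence every token
  # id) is identical whatever the session locale
  toks <- sort(unique(unlist(lapply(corpus, vq_tokenize))), method = "radix")
  ids <- seq_len(4L + length(toks))
  names(ids) <- c("<pad>", "<bos>", "<eos>", "<unk>", toks)
  structure(ids, class = "vq_vocab")
}

#' @rdname vq_vocab
#' @param vocab a `vq_vocab`.
#' @param text character scalar to encode.
#' @param add_bos,add_eos prepend/append the sentence markers.
#' @return integer token ids.
#' @export
vq_encode <- function(vocab, text, add_bos = FALSE, add_eos = FALSE) {
  toks <- vq_tokenize(text)
  ids <- unname(vocab[toks])
  ids[is.na(ids)] <- vocab[["<unk>"]]
  c(if (add_bos) vocab[["<bos>"]], ids, if (add_eos) vocab[["<eos>"]])
}

#' @rdname vq_vocab
#' @param ids integer token ids.
#' @export
vq_decode <- function(vocab, ids) {
  names(vocab)[ids]
}
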