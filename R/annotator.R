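#' Linguistic annotation of raw sentence text
#'
#' The corpus model stores, for every token, its surface form, lemma, coarse
#' part-of-speech tag, orthographic class and character span. An *annotator*
#' is any function that maps a sentence string to such a token table, so the
#' preprocessing chain is pluggable. The bundled default is deliberately
#' simple and fully deterministic: tokens are maximal alphanumeric runs or
#' single non-space characters, lemmas are case-folded surface forms, and
#' POS tags come from a small closed-class lookup plus suffix heuristics.
#'
#' @param text a single sentence string.
#' @return A tibble with one row per token and columns `text`, `lemma`,
#'   `pos`, `ortho`, `start`, `end`. Character offsets are 0-based,
#'   half-open, relative to the sentence.
#'
#' @details Orthographic classes are `ALPHA_LOWER`, `ALPHA_CAP` (initial
#' capital), `ALPHA_MIXED`, `DIGIT`, `ALNUM`, `PUNCT` and `OTHER`. The POS
#' tagset is coarse (`NOUN`, `VERB`, `ADJ`, `ADV`, `DET`, `ADP`, `CONJ`,
#' `PRON`, `NUM`, `PUNCT`, `X`): rich enough for the local-context kernel
#' features, with no claim of linguistic fidelity. Swap in a better
#' annotator via the `annotator` argument of [read_corpus()] if one is
#' available.
#'
#' @examples
#' default_annotator("Niacin maculopathy was observed.")
#' @export
default_annotator <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(
      text = character(), lemma = character(), pos = character(),
      ortho = character(), start = integer(), end = integer()
    ))
  }
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9 \t\r\n]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble(
      text = character(), lemma = character(), pos = character(),
      ortho = character(), start = integer(), end = integer()
    ))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  tok <- substring(text, start + 1L, end)
  tibble(
    text = tok,
    lemma = tolower(tok),
    pos = .pos_tag(tok),
    ortho = .ortho_class(tok),
    start = start,
    end = end
  )
}

.CLOSED_CLASS <- c(
  the = "DET", a = "DET", an = "DET", this = "DET", that = "DET",
  his = "DET", her = "DET", its = "DET", their = "DET",
  of = "ADP", "in" = "ADP", on = "ADP", at = "ADP", by = "ADP",
  with = "ADP", without = "ADP", after = "ADP", before = "ADP",
  during = "ADP", following = "ADP", to = "ADP", "for" = "ADP",
  from = "ADP", under = "ADP", despite = "ADP",
  and = "CONJ", or = "CONJ", but = "CONJ", "while" = "CONJ",
  he = "PRON", she = "PRON", it = "PRON", they = "PRON", who = "PRON",
  is = "VERB", are = "VERB", was = "VERB", were = "VERB", be = "VERB",
  been = "VERB", has = "VERB", have = "VERB", had = "VERB", did = "VERB",
  not = "ADV", also = "ADV", later = "ADV", then = "ADV"
)

.pos_tag <- function(tok) {
  low <- tolower(tok)
  out <- unname(.CLOSED_CLASS[low])
  out[is.na(out) & grepl("^[0-9]+$", tok)] <- "NUM"
  out[is.na(out) & grepl("^[^A-Za-z0-9]$", tok)] <- "PUNCT"
  idx <- is.na(out)
  out[idx & grepl("ly$", low) & nchar(low) > 3L] <- "ADV"
  idx <- is.na(out)
  out[idx & grepl("(ed|ing)$", low) & nchar(low) > 4L] <- "VERB"
  idx <- is.na(out)
  out[idx & grepl("(ous|ive|al|ic|able|severe|acute|mild)$", low) &
        nchar(low) > 4L] <- "ADJ"
  out[is.na(out) & grepl("^[A-Za-z]", tok)] <- "NOUN"
  out[is.na(out)] <- "X"
  out
}

.ortho_class <- function(tok) {
  out <- character(length(tok))
  out[grepl("^[a-z]+$", tok)] <- "ALPHA_LOWER"
  out[grepl("^[A-Z][a-z]*$", tok)] <- "ALPHA_CAP"
  idx <- !nzchar(out) & grepl("^[A-Za-z]+$", tok)
  out[idx] <- "ALPHA_MIXED"
  out[!nzchar(out) & grepl("^[0-9]+$", tok)] <- "DIGIT"
  out[!nzchar(out) & grepl("^[A-Za-z0-9]+$", tok)] <- "ALNUM"
  out[!nzchar(out) & grepl("^[^A-Za-z0-9]+$", tok) &
        grepl("[[:punct:]]", tok)] <- "PUNCT"
  out[!nzchar(out)] <- "OTHER"
  out
}
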