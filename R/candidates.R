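#' Enumerate drug-condition candidate pairs in a sentence
#'
#' Every (drug mention, condition mention) pair co-occurring in one sentence
#' is a relation candidate, regardless of provenance: machine-tagged
#' mentions participate on equal footing with human annotation, which is
#' exactly how negative training pairs arise from unannotated
#' co-occurrences. Candidates are keyed by character offsets, so two
#' mentions of the same surface string are distinct candidates.
#'
#' @param sentence a sentence from [ade_sentence()].
#' @param doc_id document id used to build stable instance ids.
#' @return A tibble with one row per pair (|drugs| x |conditions| rows),
#'   label `UNKNOWN`, ordered by (drug start, condition start). Carries the
#'   mention spans (character and token), normalized ids, provenance and a
#'   `tokens` list-column holding the sentence token table augmented with
#'   an `ent` column (`DRUG`/`CONDITION`/`O`) marking membership in any
#'   mention.
#' @export
enumerate_candidates <- function(sentence, doc_id = "doc") {
  men <- sentence$mentions
  d <- which(men$etype == "DRUG")
  co <- which(men$etype == "CONDITION")
  if (!length(d) || !length(co)) return(.empty_candidates())
  toks <- .tokens_with_ent(sentence)
  grid <- expand.grid(di = d, ci = co, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(men$start[grid$di], men$start[grid$ci]), ]
  map_dfr(seq_len(nrow(grid)), function(k) {
    dm <- men[grid$di[k], ]
    cm <- men[grid$ci[k], ]
    tibble(
      doc_id = doc_id, sid = sentence$sid,
      instance_id = sprintf("%s.%s.d%d.c%d", doc_id, sentence$sid,
                            dm$start, cm$start),
      label = "UNKNOWN",
      drug_text = substring(sentence$text, dm$start + 1L, dm$end),
      cond_text = substring(sentence$text, cm$start + 1L, cm$end),
      drug_id = dm$norm_id, cond_id = cm$norm_id,
      drug_provenance = dm$provenance, cond_provenance = cm$provenance,
      drug_start = dm$start, drug_end = dm$end,
      cond_start = cm$start, cond_end = cm$end,
      drug_tok_start = dm$tok_start, drug_tok_end = dm$tok_end,
      cond_tok_start = cm$tok_start, cond_tok_end = cm$tok_end,
      tokens = list(toks)
    )
  })
}

.tokens_with_ent <- function(sentence) {
  toks <- sentence$tokens
  ent <- rep("O", nrow(toks))
  men <- sentence$mentions
  for (i in seq_len(nrow(men))) {
    idx <- seq.int(men$tok_start[i], men$tok_end[i] - 1L)
    ent[idx] <- men$etype[i]
  }
  toks$ent <- ent
  toks
}

.empty_candidates <- function() {
  tibble(
    doc_id = character(), sid = character(), instance_id = character(),
    label = character(), drug_text = character(), cond_text = character(),
    drug_id = character(), cond_id = character(),
    drug_provenance = character(), cond_provenance = character(),
    drug_start = integer(), drug_end = integer(),
    cond_start = integer(), cond_end = integer(),
    drug_tok_start = integer(), drug_tok_end = integer(),
    cond_tok_start = integer(), cond_tok_end = integer(),
    tokens = list()
  )
}

#' Label candidate pairs against gold relations
#'
#' A candidate whose (drug, condition) mention pair appears in the gold set
#' becomes `TRUE`; every other candidate becomes `FALSE`. No `UNKNOWN`
#' label survives.
#'
#' @param cands candidate tibble from [enumerate_candidates()].
#' @param gold tibble with columns `doc_id`, `sid`, `drug_start`,
#'   `cond_start` identifying gold pairs by mention character starts.
#' @return `cands` with the `label` column filled in.
#' @export
label_candidates <- function(cands, gold) {
  key <- function(df) {
    paste(df$doc_id, df$sid, df$drug_start, df$cond_start, sep = "\r")
  }
  cands$label <- "FALSE"
  if (!is.null(gold) && nrow(gold)) {
    gk <- key(gold)
    hit <- gk %in% key(cands)
    if (!all(hit)) {
      abort(paste0("gold relation without matching candidate: ",
                   gold$doc_id[!hit][1], "/", gold$sid[!hit][1]))
    }
    cands$label[key(cands) %in% gk] <- "TRUE"
  }
  cands
}

#' Drop nested gold relations
#'
#' Gold relations whose drug and condition character spans intersect (the
#' classic case: a drug name embedded inside the condition phrase, as in
#' "acute lithium toxicity") are unusable for pair classification and are
#' removed. The mentions themselves are retained; only the relation is
#' dropped. Span intersection subsumes strict containment of one member in
#' the other.
#'
#' @param corpus an [ade_corpus()].
#' @return `list(corpus = cleaned corpus, removed = count of dropped
#'   relations)`.
#' @export
remove_nested <- function(corpus) {
  removed <- 0L
  docs <- map(corpus$documents, function(d) {
    if (!nrow(d$relations)) return(d)
    keep <- map_lgl(seq_len(nrow(d$relations)), function(i) {
      r <- d$relations[i, ]
      s <- d$sentences[[r$sid]]
      dm <- s$mentions[r$drug_idx, ]
      cm <- s$mentions[r$cond_idx, ]
      dm$start >= cm$end || cm$start >= dm$end
    })
    removed <<- removed + sum(!keep)
    d$relations <- d$relations[keep, ]
    d
  })
  list(corpus = ade_corpus(docs, name = corpus$name), removed = removed)
}

#' Build the labelled pair dataset from a corpus
#'
#' Composition of [remove_nested()], [enumerate_candidates()] and
#' [label_candidates()] over all sentences: the full training/evaluation
#' dataset of sentence-level drug-condition pairs. Deterministic: document
#' order, sentence order, then (drug start, condition start) within a
#' sentence; instance ids are offset-derived.
#'
#' @param corpus an [ade_corpus()], typically after [annotate_corpus()].
#' @param drop_nested apply [remove_nested()] first (default `TRUE`).
#' @return A labelled candidate tibble; `|TRUE| + |FALSE| = nrow`.
#' @export
build_dataset <- function(corpus, drop_nested = TRUE) {
  if (drop_nested) corpus <- remove_nested(corpus)$corpus
  out <- map_dfr(corpus$documents, function(d) {
    gold <- if (nrow(d$relations)) {
      map_dfr(seq_len(nrow(d$relations)), function(i) {
        r <- d$relations[i, ]
        s <- d$sentences[[r$sid]]
        tibble(doc_id = d$doc_id, sid = r$sid,
               drug_start = s$mentions$start[r$drug_idx],
               cond_start = s$mentions$start[r$cond_idx])
      })
    } else NULL
    map_dfr(d$sentences, function(s) {
      cands <- enumerate_candidates(s, doc_id = d$doc_id)
      if (!nrow(cands)) return(NULL)
      g <- if (!is.null(gold)) gold[gold$sid == s$sid, ] else NULL
      label_candidates(cands, g)
    })
  })
  if (!nrow(out)) return(.empty_candidates())
  out
}
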