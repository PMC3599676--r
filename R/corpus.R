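#' Annotated case-report corpora
#'
#' An `ade_corpus` holds a collection of documents (PMID-like ids), each a
#' list of sentences carrying tokens, typed entity mentions (drugs and
#' conditions, with provenance `HUMAN` or `MACHINE` and an optional
#' normalized identifier), and gold adverse-event relations between a drug
#' mention and a condition mention of the same sentence. All character
#' offsets are 0-based and half-open, relative to the sentence text.
#'
#' @param documents list of documents built with [ade_document()].
#' @param name corpus name.
#' @return An object of class `ade_corpus`.
#' @seealso [read_corpus()], [write_corpus()], [corpus_stats()]
#' @export
ade_corpus <- function(documents = list(), name = "corpus") {
  ids <- map_chr(documents, "doc_id")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate doc_id: ", ids[duplicated(ids)][1]))
  }
  structure(list(name = name, documents = documents), class = "ade_corpus")
}

#' @export
print.ade_corpus <- function(x, ...) {
  ns <- sum(map_int(x$documents, ~ length(.x$sentences)))
  cat("<ade_corpus> ", x$name, ": ", length(x$documents), " documents, ",
      ns, " sentences\n", sep = "")
  invisible(x)
}

#' @export
length.ade_corpus <- function(x) length(x$documents)

#' Construct a document
#'
#' @param doc_id document identifier (PMID-like string), unique in a corpus.
#' @param sentences list of sentences from [ade_sentence()].
#' @param relations tibble with columns `sid`, `drug_idx`, `cond_idx`; the
#'   indices are 1-based row numbers into the mention table of sentence
#'   `sid` and must point at a `DRUG` and a `CONDITION` mention
#'   respectively.
#' @return A document list suitable for [ade_corpus()].
#' @export
ade_document <- function(doc_id, sentences = list(), relations = NULL) {
  if (is.null(relations)) {
    relations <- tibble(sid = character(), drug_idx = integer(),
                        cond_idx = integer())
  }
  relations <- as_tibble(relations)
  sids <- map_chr(sentences, "sid")
  if (anyDuplicated(sids)) {
    abort(paste0("doc ", doc_id, ": duplicate sid ",
                 sids[duplicated(sids)][1]))
  }
  names(sentences) <- sids
  if (nrow(relations)) {
    for (i in seq_len(nrow(relations))) {
      r <- relations[i, ]
      s <- sentences[[r$sid]]
      if (is.null(s)) {
        abort(paste0("doc ", doc_id, ": relation references unknown sid '",
                     r$sid, "'"))
      }
      for (fld in c("drug_idx", "cond_idx")) {
        k <- r[[fld]]
        if (is.na(k) || k < 1L || k > nrow(s$mentions)) {
          abort(paste0("doc ", doc_id, " sid ", r$sid,
                       ": relation field ", fld, " out of range"))
        }
      }
      if (s$mentions$etype[r$drug_idx] != "DRUG" ||
          s$mentions$etype[r$cond_idx] != "CONDITION") {
        abort(paste0("doc ", doc_id, " sid ", r$sid,
                     ": relation mention types must be DRUG and CONDITION"))
      }
    }
  }
  list(doc_id = doc_id, sentences = sentences, relations = relations)
}

#' Construct an annotated sentence
#'
#' Tokenizes `text` with `annotator`, validates the mention table against
#' the sentence and attaches covering token index ranges (1-based,
#' half-open) to every mention.
#'
#' @param sid sentence identifier, unique in its document.
#' @param text raw sentence text.
#' @param mentions tibble with columns `etype` (`DRUG`/`CONDITION`),
#'   `start`, `end` (0-based half-open character span), `norm_id`
#'   (identifier string or `NA`), `provenance` (`HUMAN`/`MACHINE`).
#' @param annotator tokenizer/tagger function, see [default_annotator()].
#' @return A sentence list with `tokens` and a validated `mentions` table.
#' @export
ade_sentence <- function(sid, text, mentions = NULL,
                         annotator = default_annotator) {
  tokens <- annotator(text)
  if (is.null(mentions) || nrow(mentions) == 0L) {
    mentions <- tibble(etype = character(), start = integer(),
                       end = integer(), norm_id = character(),
                       provenance = character())
  }
  mentions <- as_tibble(mentions)
  if (!"norm_id" %in% names(mentions)) mentions$norm_id <- NA_character_
  if (!"provenance" %in% names(mentions)) mentions$provenance <- "HUMAN"
  mentions <- mentions[order(mentions$start, mentions$end), ]
  mentions <- .attach_token_spans(sid, text, tokens, mentions)
  .check_mention_overlap(sid, mentions)
  list(sid = sid, text = text, tokens = tokens, mentions = mentions)
}

.attach_token_spans <- function(sid, text, tokens, mentions) {
  n <- nchar(text)
  ts <- te <- integer(nrow(mentions))
  for (i in seq_len(nrow(mentions))) {
    m <- mentions[i, ]
    if (!m$etype %in% c("DRUG", "CONDITION")) {
      abort(paste0("sid ", sid, ": bad etype '", m$etype, "'"))
    }
    if (!m$provenance %in% c("HUMAN", "MACHINE")) {
      abort(paste0("sid ", sid, ": bad provenance '", m$provenance, "'"))
    }
    if (is.na(m$start) || is.na(m$end) || m$start < 0L || m$start >= m$end ||
        m$end > n) {
      abort(paste0("sid ", sid, ": mention span [", m$start, ",", m$end,
                   ") outside sentence of length ", n))
    }
    hit <- which(tokens$start < m$end & tokens$end > m$start)
    if (!length(hit)) {
      abort(paste0("sid ", sid, ": mention span matches no token"))
    }
    ts[i] <- hit[1]
    te[i] <- hit[length(hit)] + 1L
  }
  mentions$tok_start <- ts
  mentions$tok_end <- te
  mentions
}

.check_mention_overlap <- function(sid, mentions) {
  for (prov in unique(mentions$provenance)) {
    m <- mentions[mentions$provenance == prov, ]
    if (nrow(m) > 1L && any(m$start[-1] < m$end[-nrow(m)])) {
      abort(paste0("sid ", sid, ": overlapping ", prov, " mentions"))
    }
  }
  invisible(mentions)
}

#' Flatten corpus mentions to a tibble
#'
#' @param corpus an [ade_corpus()].
#' @return One row per entity mention with document and sentence ids,
#'   character and token spans, type, provenance and normalized id.
#' @export
corpus_mentions <- function(corpus) {
  out <- map_dfr(corpus$documents, function(d) {
    map_dfr(d$sentences, function(s) {
      if (!nrow(s$mentions)) return(NULL)
      mutate(s$mentions, doc_id = d$doc_id, sid = s$sid,
             text = substring(s$text, .data$start + 1L, .data$end),
             .before = 1L)
    })
  })
  if (!nrow(out)) {
    out <- tibble(doc_id = character(), sid = character(),
                  text = character(), etype = character(),
                  start = integer(), end = integer(),
                  norm_id = character(), provenance = character(),
                  tok_start = integer(), tok_end = integer())
  }
  out
}

#' Flatten gold relations to a tibble
#'
#' @param corpus an [ade_corpus()].
#' @return One row per gold relation with the referenced mentions' character
#'   spans and surface strings resolved.
#' @export
corpus_relations <- function(corpus) {
  map_dfr(corpus$documents, function(d) {
    if (!nrow(d$relations)) return(NULL)
    map_dfr(seq_len(nrow(d$relations)), function(i) {
      r <- d$relations[i, ]
      s <- d$sentences[[r$sid]]
      dm <- s$mentions[r$drug_idx, ]
      cm <- s$mentions[r$cond_idx, ]
      tibble(
        doc_id = d$doc_id, sid = r$sid,
        drug_idx = r$drug_idx, cond_idx = r$cond_idx,
        drug_start = dm$start, drug_end = dm$end,
        cond_start = cm$start, cond_end = cm$end,
        drug = substring(s$text, dm$start + 1L, dm$end),
        condition = substring(s$text, cm$start + 1L, cm$end)
      )
    })
  })
}

#' Read a corpus from the standoff JSON dialect
#'
#' The on-disk dialect is plain JSON with explicit character offsets:
#' `{"name", "documents": [{"doc_id", "sentences": [{"sid", "text",
#' "mentions": [{"etype","start","end","norm_id","provenance"}]}],
#' "relations": [{"sid","drug_idx","cond_idx"}]}]}` with 0-based half-open
#' spans and 0-based mention indices in relations. Tokenization is applied
#' on read (it is derived data, never serialized).
#'
#' @param path file path.
#' @param annotator tokenizer/tagger, see [default_annotator()].
#' @return An [ade_corpus()]; malformed records raise errors naming the
#'   document and field.
#' @export
read_corpus <- function(path, annotator = default_annotator) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$documents)) abort("standoff JSON: missing 'documents'")
  docs <- map(j$documents, function(jd) {
    if (is.null(jd$doc_id)) abort("standoff JSON: document missing doc_id")
    sents <- map(jd$sentences %||% list(), function(js) {
      for (fld in c("sid", "text")) {
        if (is.null(js[[fld]])) {
          abort(paste0("doc ", jd$doc_id, ": sentence missing ", fld))
        }
      }
      men <- map_dfr(js$mentions %||% list(), function(jm) {
        for (fld in c("etype", "start", "end")) {
          if (is.null(jm[[fld]])) {
            abort(paste0("doc ", jd$doc_id, " sid ", js$sid,
                         ": mention missing ", fld))
          }
        }
        tibble(etype = jm$etype, start = as.integer(jm$start),
               end = as.integer(jm$end),
               norm_id = jm$norm_id %||% NA_character_,
               provenance = jm$provenance %||% "HUMAN")
      })
      tryCatch(
        ade_sentence(js$sid, js$text, men, annotator = annotator),
        error = function(e) {
          abort(paste0("doc ", jd$doc_id, ": ", conditionMessage(e)))
        }
      )
    })
    rel <- map_dfr(jd$relations %||% list(), function(jr) {
      for (fld in c("sid", "drug_idx", "cond_idx")) {
        if (is.null(jr[[fld]])) {
          abort(paste0("doc ", jd$doc_id, ": relation missing ", fld))
        }
      }
      tibble(sid = jr$sid, drug_idx = as.integer(jr$drug_idx) + 1L,
             cond_idx = as.integer(jr$cond_idx) + 1L)
    })
    ade_document(jd$doc_id, sents, rel)
  })
  ade_corpus(docs, name = j$name %||% "corpus")
}

#' Write a corpus in the standoff JSON dialect
#'
#' Produces the canonical serialization: fixed field order, 0-based
#' indices, `null` for absent normalized ids, trailing newline. A
#' write/read/write cycle is byte-identical.
#'
#' @param corpus an [ade_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  docs <- map(corpus$documents, function(d) {
    list(
      doc_id = d$doc_id,
      sentences = map(unname(d$sentences), function(s) {
        list(
          sid = s$sid, text = s$text,
          mentions = map(seq_len(nrow(s$mentions)), function(i) {
            m <- s$mentions[i, ]
            list(etype = m$etype, start = m$start, end = m$end,
                 norm_id = if (is.na(m$norm_id)) NULL else m$norm_id,
                 provenance = m$provenance)
          })
        )
      }),
      relations = map(seq_len(nrow(d$relations)), function(i) {
        r <- d$relations[i, ]
        list(sid = r$sid, drug_idx = r$drug_idx - 1L,
             cond_idx = r$cond_idx - 1L)
      })
    )
  })
  txt <- jsonlite::toJSON(list(name = corpus$name, documents = docs),
                          auto_unbox = TRUE, null = "null", digits = NA)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Tabulate corpus composition
#'
#' Counts documents, drug and condition mentions (as instances, not unique
#' strings), sentences contributing at least one drug-condition candidate
#' pair, and labelled `TRUE`/`FALSE` relations as produced by
#' [build_dataset()].
#'
#' @param corpus an [ade_corpus()].
#' @param drop_nested drop gold relations with overlapping member spans
#'   before counting (see [remove_nested()]); default `TRUE`.
#' @return A one-row tibble with columns `documents`, `drugs`,
#'   `conditions`, `sentences_with_candidates`, `true_relations`,
#'   `false_relations`.
#' @export
corpus_stats <- function(corpus, drop_nested = TRUE) {
  men <- corpus_mentions(corpus)
  ds <- build_dataset(corpus, drop_nested = drop_nested)
  tibble(
    documents = length(corpus$documents),
    drugs = sum(men$etype == "DRUG"),
    conditions = sum(men$etype == "CONDITION"),
    sentences_with_candidates =
      if (nrow(ds)) nrow(distinct(ds, .data$doc_id, .data$sid)) else 0L,
    true_relations = sum(ds$label == "TRUE"),
    false_relations = sum(ds$label == "FALSE")
  )
}
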