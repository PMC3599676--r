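#' Dictionary lexicons for named-entity recognition
#'
#' A lexicon maps surface terms to normalized identifiers (DrugBank-style
#' ids for drugs, MedDRA-style ids for conditions). Keys are case-folded
#' and whitespace-normalized; matching is over token sequences, never raw
#' substrings, so "cin" does not fire inside "niacin".
#'
#' @param terms tibble or data frame with columns `term` and `id`.
#' @param etype entity type the lexicon tags: `"DRUG"` or `"CONDITION"`.
#' @param name lexicon name (e.g. `"drugbank-like"`).
#' @return An object of class `ade_lexicon`: a tibble of `term`, `id` and
#'   the internal match `key`, with `etype`/`name` attributes.
#' @export
ade_lexicon <- function(terms, etype, name = "lexicon") {
  etype <- match.arg(etype, c("DRUG", "CONDITION"))
  terms <- as_tibble(terms)
  stopifnot(all(c("term", "id") %in% names(terms)))
  terms$key <- .lexicon_key(terms$term)
  if (any(!nzchar(terms$key))) abort("lexicon contains an empty term")
  dup <- duplicated(terms$key)
  if (any(dup)) {
    if (anyDuplicated(unique(terms[, c("key", "id")])$key)) {
      warn(paste0("lexicon '", name,
                  "': duplicate terms with conflicting ids; ",
                  "first occurrence wins"))
    }
    terms <- terms[!dup, ]
  }
  structure(terms, class = c("ade_lexicon", class(terms)),
            etype = etype, lexname = name)
}

.lexicon_key <- function(term, normalize_plural = FALSE) {
  map_chr(term, function(t) {
    toks <- tolower(default_annotator(t)$text)
    if (normalize_plural) toks <- .strip_plural(toks)
    paste(toks, collapse = " ")
  })
}

.strip_plural <- function(toks) {
  long <- nchar(toks) > 3L & grepl("s$", toks) & !grepl("ss$", toks)
  toks[long] <- sub("s$", "", toks[long])
  toks
}

#' Load a lexicon from TSV
#'
#' Two tab-separated columns, `term` then `id`, UTF-8, `#` comment lines
#' and blank lines ignored. Synonym rows simply repeat the id; a duplicate
#' term mapped to a different id resolves to the first occurrence with a
#' warning.
#'
#' @param path TSV file path.
#' @inheritParams ade_lexicon
#' @return An [ade_lexicon()].
#' @export
load_lexicon <- function(path, etype, name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep)) abort(paste0("lexicon file '", path, "' is empty"))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    abort(paste0("lexicon '", path, "' line ", keep[bad[1]],
                 ": expected 2 tab-separated fields"))
  }
  ade_lexicon(
    tibble(term = map_chr(parts, 1), id = map_chr(parts, 2)),
    etype = etype, name = name
  )
}

#' Match a lexicon against a sentence
#'
#' Greedy longest-match, left-to-right, case-insensitive matching over the
#' sentence's token sequence. Matches that overlap any mention already
#' present on the sentence (human annotation always wins, and re-matching
#' cannot duplicate machine mentions) are discarded. Emitted mentions carry
#' provenance `MACHINE` and the lexicon's normalized id.
#'
#' @param sentence a sentence from [ade_sentence()].
#' @param lexicon an [ade_lexicon()].
#' @param normalize_plural also match naive plural forms (trailing "s"
#'   stripped from tokens longer than three characters). Off by default:
#'   case folding is the only normalization.
#' @return Tibble of new mentions (possibly empty) with the same columns
#'   as `sentence$mentions`.
#' @export
match_lexicon <- function(sentence, lexicon, normalize_plural = FALSE) {
  dict <- ade_lexicon_dict(lexicon, normalize_plural = normalize_plural)
  .match_dict(sentence, dict)
}

# combined dictionary: key -> row (etype, id); used so drug and condition
# lexicons can be matched in one greedy pass
ade_lexicon_dict <- function(..., normalize_plural = FALSE) {
  lexs <- list(...)
  if (length(lexs) == 1L && !inherits(lexs[[1]], "ade_lexicon")) {
    lexs <- lexs[[1]]
  }
  rows <- map_dfr(lexs, function(lx) {
    tibble(
      key = if (normalize_plural) {
        .lexicon_key(lx$term, normalize_plural = TRUE)
      } else lx$key,
      id = lx$id,
      etype = attr(lx, "etype")
    )
  })
  # on a key claimed by both lexicons, DRUG wins (deterministic, documented)
  rows <- rows[order(match(rows$etype, c("DRUG", "CONDITION"))), ]
  rows <- rows[!duplicated(rows$key), ]
  env <- new.env(parent = emptyenv(), size = max(2L, nrow(rows)))
  for (i in seq_len(nrow(rows))) {
    assign(rows$key[i], rows[i, ], envir = env)
  }
  attr(env, "max_len") <- if (nrow(rows)) {
    max(lengths(strsplit(rows$key, " ", fixed = TRUE)))
  } else 0L
  attr(env, "normalize_plural") <- normalize_plural
  env
}

.match_dict <- function(sentence, dict) {
  toks <- sentence$tokens
  n <- nrow(toks)
  empty <- tibble(etype = character(), start = integer(), end = integer(),
                  norm_id = character(), provenance = character(),
                  tok_start = integer(), tok_end = integer())
  max_len <- attr(dict, "max_len")
  if (!n || !max_len) return(empty)
  words <- tolower(toks$text)
  if (isTRUE(attr(dict, "normalize_plural"))) words <- .strip_plural(words)
  blocked <- rep(FALSE, n)
  men <- sentence$mentions
  for (i in seq_len(nrow(men))) {
    blocked[seq.int(men$tok_start[i], men$tok_end[i] - 1L)] <- TRUE
  }
  out <- list()
  i <- 1L
  while (i <= n) {
    # longest dict entry starting at i whose window is entirely free of
    # existing mentions; windows touching an annotation are discarded
    hit_len <- 0L
    hit <- NULL
    for (L in seq.int(min(max_len, n - i + 1L), 1L)) {
      if (any(blocked[i:(i + L - 1L)])) next
      key <- paste(words[i:(i + L - 1L)], collapse = " ")
      row <- get0(key, envir = dict, inherits = FALSE)
      if (!is.null(row)) {
        hit_len <- L
        hit <- row
        break
      }
    }
    if (hit_len > 0L) {
      out[[length(out) + 1L]] <- tibble(
        etype = hit$etype,
        start = toks$start[i],
        end = toks$end[i + hit_len - 1L],
        norm_id = hit$id,
        provenance = "MACHINE",
        tok_start = i,
        tok_end = i + hit_len
      )
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) empty else bind_rows(out)
}

#' Machine-annotate a corpus with drug and condition lexicons
#'
#' Adds `MACHINE` mentions wherever a lexicon term occurs in a sentence and
#' no existing annotation covers it; human annotation is never modified.
#' Drug and condition lexicons are matched in a single greedy pass
#' (longest match wins; at equal length a drug reading wins), so the
#' resulting mention set is overlap-free. Idempotent: a second run adds
#' nothing.
#'
#' @param corpus an [ade_corpus()].
#' @param drug_lexicon an [ade_lexicon()] with etype `DRUG`.
#' @param cond_lexicon an [ade_lexicon()] with etype `CONDITION`.
#' @param normalize_plural see [match_lexicon()].
#' @return The corpus with machine mentions added.
#' @export
annotate_corpus <- function(corpus, drug_lexicon, cond_lexicon,
                            normalize_plural = FALSE) {
  if (attr(drug_lexicon, "etype") != "DRUG") {
    abort("drug_lexicon must have etype DRUG")
  }
  if (attr(cond_lexicon, "etype") != "CONDITION") {
    abort("cond_lexicon must have etype CONDITION")
  }
  dict <- ade_lexicon_dict(drug_lexicon, cond_lexicon,
                           normalize_plural = normalize_plural)
  docs <- map(corpus$documents, function(d) {
    d$sentences <- map(d$sentences, function(s) {
      new <- .match_dict(s, dict)
      if (!nrow(new)) return(s)
      men <- bind_rows(s$mentions, new)
      ord <- order(men$start, men$end)
      # relations reference mention rows by index: remap after the sort
      remap <- match(seq_len(nrow(men)), ord)
      if (nrow(d$relations)) {
        sel <- d$relations$sid == s$sid
        d$relations$drug_idx[sel] <<- remap[d$relations$drug_idx[sel]]
        d$relations$cond_idx[sel] <<- remap[d$relations$cond_idx[sel]]
      }
      s$mentions <- men[ord, ]
      .check_mention_overlap(s$sid, s$mentions)
      s
    })
    d
  })
  ade_corpus(docs, name = corpus$name)
}
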