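#' Configuration for the synthetic case-report corpus generator
#'
#' The generator emulates the statistical shape of an annotated
#' adverse-event corpus: short case-report sentences, sparse gold
#' relations, and drug/condition co-mentions that are *not* adverse-event
#' assertions. A sentence is realized from either a *trigger* template (a
#' causal phrasing between the entities, marking a gold `TRUE` pair) or a
#' *distractor* template (co-mention without the causal phrasing, yielding
#' `FALSE` pairs). The deciding lexical signal always sits in the
#' between-entity segment and inside trigram reach, so the between
#' sub-kernel suffices by construction.
#'
#' @param n_docs number of documents.
#' @param true_per_doc,false_per_doc planted trigger / distractor
#'   sentences per document (one drug-condition pair each; distractors may
#'   gain an extra condition mention, see `extra_condition_rate`).
#' @param n_drugs,n_conds vocabulary sizes; every fourth condition is a
#'   two-token term to exercise multi-token mention handling.
#' @param label_noise probability in \[0,1\] of flipping a planted label
#'   (a flipped trigger loses its gold relation; a flipped distractor
#'   gains one). Default 0.
#' @param unannotated_frac probability in \[0,1\] that a mention of a
#'   `FALSE` pair is left out of the human annotation, to be recovered by
#'   dictionary NER. Default 0.
#' @param extra_condition_rate probability that a distractor sentence
#'   carries a second condition mention (two `FALSE` pairs). Default 0.2.
#' @param trigger_templates,distractor_templates character vectors with
#'   `{DRUG}` and `{COND}` slots (and optionally `{COND2}` via
#'   `extra_condition_rate`); at least one of each is required.
#' @param seed integer driving all randomness.
#' @param name corpus name.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_docs = 100L,
                         true_per_doc = 2L,
                         false_per_doc = 1L,
                         n_drugs = 30L,
                         n_conds = 40L,
                         label_noise = 0,
                         unannotated_frac = 0,
                         extra_condition_rate = 0.2,
                         trigger_templates = NULL,
                         distractor_templates = NULL,
                         seed = 1L,
                         name = "synthetic") {
  trigger_templates <- trigger_templates %||% c(
    "{COND} developed after {DRUG} therapy",
    "{DRUG} induced severe {COND} in this patient",
    "treatment with {DRUG} caused {COND}",
    "{COND} was attributed to {DRUG} exposure"
  )
  distractor_templates <- distractor_templates %||% c(
    "the patient with {COND} received {DRUG} during admission",
    "{DRUG} was continued and {COND} was monitored daily",
    "history of {COND} was noted before {DRUG} initiation",
    "{DRUG} levels remained stable despite ongoing {COND}"
  )
  stopifnot(
    length(trigger_templates) >= 1L, length(distractor_templates) >= 1L,
    label_noise >= 0, label_noise <= 1,
    unannotated_frac >= 0, unannotated_frac <= 1,
    extra_condition_rate >= 0, extra_condition_rate <= 1
  )
  structure(
    list(n_docs = as.integer(n_docs),
         true_per_doc = as.integer(true_per_doc),
         false_per_doc = as.integer(false_per_doc),
         n_drugs = as.integer(n_drugs), n_conds = as.integer(n_conds),
         label_noise = label_noise, unannotated_frac = unannotated_frac,
         extra_condition_rate = extra_condition_rate,
         trigger_templates = trigger_templates,
         distractor_templates = distractor_templates,
         seed = as.integer(seed), name = name),
    class = "synth_config"
  )
}

.synth_vocab <- function(cfg) {
  drug <- tibble(
    term = sprintf("drug%03d", seq_len(cfg$n_drugs)),
    id = sprintf("SD%04d", seq_len(cfg$n_drugs))
  )
  cond_term <- sprintf("cond%03d", seq_len(cfg$n_conds))
  two <- seq_len(cfg$n_conds) %% 4L == 0L
  cond_term[two] <- paste(cond_term[two], "syndrome")
  condition <- tibble(term = cond_term,
                      id = sprintf("SC%04d", seq_len(cfg$n_conds)))
  list(drug = drug, condition = condition)
}

.fill_template <- function(tpl, drug, cond, cond2 = NULL) {
  if (!is.null(cond2)) {
    tpl <- paste(tpl, "and {COND2} was also present")
  }
  spans <- list()
  out <- ""
  rest <- tpl
  repeat {
    m <- regexpr("\\{(DRUG|COND2?)\\}", rest)
    if (m == -1L) {
      out <- paste0(out, rest)
      break
    }
    slot <- regmatches(rest, m)
    fill <- switch(slot,
                   "{DRUG}" = drug, "{COND}" = cond, "{COND2}" = cond2)
    out <- paste0(out, substring(rest, 1L, m - 1L))
    spans[[slot]] <- c(nchar(out), nchar(out) + nchar(fill))
    out <- paste0(out, fill)
    rest <- substring(rest, m + attr(m, "match.length"))
  }
  list(text = out, spans = spans)
}

#' Generate a synthetic annotated corpus with a ground-truth ledger
#'
#' Deterministic under `cfg$seed`. The ledger is the single source of
#' truth for what was planted: one row per planted drug-condition pair
#' with its final label (after noise flips), normalized ids, character
#' offsets and whether each mention was left out of the human annotation.
#'
#' @param cfg a [synth_config()].
#' @return `list(corpus, ledger, vocabulary)`; `vocabulary` holds the
#'   drug and condition term/id tables that [make_lexicons()] exports.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  vocab <- .synth_vocab(cfg)
  ledger <- list()
  docs <- withr::with_seed(cfg$seed, {
    map(seq_len(cfg$n_docs), function(d) {
      doc_id <- sprintf("D%04d", d)
      kinds <- sample(c(rep("trigger", cfg$true_per_doc),
                        rep("distractor", cfg$false_per_doc)))
      sents <- list()
      rels <- list()
      for (si in seq_along(kinds)) {
        sid <- sprintf("s%d", si)
        kind <- kinds[si]
        tpl <- if (kind == "trigger") {
          sample(cfg$trigger_templates, 1L)
        } else {
          sample(cfg$distractor_templates, 1L)
        }
        di <- sample(cfg$n_drugs, 1L)
        ci <- sample(cfg$n_conds, 1L)
        ci2 <- NA_integer_
        if (kind == "distractor" &&
            stats::runif(1) < cfg$extra_condition_rate) {
          ci2 <- sample(setdiff(seq_len(cfg$n_conds), ci), 1L)
        }
        filled <- .fill_template(
          tpl, vocab$drug$term[di], vocab$condition$term[ci],
          if (is.na(ci2)) NULL else vocab$condition$term[ci2]
        )
        label <- kind == "trigger"
        if (stats::runif(1) < cfg$label_noise) label <- !label
        # annotation gaps only on pairs that end up FALSE: gold relations
        # must reference human mentions
        drug_ann <- TRUE
        cond_ann <- TRUE
        cond2_ann <- TRUE
        if (!label && stats::runif(1) < cfg$unannotated_frac) {
          drug_ann <- FALSE
        }
        if (!label && stats::runif(1) < cfg$unannotated_frac) {
          cond_ann <- FALSE
        }
        if (!is.na(ci2) && stats::runif(1) < cfg$unannotated_frac) {
          cond2_ann <- FALSE
        }
        men <- list()
        if (drug_ann) {
          men$drug <- tibble(etype = "DRUG",
                             start = filled$spans[["{DRUG}"]][1],
                             end = filled$spans[["{DRUG}"]][2],
                             norm_id = vocab$drug$id[di],
                             provenance = "HUMAN")
        }
        if (cond_ann) {
          men$cond <- tibble(etype = "CONDITION",
                             start = filled$spans[["{COND}"]][1],
                             end = filled$spans[["{COND}"]][2],
                             norm_id = vocab$condition$id[ci],
                             provenance = "HUMAN")
        }
        if (!is.na(ci2) && cond2_ann) {
          men$cond2 <- tibble(etype = "CONDITION",
                              start = filled$spans[["{COND2}"]][1],
                              end = filled$spans[["{COND2}"]][2],
                              norm_id = vocab$condition$id[ci2],
                              provenance = "HUMAN")
        }
        sent <- ade_sentence(sid, filled$text, bind_rows(men))
        sents[[si]] <- sent
        if (label) {
          rels[[length(rels) + 1L]] <- tibble(
            sid = sid,
            drug_idx = which(sent$mentions$start ==
                               filled$spans[["{DRUG}"]][1]),
            cond_idx = which(sent$mentions$start ==
                               filled$spans[["{COND}"]][1])
          )
        }
        led <- tibble(
          doc_id = doc_id, sid = sid, template_type = kind,
          label = c("FALSE", "TRUE")[label + 1L],
          drug = vocab$drug$term[di], drug_id = vocab$drug$id[di],
          drug_start = filled$spans[["{DRUG}"]][1],
          condition = vocab$condition$term[ci],
          cond_id = vocab$condition$id[ci],
          cond_start = filled$spans[["{COND}"]][1],
          drug_annotated = drug_ann, cond_annotated = cond_ann
        )
        if (!is.na(ci2)) {
          led <- bind_rows(led, tibble(
            doc_id = doc_id, sid = sid, template_type = kind,
            label = "FALSE",
            drug = vocab$drug$term[di], drug_id = vocab$drug$id[di],
            drug_start = filled$spans[["{DRUG}"]][1],
            condition = vocab$condition$term[ci2],
            cond_id = vocab$condition$id[ci2],
            cond_start = filled$spans[["{COND2}"]][1],
            drug_annotated = drug_ann, cond_annotated = cond2_ann
          ))
        }
        ledger[[length(ledger) + 1L]] <<- led
      }
      ade_document(doc_id, sents, bind_rows(rels))
    })
  })
  list(
    corpus = ade_corpus(docs, name = cfg$name),
    ledger = bind_rows(ledger),
    vocabulary = vocab
  )
}

#' Export generator vocabularies as lexicon TSVs
#'
#' Writes `drug_lexicon.tsv` and `condition_lexicon.tsv` covering exactly
#' the generator's vocabularies with their synthetic identifiers, and
#' loads them back through [load_lexicon()].
#'
#' @param generation result of [generate_corpus()] (or any list with a
#'   `vocabulary` element).
#' @param dir output directory (default: a temporary directory).
#' @return `list(drug, condition, paths)` with the two [ade_lexicon()]s
#'   and the file paths written.
#' @export
make_lexicons <- function(generation, dir = tempfile("lexicons")) {
  vocab <- generation$vocabulary
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    drug = file.path(dir, "drug_lexicon.tsv"),
    condition = file.path(dir, "condition_lexicon.tsv")
  )
  writeLines(paste(vocab$drug$term, vocab$drug$id, sep = "\t"),
             paths["drug"])
  writeLines(paste(vocab$condition$term, vocab$condition$id, sep = "\t"),
             paths["condition"])
  list(
    drug = load_lexicon(paths[["drug"]], "DRUG", name = "synthetic-drug"),
    condition = load_lexicon(paths[["condition"]], "CONDITION",
                             name = "synthetic-condition"),
    paths = paths
  )
}
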