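test_that("lexicon loading folds case and resolves duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# drug synonyms",
               "Lithium\tDB01356",
               "niacin\tDB00627",
               "nicotinic acid\tDB00627",
               "NIACIN\tDB00627"), f)
  lex <- load_lexicon(f, "DRUG")
  expect_equal(nrow(lex), 3L)  # unique case-folded terms
  expect_setequal(lex$id[lex$key %in% c("niacin", "nicotinic acid")],
                  "DB00627")

  # conflicting duplicate: first occurrence wins, with a warning
  writeLines(c("aspirin\tDB1", "Aspirin\tDB2"), f)
  expect_warning(lex2 <- load_lexicon(f, "DRUG"), "first occurrence wins")
  expect_equal(lex2$id, "DB1")

  writeLines(c("# nothing but comments"), f)
  expect_error(load_lexicon(f, "DRUG"), "empty")
  writeLines(c("a\tb\tc"), f)
  expect_error(load_lexicon(f, "DRUG"), "line 1")
})

test_that("matching is longest-match, case-insensitive, annotation-aware", {
  drug <- ade_lexicon(tibble::tibble(term = "niacin", id = "DB00627"),
                      "DRUG")
  s <- ade_sentence("s1", "Niacin maculopathy")
  hit <- match_lexicon(s, drug)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$etype, "DRUG")
  expect_equal(hit$tok_start, 1L)
  expect_equal(hit$norm_id, "DB00627")

  # a human mention at the only lexicon hit suppresses the match
  s2 <- fixture_sentence("Niacin maculopathy", drugs = "Niacin")
  expect_equal(nrow(match_lexicon(s2, drug)), 0L)

  # longest match wins over its prefix
  cond <- ade_lexicon(
    tibble::tibble(term = c("serotonin", "serotonin syndrome"),
                   id = c("C1", "C2")), "CONDITION")
  s3 <- ade_sentence("s1", "signs of serotonin syndrome appeared")
  hit3 <- match_lexicon(s3, cond)
  expect_equal(nrow(hit3), 1L)
  expect_equal(hit3$norm_id, "C2")
  expect_equal(hit3$tok_end - hit3$tok_start, 2L)
})

test_that("matcher agrees with the brute-force all-window oracle", {
  set.seed(42)
  vocab <- c(sprintf("w%02d", 1:12), "niacin", "acid", "nicotinic",
             "serotonin", "syndrome", "rash")
  terms <- c("niacin", "nicotinic acid", "serotonin syndrome",
             "serotonin", "rash", "w01 w02", "w03")
  lex <- ade_lexicon(tibble::tibble(term = terms,
                                    id = paste0("ID", seq_along(terms))),
                     "CONDITION")
  dict_df <- data.frame(key = lex$key, id = lex$id,
                        etype = attr(lex, "etype"))
  for (i in 1:300) {
    txt <- random_short_sentence(vocab, sample(3:20, 1))
    s <- ade_sentence("s1", txt)
    got <- match_lexicon(s, lex)
    want <- oracle_match(s$tokens$text, dict_df)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$tok_start, want$tok_start)
      expect_equal(got$tok_end, want$tok_end)
      expect_equal(got$norm_id, want$id)
    }
  }
})

test_that("annotate_corpus fills gaps, is idempotent and overlap-free", {
  gen <- cached_generation(30, unannotated_frac = 0.5)
  lex <- make_lexicons(gen)
  led <- gen$ledger

  ann <- annotate_corpus(gen$corpus, lex$drug, lex$condition)
  men <- corpus_mentions(ann)

  # exactly the planted annotation gaps are recovered as MACHINE mentions
  # (one drug per sentence, conditions distinct per (sentence, id))
  planted_gaps <-
    sum(!dplyr::distinct(led, doc_id, sid,
                         .keep_all = TRUE)$drug_annotated) +
    sum(!dplyr::distinct(led, doc_id, sid, cond_id,
                         .keep_all = TRUE)$cond_annotated)
  expect_equal(sum(men$provenance == "MACHINE"), planted_gaps)

  # human mentions untouched
  men0 <- corpus_mentions(gen$corpus)
  expect_equal(sum(men$provenance == "HUMAN"), nrow(men0))

  # idempotence: a second pass adds nothing
  ann2 <- annotate_corpus(ann, lex$drug, lex$condition)
  expect_equal(nrow(corpus_mentions(ann2)), nrow(men))

  # no overlapping mentions anywhere, any provenance
  for (d in ann$documents) {
    for (s in d$sentences) {
      m <- s$mentions[order(s$mentions$start), ]
      if (nrow(m) > 1) {
        expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
      }
    }
  }

  # fully annotated corpus is unchanged; empty lexicons are a no-op
  full <- cached_generation(10)
  flex <- make_lexicons(full)
  expect_equal(
    nrow(corpus_mentions(annotate_corpus(full$corpus, flex$drug,
                                         flex$condition))),
    nrow(corpus_mentions(full$corpus))
  )

  expect_error(annotate_corpus(full$corpus, flex$condition, flex$drug),
               "etype")
})

test_that("matching is invariant to input letter case", {
  lex <- ade_lexicon(tibble::tibble(term = "Nicotinic Acid", id = "X"),
                     "DRUG")
  for (txt in c("nicotinic acid", "NICOTINIC ACID", "Nicotinic acid")) {
    s <- ade_sentence("s1", paste("dose of", txt, "given"))
    expect_equal(nrow(match_lexicon(s, lex)), 1L)
  }
})
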