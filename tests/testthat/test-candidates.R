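test_that("candidate enumeration is the ordered Cartesian product", {
  s <- fixture_sentence(
    "aspirin and warfarin caused rash then nausea and fever",
    drugs = c("aspirin", "warfarin"),
    conds = c("rash", "nausea", "fever")
  )
  cands <- enumerate_candidates(s, "d1")
  expect_equal(nrow(cands), 6L)
  expect_true(all(cands$label == "UNKNOWN"))
  expect_equal(cands$drug_start, sort(cands$drug_start))
  expect_false(anyDuplicated(cands$instance_id) > 0)

  expect_equal(nrow(enumerate_candidates(
    fixture_sentence("only rash here", conds = "rash"), "d1")), 0L)
  expect_equal(nrow(enumerate_candidates(
    fixture_sentence("aspirin caused rash", drugs = "aspirin",
                     conds = "rash"), "d1")), 1L)
})

test_that("labelling partitions candidates exactly by the gold set", {
  s <- fixture_sentence("ampicillin caused rash and nausea",
                        drugs = "ampicillin", conds = c("rash", "nausea"))
  cands <- enumerate_candidates(s, "d1")
  gold <- tibble::tibble(doc_id = "d1", sid = "s1",
                         drug_start = cands$drug_start[1],
                         cond_start = cands$cond_start[1])
  lab <- label_candidates(cands, gold)
  expect_equal(sort(lab$label), c("FALSE", "TRUE"))
  expect_true(all(label_candidates(cands, cands[, c("doc_id", "sid",
                  "drug_start", "cond_start")])$label == "TRUE"))
  expect_error(
    label_candidates(cands, tibble::tibble(doc_id = "d1", sid = "s1",
                                           drug_start = 999L,
                                           cond_start = 0L)),
    "without matching candidate"
  )

  # property: d drugs x c conditions with g gold pairs -> d*c - g FALSE
  set.seed(9)
  for (i in 1:20) {
    nd <- sample(1:3, 1)
    nc <- sample(1:3, 1)
    drugs <- sprintf("drg%d", seq_len(nd))
    conds <- sprintf("cnd%d", seq_len(nc))
    txt <- paste(c(drugs, "caused", conds), collapse = " ")
    s <- fixture_sentence(txt, drugs = drugs, conds = conds)
    cands <- enumerate_candidates(s, "d1")
    g <- sample(nrow(cands), sample(0:nrow(cands), 1))
    lab <- label_candidates(
      cands, cands[g, c("doc_id", "sid", "drug_start", "cond_start")])
    expect_equal(sum(lab$label == "TRUE"), length(g))
    expect_equal(sum(lab$label == "FALSE"), nd * nc - length(g))
  }
})

test_that("nested gold relations are removed and counted", {
  # drug span inside the condition phrase: the classic nested annotation
  s <- ade_sentence("s1", "acute lithium toxicity was seen", tibble::tibble(
    etype = c("DRUG", "CONDITION"), start = c(6L, 0L), end = c(13L, 22L),
    norm_id = NA_character_, provenance = c("HUMAN", "MACHINE")
  ))
  d <- ade_document("p1", list(s),
                    tibble::tibble(sid = "s1", drug_idx = 2L,
                                   cond_idx = 1L))
  rn <- remove_nested(ade_corpus(list(d)))
  expect_equal(rn$removed, 1L)
  expect_equal(nrow(corpus_relations(rn$corpus)), 0L)
  # mentions themselves are retained
  expect_equal(nrow(corpus_mentions(rn$corpus)), 2L)

  # disjoint spans: nothing removed
  ok <- fixture_corpus("lithium caused toxicity", drugs = "lithium",
                       conds = "toxicity",
                       gold = list(c("lithium", "toxicity")))
  expect_equal(remove_nested(ok)$removed, 0L)

  # 3 relations, 1 nested -> 2 survive
  both <- ade_corpus(list(
    ok$documents[[1]],
    ade_document("p2", list(s), tibble::tibble(sid = "s1", drug_idx = 2L,
                                               cond_idx = 1L)),
    ade_document("p3", ok$documents[[1]]$sentences,
                 ok$documents[[1]]$relations)
  ))
  rn2 <- remove_nested(both)
  expect_equal(rn2$removed, 1L)
  expect_equal(nrow(corpus_relations(rn2$corpus)), 2L)
})

test_that("build_dataset is deterministic and matches the ledger", {
  gen <- cached_generation(20)
  ds1 <- build_dataset(gen$corpus)
  ds2 <- build_dataset(gen$corpus)
  expect_identical(ds1$instance_id, ds2$instance_id)
  expect_identical(ds1$label, ds2$label)
  expect_false(any(ds1$label == "UNKNOWN"))

  # empty corpus -> empty dataset
  expect_equal(nrow(build_dataset(ade_corpus(list()))), 0L)

  # dataset equals the generator ledger pair-for-pair (noise 0, full
  # annotation): same keys, same labels
  led <- gen$ledger
  key <- function(df, ds, cs) {
    paste(df$doc_id, df$sid, df[[ds]], df[[cs]], sep = "|")
  }
  expect_setequal(key(ds1, "drug_start", "cond_start"),
                  key(led, "drug_start", "cond_start"))
  m <- match(key(ds1, "drug_start", "cond_start"),
             key(led, "drug_start", "cond_start"))
  expect_identical(ds1$label, led$label[m])

  # TRUE count equals surviving gold; FALSE = sum(d*c) - TRUE
  expect_equal(sum(ds1$label == "TRUE"),
               nrow(corpus_relations(remove_nested(gen$corpus)$corpus)))
  percell <- purrr::map_int(gen$corpus$documents, function(d) {
    sum(purrr::map_int(d$sentences, function(s) {
      sum(s$mentions$etype == "DRUG") * sum(s$mentions$etype == "CONDITION")
    }))
  })
  expect_equal(nrow(ds1), sum(percell))
})
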