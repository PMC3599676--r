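toy_dataset <- function() {
  t1 <- fixture_corpus("drugx induced condx", drugs = "drugx",
                       conds = "condx", gold = list(c("drugx", "condx")),
                       doc_id = "T1")
  t2 <- fixture_corpus("drugx was given and condx was monitored",
                       drugs = "drugx", conds = "condx", doc_id = "T2")
  t3 <- fixture_corpus("drugy induced condy", drugs = "drugy",
                       conds = "condy", gold = list(c("drugy", "condy")),
                       doc_id = "T3")
  t4 <- fixture_corpus("drugy was given and condy was monitored",
                       drugs = "drugy", conds = "condy", doc_id = "T4")
  build_dataset(ade_corpus(c(t1$documents, t2$documents, t3$documents,
                             t4$documents)))
}

test_that("a separable toy set is fit exactly and predictions round-trip", {
  ds <- toy_dataset()
  m <- train_classifier(ds, C = 10, seed = 1)
  preds <- predict(m, ds)
  expect_identical(preds$label, ds$label)
  expect_identical(preds$instance_id, ds$instance_id)
  expect_equal(nrow(predict(m, ds[0, ])), 0L)

  # persistence round-trip is bit-exact on predictions, metadata kept
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict(m2, ds)$score, preds$score)
  expect_identical(m2$meta$seed, m$meta$seed)

  writeLines("not a model", f)
  expect_error(load_model(f), "model")
})

test_that("training refuses degenerate input", {
  ds <- toy_dataset()
  expect_error(train_classifier(ds[ds$label == "TRUE", ]), "both TRUE")
  dsu <- ds
  dsu$label[1] <- "UNKNOWN"
  expect_error(train_classifier(dsu), "UNKNOWN")
})

test_that("training is deterministic and shuffle-invariant", {
  gen <- cached_generation(30)
  ds <- build_dataset(gen$corpus)
  m1 <- train_classifier(ds, seed = 3)
  m2 <- train_classifier(ds[sample(nrow(ds)), ], seed = 3)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$bias, m2$bias)
  held <- build_dataset(cached_generation(10, seed = 99)$corpus)
  expect_identical(predict(m1, held)$score, predict(m2, held)$score)
})

test_that("noise-free synthetic training is nearly perfectly recovered", {
  gen <- cached_generation(60)
  ds <- build_dataset(gen$corpus)
  m <- cached_model(60)
  preds <- predict(m, ds)
  cm <- table(factor(preds$label, c("TRUE", "FALSE")),
              factor(ds$label, c("TRUE", "FALSE")))
  res <- prf(cm[1, 1], cm[1, 2], cm[2, 1], cm[2, 2])
  expect_gte(res$f_score, 0.99)
})

test_that("a causal trigger phrase between the entities raises the score", {
  m <- cached_model(60)
  base <- build_dataset(fixture_corpus(
    "history of cond001 was noted before drug001 initiation",
    drugs = "drug001", conds = "cond001", doc_id = "E1"))
  edited <- build_dataset(fixture_corpus(
    "cond001 developed after drug001 therapy",
    drugs = "drug001", conds = "cond001", doc_id = "E1"))
  s_base <- predict(m, base)$score
  s_edit <- predict(m, edited)$score
  expect_gt(s_edit, s_base)
  expect_gt(s_edit, 0)
  expect_lt(s_base, 0)
})

test_that("duplicating a training instance never flips its own label", {
  ds <- toy_dataset()
  m0 <- train_classifier(ds, seed = 1)
  p0 <- predict(m0, ds[1, ])
  dup <- dplyr::bind_rows(ds, dplyr::mutate(
    ds[1, ], instance_id = paste0(instance_id, ".dup")))
  m1 <- train_classifier(dup, seed = 1)
  expect_identical(predict(m1, ds[1, ])$label, p0$label)
})

test_that("tidy and glance expose the fitted model", {
  m <- cached_model(60)
  tw <- tidy(m)
  expect_true(all(c("feature", "namespace", "weight") %in% names(tw)))
  expect_true(all(tw$namespace %in% c("FB", "B", "BA", "LC")))
  g <- glance(m)
  expect_equal(g$n_train, nrow(build_dataset(cached_generation(60)$corpus)))
  expect_equal(g$C, 1)
})
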