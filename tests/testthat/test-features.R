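one_pair_cand <- function(text, drug, cond) {
  s <- fixture_sentence(text, drugs = drug, conds = cond)
  cands <- enumerate_candidates(s, "d1")
  cands$label <- "FALSE"
  cands
}

test_that("global context namespaces follow the segment definitions", {
  # adjacent entities: between namespace empty
  adj <- one_pair_cand("aspirin rash", "aspirin", "rash")
  g <- global_context(adj)
  expect_false(any(g$namespace == "B"))
  expect_true(all(c("FB", "BA") %in% g$namespace))

  # single between token with n_max = 1
  cand <- one_pair_cand("aspirin induced rash", "aspirin", "rash")
  g1 <- global_context(cand, kernel_params(n_max = 1))
  expect_equal(g1$count[g1$feature == "B:induced"], 1)
  # entity blinding: placeholders appear, lexical drug name does not
  expect_true("FB:DRUG_CAND" %in% g1$feature)
  expect_false(any(grepl("aspirin", g1$feature)))
  g1u <- global_context(cand, kernel_params(n_max = 1,
                                            blind_entities = FALSE))
  expect_true("FB:aspirin" %in% g1u$feature)

  # 5-token between segment, n_max = 3: 5 + 4 + 3 = 12 B-grams
  cand5 <- one_pair_cand("aspirin was linked to the acute rash",
                         "aspirin", "rash")
  gb <- dplyr::filter(global_context(cand5, kernel_params(n_max = 3)),
                      namespace == "B")
  expect_equal(sum(gb$count), 12)

  # counts agree with a brute-force n-gram enumeration oracle
  set.seed(31)
  vocab <- sprintf("tok%02d", 1:8)
  for (i in 1:100) {
    mid <- random_short_sentence(vocab, sample(1:7, 1))
    txt <- paste("drugx", mid, "condx")
    cc <- one_pair_cand(txt, "drugx", "condx")
    nmax <- sample(1:4, 1)
    gb <- dplyr::filter(global_context(cc, kernel_params(n_max = nmax)),
                        namespace == "B")
    grams <- oracle_ngrams(strsplit(mid, " ")[[1]], nmax)
    expect_equal(sort(paste0("B:", grams)),
                 sort(rep(gb$feature, gb$count)))
  }
})

test_that("local context emits positional attribute features", {
  # window 0: empty
  cand <- one_pair_cand("yesterday the drugx caused severe condx today again",
                        "drugx", "condx")
  expect_equal(nrow(local_context(cand, kernel_params(window = 0))), 0L)

  # mid-sentence entities with window 2: 4 positions x 4 attributes each
  lc <- local_context(cand, kernel_params(window = 2))
  expect_equal(sum(lc$count[lc$namespace == "LC_LEFT"]), 16)
  expect_equal(sum(lc$count[lc$namespace == "LC_RIGHT"]), 16)

  # entity at sentence start: only right-side positions for it
  edge <- one_pair_cand("drugx caused condx", "drugx", "condx")
  lce <- local_context(edge, kernel_params(window = 2))
  left <- lce$feature[lce$namespace == "LC_LEFT"]
  expect_true(all(grepl("^LC_LEFT:[12]:", left)))

  # positional enumeration oracle: keys are exactly the in-range
  # (position, attribute) combinations
  toks <- cand$tokens[[1]]
  expected <- 0L
  for (rng in list(c(cand$drug_tok_start, cand$drug_tok_end - 1),
                   c(cand$cond_tok_start, cand$cond_tok_end - 1))) {
    for (r in c(-2L, -1L, 1L, 2L)) {
      i <- if (r < 0) rng[1] + r else rng[2] + r
      if (i >= 1 && i <= nrow(toks)) expected <- expected + 4L
    }
  }
  expect_equal(sum(lc$count), expected)
})

test_that("kernel algebra: symmetry, self-similarity, bounds, PSD", {
  gen <- cached_generation(15)
  ds <- build_dataset(gen$corpus)
  set.seed(5)
  idx <- sample(nrow(ds), 12)
  p <- kernel_params()
  K <- matrix(0, 12, 12)
  for (i in 1:12) {
    for (j in i:12) {
      K[i, j] <- K[j, i] <- slk_kernel(ds[idx[i], ], ds[idx[j], ], p)
    }
  }
  # exact symmetry by independent recomputation of a few transposes
  for (k in 1:5) {
    i <- sample(12, 1); j <- sample(12, 1)
    expect_identical(slk_kernel(ds[idx[i], ], ds[idx[j], ], p),
                     slk_kernel(ds[idx[j], ], ds[idx[i], ], p))
  }
  # bound 0 <= K <= 4 and K(x,x) = number of non-empty sub-kernels
  expect_true(all(K >= 0 & K <= 4 + 1e-12))
  for (i in 1:12) {
    f <- feature_map(ds[idx[i], ], p)
    groups <- unique(ifelse(grepl("^LC_", f$feature), "LC",
                            sub(":.*$", "", f$feature)))
    expect_equal(K[i, i], length(groups), tolerance = 1e-12)
  }
  expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-8)
})

test_that("explicit map reproduces the kernel and the dense oracle", {
  gen <- cached_generation(15)
  ds <- build_dataset(gen$corpus)
  set.seed(6)
  idx <- sample(nrow(ds), 10)
  p <- kernel_params()
  for (i in seq_along(idx)) {
    a <- ds[idx[i], ]
    fa <- feature_map(a, p)
    expect_equal(sum(fa$value^2), slk_kernel(a, a, p), tolerance = 1e-12)
    j <- idx[(i %% length(idx)) + 1]
    b <- ds[j, ]
    fb <- feature_map(b, p)
    m <- dplyr::inner_join(fa, fb, by = "feature")
    dot <- sum(m$value.x * m$value.y)
    expect_equal(dot, slk_kernel(a, b, p), tolerance = 1e-10)
    expect_equal(dot, oracle_kernel(a, b, p), tolerance = 1e-10)
  }
})

test_that("featurize builds the map as a sparse matrix, row per instance", {
  gen <- cached_generation(10)
  ds <- build_dataset(gen$corpus)
  feat <- featurize(ds)
  expect_equal(nrow(feat$x), nrow(ds))
  expect_identical(rownames(feat$x), ds$instance_id)
  i <- 3L
  fm <- feature_map(ds[i, ])
  expect_equal(sum(feat$x[i, ]^2), sum(fm$value^2), tolerance = 1e-12)
  # restricting the vocabulary drops unknown features but keeps values
  feat2 <- featurize(ds[1:2, ], features = feat$features[1:50])
  expect_equal(ncol(feat2$x), 50L)

  # unannotated tokens are refused
  broken <- ds[1, ]
  tk <- broken$tokens[[1]]
  tk$lemma[1] <- NA_character_
  broken$tokens <- list(tk)
  expect_error(global_context(broken), "lemma/POS")
})
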