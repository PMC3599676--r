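# Shared fixture builders and independent oracles. All fixtures are built
# in code; nothing is read from disk except the installed extdata TSVs.

# quick sentence: mentions given as surface substrings (first occurrence)
fixture_sentence <- function(text, drugs = character(), conds = character(),
                             sid = "s1", provenance = "HUMAN") {
  men <- NULL
  spot <- function(term, etype, i) {
    start <- as.integer(regexpr(term, text, fixed = TRUE)) - 1L
    stopifnot(start >= 0L)
    tibble::tibble(etype = etype, start = start,
                   end = start + nchar(term),
                   norm_id = paste0(substr(etype, 1, 1), i),
                   provenance = provenance)
  }
  men <- dplyr::bind_rows(
    purrr::imap(drugs, ~ spot(.x, "DRUG", .y)),
    purrr::imap(conds, ~ spot(.x, "CONDITION", .y))
  )
  ade_sentence(sid, text, men)
}

# one-sentence document + corpus with optional gold relations given as
# (drug surface, condition surface) pairs
fixture_corpus <- function(text, drugs, conds, gold = list(),
                           doc_id = "PMID1") {
  s <- fixture_sentence(text, drugs, conds)
  rel <- purrr::map_dfr(gold, function(g) {
    di <- which(s$mentions$etype == "DRUG" &
                  substring(text, s$mentions$start + 1,
                            s$mentions$end) == g[[1]])
    ci <- which(s$mentions$etype == "CONDITION" &
                  substring(text, s$mentions$start + 1,
                            s$mentions$end) == g[[2]])
    tibble::tibble(sid = "s1", drug_idx = di[1], cond_idx = ci[1])
  })
  ade_corpus(list(ade_document(doc_id, list(s), rel)))
}

# memoized generated corpora so expensive fixtures build once per run
.gen_cache <- new.env(parent = emptyenv())
cached_generation <- function(n_docs, label_noise = 0, seed = 7,
                              unannotated_frac = 0) {
  key <- paste(n_docs, label_noise, seed, unannotated_frac, sep = "|")
  if (is.null(.gen_cache[[key]])) {
    .gen_cache[[key]] <- generate_corpus(synth_config(
      n_docs = n_docs, label_noise = label_noise,
      unannotated_frac = unannotated_frac, seed = seed
    ))
  }
  .gen_cache[[key]]
}

cached_model <- function(n_docs = 60, seed = 7) {
  key <- paste("model", n_docs, seed, sep = "|")
  if (is.null(.gen_cache[[key]])) {
    gen <- cached_generation(n_docs, seed = seed)
    ds <- build_dataset(gen$corpus)
    .gen_cache[[key]] <- train_classifier(ds, seed = seed,
                                          corpus_name = "cached")
  }
  .gen_cache[[key]]
}

# ---- independent oracles -------------------------------------------------

# naive n-gram enumeration by explicit double loop
oracle_ngrams <- function(units, n_max) {
  out <- character(0)
  for (i in seq_along(units)) {
    for (k in seq_len(n_max)) {
      if (i + k - 1L > length(units)) break
      out <- c(out, paste(units[i:(i + k - 1L)], collapse = " "))
    }
  }
  sort(out)
}

# naive dictionary matcher: all-window lookup against a plain data frame,
# then the documented greedy longest-match left-to-right resolution,
# skipping windows that touch blocked token positions
oracle_match <- function(words, dict_df, blocked = rep(FALSE, length(words))) {
  n <- length(words)
  hits <- list()
  i <- 1L
  while (i <= n) {
    found <- 0L
    for (L in rev(seq_len(n - i + 1L))) {
      if (any(blocked[i:(i + L - 1L)])) next
      key <- paste(tolower(words[i:(i + L - 1L)]), collapse = " ")
      row <- dict_df[dict_df$key == key, ]
      if (nrow(row)) {
        hits[[length(hits) + 1L]] <-
          data.frame(tok_start = i, tok_end = i + L, id = row$id[1],
                     etype = row$etype[1])
        found <- L
        break
      }
    }
    i <- i + max(found, 1L)
  }
  if (!length(hits)) {
    return(data.frame(tok_start = integer(), tok_end = integer(),
                      id = character(), etype = character()))
  }
  do.call(rbind, hits)
}

# dense-vector kernel oracle built from the exported feature tibbles
oracle_kernel <- function(a, b, params = kernel_params()) {
  feats <- function(x) {
    f <- dplyr::bind_rows(global_context(x, params), local_context(x, params))
    f$group <- ifelse(f$namespace %in% c("LC_LEFT", "LC_RIGHT"), "LC",
                      f$namespace)
    f
  }
  fa <- feats(a)
  fb <- feats(b)
  total <- 0
  for (g in c("FB", "B", "BA", "LC")) {
    xa <- fa[fa$group == g, ]
    xb <- fb[fb$group == g, ]
    if (!nrow(xa) || !nrow(xb)) next
    keys <- union(xa$feature, xb$feature)
    va <- vb <- numeric(length(keys))
    va[match(xa$feature, keys)] <- xa$count
    vb[match(xb$feature, keys)] <- xb$count
    total <- total + sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  }
  total
}

random_short_sentence <- function(vocab, n_tokens) {
  paste(sample(vocab, n_tokens, replace = TRUE), collapse = " ")
}
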