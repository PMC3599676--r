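#' Precision, recall and F-score over the TRUE class
#'
#' Adverse-event extraction is evaluated on the positive (`TRUE`) relation
#' class: precision `tp/(tp+fp)`, recall `tp/(tp+fn)` and their harmonic
#' mean, with the convention that an empty denominator yields 0. Rounding
#' happens only at presentation time.
#'
#' @param tp,fp,fn,tn confusion counts (vectors recycle).
#' @return A tibble with the counts and `precision`, `recall`, `f_score`.
#' @export
prf <- function(tp, fp, fn, tn) {
  stopifnot(all(c(tp, fp, fn, tn) >= 0))
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         precision = p, recall = r, f_score = f_from_pr(p, r))
}

#' F-score from precision and recall
#'
#' @param p,r precision and recall in \[0, 1\] (vectorized).
#' @return Harmonic mean `2pr/(p+r)`, 0 where `p + r = 0`.
#' @export
f_from_pr <- function(p, r) {
  stopifnot(all(p >= 0 & p <= 1), all(r >= 0 & r <= 1))
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

# one CV round over a document->fold assignment; dataset rows must align
# with rows of the sparse feature matrix x. Returns per-fold confusion
# counts. A fold whose training side is single-class falls back to a
# majority-class constant predictor.
.run_cv <- function(dataset, x, doc_fold, C, seed) {
  lab <- dataset$label == "TRUE"
  folds <- sort(unique(doc_fold))
  map_dfr(folds, function(f) {
    test_docs <- names(doc_fold)[doc_fold == f]
    te <- dataset$doc_id %in% test_docs
    tr <- dataset$doc_id %in% names(doc_fold) & !te
    if (!any(te)) return(NULL)
    if (length(unique(lab[tr])) < 2L) {
      pred <- rep(mean(lab[tr]) >= 0.5, sum(te))
    } else {
      fit <- .fit_linear_svm(x[tr, , drop = FALSE], dataset$label[tr],
                             C = C, seed = seed)
      score <- as.numeric(x[te, , drop = FALSE] %*% fit$w) + fit$b
      pred <- score > 0
    }
    y <- lab[te]
    tibble(fold = f,
           tp = sum(pred & y), fp = sum(pred & !y),
           fn = sum(!pred & y), tn = sum(!pred & !y))
  })
}

#' Document-level k-fold cross-validation
#'
#' Folds partition *documents*, never individual candidate pairs, so all
#' candidates of one case report land on the same side of every split and
#' near-duplicate sentences cannot leak between train and test. The
#' headline result pools (micro-averages) confusion counts across folds;
#' per-fold results are kept for dispersion estimates.
#'
#' @param corpus an annotated [ade_corpus()].
#' @param k number of folds (default 10); must not exceed the number of
#'   documents contributing candidates.
#' @param params a [kernel_params()].
#' @param C SVM regularization constant.
#' @param seed integer; fold assignment and training are deterministic
#'   given the seed.
#' @param drop_nested passed to [build_dataset()].
#' @return An `ade_cv` object: `pooled` (one-row [prf()] tibble), `folds`
#'   (per-fold tibble), plus `k` and `seed`. `glance()` returns the pooled
#'   row, `tidy()` the per-fold table.
#' @export
cross_validate <- function(corpus, k = 10L, params = kernel_params(),
                           C = 1, seed = 1L, drop_nested = TRUE) {
  dataset <- build_dataset(corpus, drop_nested = drop_nested)
  if (!nrow(dataset) || length(unique(dataset$label)) < 2L) {
    abort("cross-validation needs a dataset with both TRUE and FALSE pairs")
  }
  docs <- unique(dataset$doc_id)
  if (k > length(docs)) {
    abort(paste0("k = ", k, " exceeds the ", length(docs),
                 " documents with candidates"))
  }
  feat <- featurize(dataset, params)
  doc_fold <- withr::with_seed(as.integer(seed), {
    stats::setNames(sample(rep_len(seq_len(k), length(docs))), sort(docs))
  })
  per_fold <- .run_cv(dataset, feat$x, doc_fold, C = C, seed = seed)
  m <- prf(per_fold$tp, per_fold$fp, per_fold$fn, per_fold$tn)
  folds <- mutate(per_fold, precision = m$precision, recall = m$recall,
                  f_score = m$f_score)
  pooled <- prf(sum(per_fold$tp), sum(per_fold$fp),
                sum(per_fold$fn), sum(per_fold$tn))
  structure(
    list(pooled = pooled, folds = folds, k = k, seed = as.integer(seed)),
    class = "ade_cv"
  )
}

#' @export
print.ade_cv <- function(x, ...) {
  cat("<ade_cv> ", x$k, "-fold document-level cross-validation\n", sep = "")
  print(x$pooled)
  invisible(x)
}

#' @export
tidy.ade_cv <- function(x, ...) as_tibble(x$folds)

#' @export
glance.ade_cv <- function(x, ...) x$pooled

#' Learning curve over training-set size
#'
#' Samples document subsets of increasing size without replacement, runs
#' document-level k-fold cross-validation on each subset, and reports the
#' mean and standard deviation of precision, recall and F across folds
#' (and repeats). This reproduces the classic diagnostic: small corpora
#' give volatile estimates, and the fold-to-fold standard deviation
#' shrinks as annotation grows.
#'
#' @param corpus an annotated [ade_corpus()].
#' @param sizes document counts to evaluate; sizes exceeding the corpus
#'   are skipped with a warning.
#' @param k folds per size.
#' @param repeats independent subsamples per size (default 1).
#' @param params a [kernel_params()].
#' @param C SVM regularization constant.
#' @param seed integer; the whole experiment is deterministic given it.
#' @param drop_nested passed to [build_dataset()].
#' @return An `ade_learning_curve` tibble: `n_docs`, mean/SD of the three
#'   metrics, and `n_folds`.
#' @export
learning_curve <- function(corpus,
                           sizes = c(10, 20, 50, 100, 200, 500, 1000, 2000),
                           k = 10L, repeats = 1L,
                           params = kernel_params(), C = 1, seed = 1L,
                           drop_nested = TRUE) {
  dataset <- build_dataset(corpus, drop_nested = drop_nested)
  docs <- unique(dataset$doc_id)
  usable <- sizes[sizes <= length(docs)]
  if (length(usable) < length(sizes)) {
    warn(paste0("skipping sizes beyond the ", length(docs),
                " available documents: ",
                paste(setdiff(sizes, usable), collapse = ", ")))
  }
  feat <- featurize(dataset, params)
  rows <- withr::with_seed(as.integer(seed), {
    map_dfr(usable, function(s) {
      map_dfr(seq_len(repeats), function(rep_i) {
        sub <- sample(sort(docs), s)
        doc_fold <- stats::setNames(
          sample(rep_len(seq_len(min(k, s)), s)), sub)
        cf <- .run_cv(dataset, feat$x, doc_fold, C = C, seed = seed)
        m <- prf(cf$tp, cf$fp, cf$fn, cf$tn)
        tibble(n_docs = s, repeat_i = rep_i, fold = cf$fold,
               precision = m$precision, recall = m$recall,
               f_score = m$f_score)
      })
    })
  })
  out <- rows |>
    group_by(.data$n_docs) |>
    summarise(
      precision_mean = mean(.data$precision),
      precision_sd = sd(.data$precision),
      recall_mean = mean(.data$recall),
      recall_sd = sd(.data$recall),
      f_mean = mean(.data$f_score),
      f_sd = sd(.data$f_score),
      n_folds = n(),
      .groups = "drop"
    )
  class(out) <- c("ade_learning_curve", class(out))
  attr(out, "seed") <- as.integer(seed)
  out
}
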