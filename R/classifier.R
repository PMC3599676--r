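#' Train the relation classifier
#'
#' Fits a binary support-vector machine on the explicit feature map of the
#' shallow linguistic kernel. Because the map's dot products equal the
#' kernel exactly, the linear SVM is the kernel machine, but training
#' scales to large candidate sets. Instances are canonicalized
#' (sorted by instance id) before fitting, so training is invariant to
#' dataset shuffling and deterministic under a fixed seed.
#'
#' @param dataset labelled candidate tibble from [build_dataset()]; both
#'   labels must be present and no `UNKNOWN` label may remain.
#' @param params a [kernel_params()], stored with the model and used for
#'   all later featurization.
#' @param C SVM regularization constant (default 1; no class reweighting —
#'   the positive/negative pair counts in case-report corpora are near
#'   balanced).
#' @param seed integer seed recorded in the model metadata and applied
#'   around the fit.
#' @param corpus_name free-text provenance recorded in the metadata.
#' @return An `ade_model`: explicit weight vector over feature keys, bias,
#'   kernel parameters, `C`, label map and training metadata.
#' @export
train_classifier <- function(dataset, params = kernel_params(), C = 1,
                             seed = 1L, corpus_name = "dataset") {
  stopifnot(C > 0)
  if (any(dataset$label == "UNKNOWN")) {
    abort("dataset contains UNKNOWN labels; run label_candidates() first")
  }
  if (length(unique(dataset$label)) < 2L) {
    abort("training requires both TRUE and FALSE instances")
  }
  dataset <- arrange(dataset, .data$instance_id)
  feat <- featurize(dataset, params)
  fit <- .fit_linear_svm(feat$x, dataset$label, C = C, seed = seed)
  structure(
    list(
      weights = stats::setNames(fit$w, feat$features),
      bias = fit$b,
      params = params,
      C = C,
      labels = c(positive = "TRUE", negative = "FALSE"),
      meta = list(corpus_name = corpus_name, seed = as.integer(seed),
                  n_train = nrow(dataset), timestamp = format(Sys.time())),
      version = 1L
    ),
    class = "ade_model"
  )
}

# libsvm orients its decision function by the first label it sees; recover
# an explicit (w, b) and re-orient so that TRUE scores positive.
.fit_linear_svm <- function(x, label, C, seed) {
  y <- factor(label, levels = c("TRUE", "FALSE"))
  # columns inactive in this training slice carry zero weight; drop them
  # before densifying for libsvm
  nz <- which(Matrix::colSums(x * x) > 0)
  xd <- as.matrix(x[, nz, drop = FALSE])
  fit <- withr::with_seed(as.integer(seed), {
    e1071::svm(xd, y, kernel = "linear", cost = C, scale = FALSE)
  })
  w_nz <- drop(crossprod(fit$coefs, fit$SV))
  b <- unname(-fit$rho)
  d <- drop(xd %*% w_nz) + b
  if (mean(d[y == "TRUE"]) < mean(d[y == "FALSE"])) {
    w_nz <- -w_nz
    b <- -b
  }
  w <- numeric(ncol(x))
  w[nz] <- unname(w_nz)
  list(w = w, b = b)
}

#' @export
print.ade_model <- function(x, ...) {
  cat("<ade_model> linear SVM on shallow-linguistic-kernel feature map\n",
      "  features: ", length(x$weights),
      "  C: ", x$C,
      "  trained on: ", x$meta$corpus_name,
      " (n = ", x$meta$n_train, ", seed ", x$meta$seed, ")\n", sep = "")
  invisible(x)
}

#' Classify relation candidates
#'
#' Candidates are featurized under the kernel parameters stored in the
#' model (features unseen at training time carry zero weight). The margin
#' score is `w . phi(x) + b`; the predicted label is `TRUE` iff the score
#' is strictly positive — an exact tie goes to `FALSE`, the conservative
#' choice for a pharmacovigilance signal.
#'
#' @param object an `ade_model` from [train_classifier()].
#' @param cands candidate tibble.
#' @param ... unused.
#' @return Tibble `instance_id`, `label`, `score` in input order.
#' @export
predict.ade_model <- function(object, cands, ...) {
  if (!nrow(cands)) {
    return(tibble(instance_id = character(), label = character(),
                  score = numeric()))
  }
  feat <- featurize(cands, object$params, features = names(object$weights))
  score <- as.numeric(feat$x %*% object$weights) + object$bias
  tibble(
    instance_id = cands$instance_id,
    label = ifelse(score > 0, "TRUE", "FALSE"),
    score = unname(score)
  )
}

#' Persist and restore a trained model
#'
#' @param model an `ade_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model, and errors on a corrupt file or an incompatible model version.
#'   Round-tripping preserves predictions bit-exactly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ade_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("cannot read model file '", path, "': ",
                 conditionMessage(e)))
  })
  if (!inherits(model, "ade_model")) {
    abort(paste0("'", path, "' does not contain an ade_model"))
  }
  if (!identical(model$version, 1L)) {
    abort(paste0("model version ", model$version %||% "<none>",
                 " not supported"))
  }
  model
}

#' @export
tidy.ade_model <- function(x, ...) {
  w <- x$weights[x$weights != 0]
  tibble(
    feature = names(w),
    namespace = .feature_group(names(w)),
    weight = unname(w)
  ) |> arrange(desc(abs(.data$weight)))
}

#' @export
glance.ade_model <- function(x, ...) {
  tibble(
    n_features = length(x$weights),
    n_active = sum(x$weights != 0),
    bias = x$bias,
    C = x$C,
    n_max = x$params$n_max,
    window = x$params$window,
    blind_entities = x$params$blind_entities,
    n_train = x$meta$n_train,
    seed = x$meta$seed,
    corpus_name = x$meta$corpus_name
  )
}
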