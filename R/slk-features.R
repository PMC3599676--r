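#' Shallow linguistic kernel parameters
#'
#' @param n_max maximum n-gram length of the global-context patterns
#'   (default 3).
#' @param window half-width, in tokens, of the local context around each
#'   candidate entity (default 2).
#' @param blind_entities replace the candidate entities' tokens by the
#'   placeholders `DRUG_CAND` / `COND_CAND` in the global contexts, so the
#'   classifier learns contextual rather than lexical evidence (default
#'   `TRUE`).
#' @return A `kernel_params` list.
#' @export
kernel_params <- function(n_max = 3L, window = 2L, blind_entities = TRUE) {
  stopifnot(n_max >= 1L, window >= 0L)
  structure(list(n_max = as.integer(n_max), window = as.integer(window),
                 blind_entities = isTRUE(blind_entities)),
            class = "kernel_params")
}

# ---- internal unit-sequence construction ---------------------------------
#
# The global contexts operate on the sentence as a sequence of lemma
# "units" in which each candidate entity's token run is collapsed to a
# single placeholder unit (when blinding is on). Segments:
#   FB = [sentence start, second entity]   (fore + first entity + between)
#   B  = strictly between the entities
#   BA = [first entity, sentence end]      (between + second entity + after)
# so the candidate placeholders participate in the patterns at the segment
# boundaries, while B carries pure inter-entity context.

.candidate_units <- function(cand, params) {
  toks <- cand$tokens[[1]]
  n <- nrow(toks)
  d_idx <- seq.int(cand$drug_tok_start, cand$drug_tok_end - 1L)
  c_idx <- seq.int(cand$cond_tok_start, cand$cond_tok_end - 1L)
  if (length(intersect(d_idx, c_idx))) {
    # nested candidate: no meaningful segmentation
    abort(paste0("candidate ", cand$instance_id,
                 ": drug and condition token spans overlap"))
  }
  if (anyNA(toks$lemma) || anyNA(toks$pos)) {
    abort(paste0("candidate ", cand$instance_id,
                 ": tokens lack lemma/POS annotation"))
  }
  drug_first <- min(d_idx) < min(c_idx)
  e1 <- if (drug_first) d_idx else c_idx
  e2 <- if (drug_first) c_idx else d_idx
  lab1 <- if (drug_first) "DRUG_CAND" else "COND_CAND"
  lab2 <- if (drug_first) "COND_CAND" else "DRUG_CAND"
  units <- character(0)
  upos <- integer(0)  # 1 = first entity, 2 = second entity, 0 = plain token
  i <- 1L
  while (i <= n) {
    if (i == min(e1)) {
      if (params$blind_entities) {
        units <- c(units, lab1); upos <- c(upos, 1L)
      } else {
        units <- c(units, toks$lemma[e1]); upos <- c(upos, rep(1L, length(e1)))
      }
      i <- max(e1) + 1L
    } else if (i == min(e2)) {
      if (params$blind_entities) {
        units <- c(units, lab2); upos <- c(upos, 2L)
      } else {
        units <- c(units, toks$lemma[e2]); upos <- c(upos, rep(2L, length(e2)))
      }
      i <- max(e2) + 1L
    } else {
      units <- c(units, toks$lemma[i]); upos <- c(upos, 0L)
      i <- i + 1L
    }
  }
  list(units = units, upos = upos,
       e1 = range(which(upos == 1L)), e2 = range(which(upos == 2L)),
       drug_first = drug_first)
}

.ngram_counts <- function(units, ns, n_max) {
  if (!length(units)) return(character(0))
  out <- character(0)
  for (k in seq_len(min(n_max, length(units)))) {
    if (k == 1L) {
      grams <- units
    } else {
      idx <- seq_len(length(units) - k + 1L)
      grams <- map_chr(idx, function(i) {
        paste(units[i:(i + k - 1L)], collapse = " ")
      })
    }
    out <- c(out, paste0(ns, ":", grams))
  }
  out
}

# named count vector from a character vector of keys
.count_vec <- function(keys) {
  if (!length(keys)) return(stats::setNames(numeric(0), character(0)))
  tb <- table(keys)
  stats::setNames(as.numeric(tb), names(tb))
}

.global_keys <- function(cand, params) {
  u <- .candidate_units(cand, params)
  n <- length(u$units)
  fb <- u$units[seq_len(u$e2[2])]
  b <- if (u$e2[1] - u$e1[2] > 1L) {
    u$units[(u$e1[2] + 1L):(u$e2[1] - 1L)]
  } else character(0)
  ba <- u$units[u$e1[1]:n]
  c(.ngram_counts(fb, "FB", params$n_max),
    .ngram_counts(b, "B", params$n_max),
    .ngram_counts(ba, "BA", params$n_max))
}

.local_keys <- function(cand, params) {
  toks <- cand$tokens[[1]]
  n <- nrow(toks)
  d_rng <- c(cand$drug_tok_start, cand$drug_tok_end - 1L)
  c_rng <- c(cand$cond_tok_start, cand$cond_tok_end - 1L)
  drug_first <- d_rng[1] < c_rng[1]
  ents <- if (drug_first) list(d_rng, c_rng) else list(c_rng, d_rng)
  ns <- c("LC_LEFT", "LC_RIGHT")
  cand_idx <- c(seq.int(d_rng[1], d_rng[2]), seq.int(c_rng[1], c_rng[2]))
  out <- character(0)
  if (params$window == 0L) return(out)
  for (e in 1:2) {
    rng <- ents[[e]]
    for (r in seq_len(params$window)) {
      for (sgn in c(-1L, 1L)) {
        i <- if (sgn < 0L) rng[1] - r else rng[2] + r
        if (i < 1L || i > n) next
        pos_lab <- sgn * r
        # a neighbouring token inside another entity mention exposes its
        # entity flag in place of the orthographic class
        ortho <- if (toks$ent[i] != "O" && !(i %in% cand_idx)) {
          paste0("ENT_", toks$ent[i])
        } else {
          toks$ortho[i]
        }
        out <- c(out, paste0(
          ns[e], ":", pos_lab, ":",
          c(paste0("text=", toks$text[i]),
            paste0("lemma=", toks$lemma[i]),
            paste0("pos=", toks$pos[i]),
            paste0("ortho=", ortho))
        ))
      }
    }
  }
  out
}

#' Global-context n-gram features of a relation candidate
#'
#' Contiguous lemma n-grams (lengths 1..`n_max`) over three segments of
#' the sentence: fore-between (`FB`, sentence start through the second
#' candidate entity), between (`B`, strictly between the entities) and
#' between-after (`BA`, first entity through sentence end). With
#' `blind_entities` the candidate entities appear as the single units
#' `DRUG_CAND` / `COND_CAND`. Counts keep multiplicity.
#'
#' @param cand one row of a candidate tibble (see [build_dataset()]).
#' @param params a [kernel_params()].
#' @return Tibble `namespace`, `feature`, `count`.
#' @export
global_context <- function(cand, params = kernel_params()) {
  .keys_to_tibble(.global_keys(.one_cand(cand), params))
}

#' Local-context positional token features of a relation candidate
#'
#' For each candidate entity (namespaces `LC_LEFT` for the first entity in
#' sentence order, `LC_RIGHT` for the second), every token at relative
#' position r in \[-window, +window\] outside the entity's own span emits
#' one feature per attribute: surface `text`, `lemma`, `pos` and `ortho`
#' (replaced by an `ENT_DRUG`/`ENT_CONDITION` flag for tokens belonging to
#' other entity mentions).
#'
#' @inheritParams global_context
#' @return Tibble `namespace`, `feature`, `count`.
#' @export
local_context <- function(cand, params = kernel_params()) {
  .keys_to_tibble(.local_keys(.one_cand(cand), params))
}

.one_cand <- function(cand) {
  cand <- as_tibble(cand)
  if (nrow(cand) != 1L) abort("expected exactly one candidate row")
  cand
}

.keys_to_tibble <- function(keys) {
  v <- .count_vec(keys)
  if (!length(v)) {
    return(tibble(namespace = character(), feature = character(),
                  count = numeric()))
  }
  tibble(
    namespace = sub(":.*$", "", names(v)),
    feature = names(v),
    count = unname(v)
  ) |> arrange(.data$feature)
}

# full raw count vector, all namespaces
.feature_counts <- function(cand, params) {
  .count_vec(c(.global_keys(cand, params), .local_keys(cand, params)))
}

# namespace group of each feature key; the two local-context namespaces are
# one sub-kernel, normalized jointly
.feature_group <- function(keys) {
  g <- sub(":.*$", "", keys)
  g[g %in% c("LC_LEFT", "LC_RIGHT")] <- "LC"
  g
}

.SUBKERNELS <- c("FB", "B", "BA", "LC")

# explicit map: per-group L2 normalization of the count vector
.feature_map_vec <- function(cand, params) {
  v <- .feature_counts(cand, params)
  if (!length(v)) return(v)
  g <- .feature_group(names(v))
  for (s in unique(g)) {
    idx <- g == s
    v[idx] <- v[idx] / sqrt(sum(v[idx]^2))
  }
  v
}

#' Shallow linguistic kernel between two relation candidates
#'
#' The similarity is the unweighted sum of four normalized sub-kernels:
#' the `FB`, `B` and `BA` n-gram namespaces and the combined local-context
#' namespace `LC`. Each sub-kernel is the dot product of the namespace's
#' count vectors, normalized by the geometric mean of the self-similarities
#' (defined as 0 when either side is empty). Hence `0 <= K <= 4` and
#' `K(x, x)` equals the number of non-empty sub-kernels of `x`.
#'
#' @param a,b single candidate rows.
#' @param params a [kernel_params()].
#' @return A non-negative similarity.
#' @export
slk_kernel <- function(a, b, params = kernel_params()) {
  va <- .feature_counts(.one_cand(a), params)
  vb <- .feature_counts(.one_cand(b), params)
  ga <- .feature_group(names(va))
  gb <- .feature_group(names(vb))
  total <- 0
  for (s in .SUBKERNELS) {
    xa <- va[ga == s]
    xb <- vb[gb == s]
    saa <- sum(xa^2)
    sbb <- sum(xb^2)
    if (saa == 0 || sbb == 0) next
    common <- intersect(names(xa), names(xb))
    total <- total + sum(xa[common] * xb[common]) / sqrt(saa * sbb)
  }
  total
}

#' Explicit feature map of the shallow linguistic kernel
#'
#' Concatenation of the per-sub-kernel count vectors, each L2-normalized
#' within its namespace group, so that the dot product of two feature maps
#' equals [slk_kernel()] exactly (in exact arithmetic) and a linear SVM on
#' the map is the kernel machine.
#'
#' @inheritParams global_context
#' @return Tibble `feature`, `value`; `sum(value^2)` equals
#'   `slk_kernel(cand, cand, params)`.
#' @export
feature_map <- function(cand, params = kernel_params()) {
  v <- .feature_map_vec(.one_cand(cand), params)
  tibble(feature = names(v), value = unname(v)) |> arrange(.data$feature)
}

#' Featurize a candidate dataset into a sparse matrix
#'
#' @param dataset candidate tibble from [build_dataset()].
#' @param params a [kernel_params()].
#' @param features optional fixed feature vocabulary (character); features
#'   outside it are dropped, which leaves predictions of a linear model
#'   unchanged. Default: the union observed in `dataset`.
#' @return A list with `x` (a `dgCMatrix`, rows in dataset order, row
#'   names = instance ids) and `features`.
#' @export
featurize <- function(dataset, params = kernel_params(), features = NULL) {
  vecs <- map(seq_len(nrow(dataset)), function(i) {
    .feature_map_vec(dataset[i, ], params)
  })
  if (is.null(features)) {
    features <- sort(unique(unlist(map(vecs, names))))
  }
  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (i in seq_along(vecs)) {
    v <- vecs[[i]]
    j <- match(names(v), features)
    keep <- !is.na(j)
    ii <- c(ii, rep.int(i, sum(keep)))
    jj <- c(jj, j[keep])
    xx <- c(xx, unname(v[keep]))
  }
  x <- Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(nrow(dataset), length(features)),
    dimnames = list(dataset$instance_id, features)
  )
  list(x = x, features = features, params = params)
}
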