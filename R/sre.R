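#' Write candidates in the SRE instance line format
#'
#' One line per labelled candidate: `<label>TAB<instance_id>TAB<token
#' stream>`, where the label is `1` for `TRUE` and `0` for `FALSE` and the
#' token stream joins per-token records
#' `<index>&&<text>&&<lemma>&&<pos>&&<etype|O>&&<role>` with single
#' spaces. Roles: `A` = candidate drug tokens, `T` = candidate condition
#' tokens, `O` = everything else. Token indices are 0-based. Lines are
#' ordered by (doc id, sentence id, drug offset, condition offset).
#'
#' @param dataset labelled candidate tibble (no `UNKNOWN` labels; all
#'   tokens must carry lemma and POS annotation).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sre <- function(dataset, path) {
  if (any(dataset$label == "UNKNOWN")) {
    abort("SRE output requires labelled candidates (TRUE/FALSE)")
  }
  ord <- order(dataset$doc_id, dataset$sid, dataset$drug_start,
               dataset$cond_start)
  dataset <- dataset[ord, ]
  lines <- map_chr(seq_len(nrow(dataset)), function(i) {
    cand <- dataset[i, ]
    toks <- cand$tokens[[1]]
    if (anyNA(toks$lemma) || anyNA(toks$pos) ||
        any(!nzchar(toks$lemma)) || any(!nzchar(toks$pos))) {
      abort(paste0("candidate ", cand$instance_id,
                   ": incomplete annotation (missing lemma/POS)"))
    }
    if (any(grepl("&&|\\s", toks$text))) {
      abort(paste0("candidate ", cand$instance_id,
                   ": token text not encodable in SRE"))
    }
    role <- rep("O", nrow(toks))
    role[seq.int(cand$drug_tok_start, cand$drug_tok_end - 1L)] <- "A"
    role[seq.int(cand$cond_tok_start, cand$cond_tok_end - 1L)] <- "T"
    ent <- if ("ent" %in% names(toks)) toks$ent else rep("O", nrow(toks))
    stream <- paste(
      paste(seq_len(nrow(toks)) - 1L, toks$text, toks$lemma, toks$pos,
            ent, role, sep = "&&"),
      collapse = " "
    )
    paste(if (cand$label == "TRUE") "1" else "0", cand$instance_id,
          stream, sep = "\t")
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read candidates from the SRE line format
#'
#' Inverse of [write_sre()] up to canonical ordering. Character offsets are
#' reconstructed by joining tokens with single spaces (the raw sentence
#' string is not part of the format); normalized ids are absent (`NA`) and
#' orthographic classes are recomputed from the surface forms.
#'
#' @param path SRE file.
#' @return A candidate tibble with `label`, `instance_id` and full token
#'   annotation restored.
#' @export
read_sre <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(.empty_candidates())
  map_dfr(seq_along(lines), function(ln) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      abort(paste0("SRE line ", ln, ": expected 3 tab-separated fields"))
    }
    if (!parts[1] %in% c("0", "1")) {
      abort(paste0("SRE line ", ln, ": bad label '", parts[1], "'"))
    }
    recs <- strsplit(strsplit(parts[3], " ", fixed = TRUE)[[1]], "&&",
                     fixed = TRUE)
    bad <- which(lengths(recs) != 6L)
    if (length(bad)) {
      abort(paste0("SRE line ", ln, ": token ", bad[1],
                   " has ", lengths(recs)[bad[1]], " fields, expected 6"))
    }
    text <- map_chr(recs, 2)
    width <- nchar(text)
    start <- cumsum(c(0L, head(width + 1L, -1L)))
    toks <- tibble(
      text = text,
      lemma = map_chr(recs, 3),
      pos = map_chr(recs, 4),
      ortho = .ortho_class(text),
      start = start,
      end = start + width,
      ent = map_chr(recs, 5)
    )
    role <- map_chr(recs, 6)
    d_idx <- which(role == "A")
    c_idx <- which(role == "T")
    if (!length(d_idx) || !length(c_idx)) {
      abort(paste0("SRE line ", ln, ": missing candidate role A or T"))
    }
    id <- parts[2]
    m <- regmatches(id, regexec("^(.+)\\.([^.]+)\\.d[0-9]+\\.c[0-9]+$", id))[[1]]
    tibble(
      doc_id = if (length(m)) m[2] else id,
      sid = if (length(m)) m[3] else "s1",
      instance_id = id,
      label = if (parts[1] == "1") "TRUE" else "FALSE",
      drug_text = paste(text[d_idx], collapse = " "),
      cond_text = paste(text[c_idx], collapse = " "),
      drug_id = NA_character_, cond_id = NA_character_,
      drug_provenance = NA_character_, cond_provenance = NA_character_,
      drug_start = toks$start[d_idx[1]],
      drug_end = toks$end[d_idx[length(d_idx)]],
      cond_start = toks$start[c_idx[1]],
      cond_end = toks$end[c_idx[length(c_idx)]],
      drug_tok_start = d_idx[1], drug_tok_end = d_idx[length(d_idx)] + 1L,
      cond_tok_start = c_idx[1], cond_tok_end = c_idx[length(c_idx)] + 1L,
      tokens = list(toks)
    )
  })
}
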