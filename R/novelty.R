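#' Aggregate positive predictions into a normalized pair ledger
#'
#' Collapses sentence-level `TRUE` predictions into distinct
#' (drug id, event id) pairs with their support: how many predictions and
#' how many distinct documents back each pair. Comparison against
#' references happens strictly in identifier space, so candidates whose
#' mentions lack a normalized id are tallied and skipped with a warning,
#' never matched by surface string.
#'
#' @param predictions tibble from [predict.ade_model()] (needs
#'   `instance_id`, `label`).
#' @param cands the candidate tibble the predictions were made on (source
#'   of `drug_id`, `cond_id`, `doc_id`).
#' @return An `ade_pair_ledger` tibble: `drug_id`, `event_id`, `support`,
#'   `n_docs`, `doc_ids` (list-column).
#' @export
aggregate_pairs <- function(predictions, cands) {
  df <- left_join(
    filter(predictions, .data$label == "TRUE"),
    select(cands, "instance_id", "doc_id", "drug_id", "cond_id"),
    by = "instance_id"
  )
  skipped <- sum(is.na(df$drug_id) | is.na(df$cond_id))
  if (skipped > 0) {
    warn(paste0(skipped, " positive prediction(s) without normalized ids ",
                "skipped"))
    df <- filter(df, !is.na(.data$drug_id) & !is.na(.data$cond_id))
  }
  out <- df |>
    group_by(drug_id = .data$drug_id, event_id = .data$cond_id) |>
    summarise(
      support = n(),
      n_docs = length(unique(.data$doc_id)),
      doc_ids = list(sort(unique(.data$doc_id))),
      .groups = "drop"
    ) |>
    arrange(desc(.data$support), .data$drug_id, .data$event_id)
  class(out) <- c("ade_pair_ledger", class(out))
  out
}

#' Load a drug/event reference table
#'
#' Two tab-separated identifier columns (`drug_id`, `event_id`), `#`
#' comments and blank lines ignored, duplicates dropped. Used for
#' side-effect references compiled from product leaflets (SIDER-style) and
#' for regulator label-change tables used to validate novel pairs.
#'
#' @param path TSV file.
#' @param name source name recorded on the table.
#' @return An `ade_reference` tibble of distinct pairs.
#' @export
load_reference <- function(path, name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    abort(paste0("reference '", path, "' line ", keep[bad[1]],
                 ": expected 2 tab-separated fields"))
  }
  out <- distinct(tibble(drug_id = map_chr(parts, 1),
                         event_id = map_chr(parts, 2)))
  attr(out, "source") <- name
  class(out) <- c("ade_reference", class(out))
  out
}

#' Pairs extracted from text but absent from a reference
#'
#' The pharmacovigilance payoff: extracted (drug, adverse event) pairs not
#' yet present in the side-effect reference are candidate under-reported
#' signals. Sorted by support (descending), then lexicographically.
#'
#' @param ledger an [aggregate_pairs()] ledger.
#' @param reference an [load_reference()] table.
#' @param min_support minimum prediction support to report (default 1).
#' @return Tibble of novel pairs, a subset of `ledger` rows.
#' @export
novel_pairs <- function(ledger, reference, min_support = 1L) {
  out <- ledger |>
    anti_join(as_tibble(reference), by = c("drug_id", "event_id")) |>
    filter(.data$support >= min_support) |>
    arrange(desc(.data$support), .data$drug_id, .data$event_id)
  out
}

#' Validate novel pairs against a second reference
#'
#' Intersects novel pairs with an independent table (e.g. regulator drug
#' label changes) to confirm which extracted signals were later
#' acknowledged.
#'
#' @param pairs output of [novel_pairs()].
#' @param reference an [load_reference()] table.
#' @return The subset of `pairs` present in `reference`.
#' @export
validate_pairs <- function(pairs, reference) {
  semi_join(pairs, as_tibble(reference), by = c("drug_id", "event_id"))
}
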