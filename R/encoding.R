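# Vocabulary construction and sequence encoding.
#
# Each labeled sample becomes an ordered list of visits; a visit is the set
# of in-vocabulary integer code indices observed on one encounter date plus
# the day gap to the previous visit. Index 1 is reserved for
# out-of-vocabulary codes so unseen codes keep the visit structure instead of
# silently vanishing.

OOV_TOKEN <- "<OOV>"
OOV_INDEX <- 1L

#' Map ICD-9 diagnosis codes to 3-character ICD-10 groups
#'
#' Codes found in the lookup are mapped to their ICD-10 group; codes that
#' already look like ICD-10 (letter + digit) pass through truncated to their
#' 3-character group; anything else becomes the out-of-vocabulary marker with
#' one warning listing the offenders.
#'
#' @param codes Character vector of diagnosis codes.
#' @param lookup Tibble with columns `icd9` and `icd10_group`.
#' @return Character vector of groups, same length as `codes`.
#' @export
map_icd9_to_icd10 <- function(codes, lookup) {
  if (!all(c("icd9", "icd10_group") %in% names(lookup))) {
    abort("`lookup` needs columns icd9 and icd10_group.")
  }
  bad <- which(is.na(codes) | !nzchar(trimws(codes)))
  if (length(bad)) {
    abort(sprintf("malformed diagnosis code at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  out <- lookup$icd10_group[match(codes, lookup$icd9)]
  icd10_like <- is.na(out) & grepl("^[A-Za-z][0-9]", codes)
  out[icd10_like] <- toupper(substr(codes[icd10_like], 1, 3))
  unmapped <- is.na(out)
  if (any(unmapped)) {
    warn(sprintf("%d diagnosis code(s) not mappable; using %s: %s",
                 sum(unmapped), OOV_TOKEN,
                 paste(unique(codes[unmapped])[1:min(5, length(unique(codes[unmapped])))],
                       collapse = ", ")))
    out[unmapped] <- OOV_TOKEN
  }
  out
}

#' Read a two-column ICD-9 to ICD-10 lookup TSV
#'
#' @param path Path to a TSV with columns `icd9` and `icd10_group`.
#' @return A tibble.
#' @export
read_icd_lookup <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Build a capped code vocabulary from training samples
#'
#' Built from the training split only, so no information from validation or
#' test patients leaks into the feature space. Lab codes are ranked by
#' patient-level frequency and capped at `lab_top_k` (the most frequently
#' tested labs); all retained codes are then ordered by frequency (desc) with
#' a lexicographic tie-break and indexed densely after the reserved
#' out-of-vocabulary index.
#'
#' @param train_samples Samples tibble (rows with an `events` list-column),
#'   training split only.
#' @param lab_top_k Cap on lab codes (default 89).
#' @param max_size Overall vocabulary cap including the OOV slot
#'   (default 30000).
#' @return A tibble of class `ehr_vocab`: `code, code_type, index`, with the
#'   OOV token at index 1.
#' @export
build_vocabulary <- function(train_samples, lab_top_k = 89, max_size = 30000) {
  if (!nrow(train_samples)) abort("empty training split: cannot build a vocabulary.")
  counts <- train_samples |>
    select("patient_id", "events") |>
    tidyr::unnest("events") |>
    distinct(.data$patient_id, .data$code_type, .data$code) |>
    count(.data$code_type, .data$code, name = "n_patients") |>
    arrange(desc(.data$n_patients), .data$code)
  labs <- counts |> filter(.data$code_type == "LAB_ABN") |> head(lab_top_k)
  rest <- counts |> filter(.data$code_type != "LAB_ABN")
  vocab <- bind_rows(rest, labs) |>
    arrange(desc(.data$n_patients), .data$code) |>
    head(max_size - 1L) |>
    mutate(index = row_number() + 1L) |>
    select("code", "code_type", "index")
  vocab <- bind_rows(
    tibble(code = OOV_TOKEN, code_type = "OOV", index = OOV_INDEX),
    vocab
  )
  class(vocab) <- c("ehr_vocab", class(vocab))
  vocab
}

vocab_size <- function(vocab) nrow(vocab)

vocab_index <- function(vocab, codes) {
  idx <- vocab$index[match(codes, vocab$code)]
  idx[is.na(idx)] <- OOV_INDEX
  idx
}

#' Encode labeled samples as integer-indexed visit sequences
#'
#' One visit per encounter date; codes are deduplicated within a visit and
#' mapped through the vocabulary (unknown codes to the shared OOV index);
#' `delta` holds the integer day gap to the previous visit (0 for the
#' first).
#'
#' @param samples Samples tibble with `events` list-column (typically split
#'   output of [split_cohort()]).
#' @param vocab An `ehr_vocab` from [build_vocabulary()].
#' @return A tibble of class `encoded_cohort`: `sample_id, patient_id,
#'   label` (0/1), `split` if present, plus list-columns `visits` (integer
#'   vectors), `codes` (the code strings, parallel to `visits`), `days`
#'   (integer visit days relative to the first visit) and `delta`.
#' @export
encode_samples <- function(samples, vocab) {
  enc <- purrr::map(samples$events, function(ev) {
    if (!nrow(ev)) {
      return(list(visits = list(), codes = list(), days = integer(0),
                  delta = integer(0)))
    }
    ev <- ev |> distinct(.data$date, .data$code, .keep_all = TRUE) |>
      arrange(.data$date, .data$code)
    by_day <- split(ev, ev$date)
    days <- as.integer(as.Date(names(by_day)) - min(ev$date))
    list(
      visits = purrr::map(by_day, function(v) vocab_index(vocab, v$code)),
      codes = purrr::map(by_day, function(v) v$code),
      days = days,
      delta = c(0L, diff(days))
    )
  })
  out <- tibble(
    sample_id = paste0(samples$patient_id, "@", format(samples$index_date)),
    patient_id = samples$patient_id,
    label = as.integer(samples$label == "case"),
    visits = purrr::map(enc, function(e) unname(e$visits)),
    codes = purrr::map(enc, function(e) unname(e$codes)),
    days = purrr::map(enc, "days"),
    delta = purrr::map(enc, "delta")
  )
  if ("split" %in% names(samples)) out$split <- samples$split
  if ("provenance" %in% names(samples)) out$provenance <- samples$provenance
  attr(out, "vocab") <- vocab
  class(out) <- c("encoded_cohort", class(out))
  out
}

#' Decode an encoded sample back to per-visit code sets
#'
#' Inverse of [encode_samples()] for in-vocabulary codes: OOV indices decode
#' to the OOV marker.
#'
#' @param encoded An `encoded_cohort` row subset (or whole tibble).
#' @param vocab The vocabulary used for encoding (defaults to the one
#'   attached to `encoded`).
#' @return A list (per sample) of lists (per visit) of code strings.
#' @export
decode_sample <- function(encoded, vocab = attr(encoded, "vocab")) {
  purrr::map(encoded$visits, function(vs) {
    purrr::map(vs, function(v) sort(vocab$code[match(v, vocab$index)]))
  })
}

#' Drop one code type from encoded sequences (ablation)
#'
#' Removes every index of the given type, drops visits that become empty,
#' and recomputes day gaps from the surviving visit dates. Labels are
#' unchanged.
#'
#' @param encoded An `encoded_cohort`.
#' @param drop One of `"DIAG"`, `"MED"`, `"LAB_ABN"`.
#' @param vocab Vocabulary (defaults to the attached one).
#' @return An `encoded_cohort` of the same shape.
#' @export
ablate_codes <- function(encoded, drop, vocab = attr(encoded, "vocab")) {
  if (!drop %in% CODE_TYPES) {
    abort(sprintf("`drop` must be one of %s.", paste(CODE_TYPES, collapse = ", ")))
  }
  dropped_idx <- vocab$index[vocab$code_type == drop]
  out <- encoded
  pruned <- purrr::pmap(list(encoded$visits, encoded$codes, encoded$days),
                        function(vs, cs, days) {
    kept <- purrr::map(vs, function(v) v[!v %in% dropped_idx])
    keep_visit <- lengths(kept) > 0L
    kept_codes <- purrr::map2(cs, vs, function(cv, v) cv[!v %in% dropped_idx])
    days <- days[keep_visit]
    list(visits = kept[keep_visit], codes = kept_codes[keep_visit], days = days,
         delta = if (length(days)) c(0L, diff(days)) else integer(0))
  })
  out$visits <- purrr::map(pruned, "visits")
  out$codes <- purrr::map(pruned, "codes")
  out$days <- purrr::map(pruned, "days")
  out$delta <- purrr::map(pruned, "delta")
  out
}

#' Serialize a vocabulary to / from two-column TSV
#'
#' @param vocab An `ehr_vocab`.
#' @param path File path.
#' @name vocab-io
#' @export
write_vocabulary <- function(vocab, path) {
  readr::write_tsv(vocab[, c("code", "code_type", "index")], path)
  invisible(vocab)
}

#' @rdname vocab-io
#' @export
read_vocabulary <- function(path) {
  vocab <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(index = readr::col_integer(),
                                                   .default = readr::col_character()))
  class(vocab) <- c("ehr_vocab", class(vocab))
  vocab
}
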