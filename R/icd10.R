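# ICD-10 parsing and the 20-category disease grouping used for burden tables.
# Two standard chapters are merged and re-split: injury/poisoning (S00-T98)
# and external causes of morbidity and mortality (V01-Y98) are pooled, then
# intentional self-harm (X60-X84) is pulled out as its own category.

the_groups <- new.env(parent = emptyenv())

range_key <- function(code) {
  # lexicographic order on (letter, number) as an integer key
  (match(substr(code, 1L, 1L), LETTERS) - 1L) * 100L +
    as.integer(substr(code, 2L, 3L))
}

parse_block_ranges <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) {
    return(data.frame(lo = integer(), hi = integer()))
  }
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  ends <- strsplit(trimws(parts), "-", fixed = TRUE)
  data.frame(
    lo = vapply(ends, function(e) range_key(e[[1]]), integer(1)),
    hi = vapply(ends, function(e) range_key(e[[length(e)]]), integer(1))
  )
}

#' Disease-group mapping table
#'
#' The 20 disease categories used throughout the package: the standard ICD-10
#' chapter blocks, with S00-T98 and V01-Y98 pooled into a single external
#' causes/injuries category from which intentional self-harm (X60-X84) is
#' separated out. The table ships as a plain CSV
#' (`system.file("extdata", "icd10_groups.csv", package = "wyloss")`) so the
#' grouping can be audited; `disease_groups()` returns it parsed.
#'
#' The endocrine/metabolic row is written E00-E99 (E91-E99 are unused in
#' ICD-10, so the wider range is harmless). Codes outside every block -
#' e.g. the perinatal chapter P00-P96, U-codes, or gap codes such as D49 -
#' are not part of the grouping; see [icd10_group()].
#'
#' @return A tibble with columns `label`, `blocks`, `exclusions`.
#' @export
disease_groups <- function() {
  if (is.null(the_groups$table)) {
    path <- system.file("extdata", "icd10_groups.csv", package = "wyloss")
    tbl <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = NULL)
    the_groups$table <- tibble::as_tibble(tbl)
    the_groups$ranges <- lapply(seq_len(nrow(tbl)), function(i) {
      list(
        label = tbl$label[i],
        inc = parse_block_ranges(tbl$blocks[i]),
        exc = parse_block_ranges(tbl$exclusions[i])
      )
    })
  }
  the_groups$table
}

#' Group labels in table order
#' @return Character vector of the 20 category labels.
#' @export
disease_group_labels <- function() disease_groups()$label

#' Parse ICD-10 codes to canonical three-character form
#'
#' Accepts codes like `"F32"`, `"F32.1"`, `"f321"`, with or without a dot;
#' sub-classification digits beyond the first three characters are dropped,
#' since grouping only ever uses the letter + two-digit base code.
#'
#' @param raw Character vector of raw code strings.
#' @return Character vector of canonical codes (`"F32"`).
#' @examples
#' parse_icd10(c("F32.1", "x70")) # "F32" "X70"
#' @export
parse_icd10 <- function(raw) {
  raw <- trimws(as.character(raw))
  ok <- grepl("^[A-Za-z][0-9]{2}", raw)
  if (!all(ok)) {
    stop(sprintf(
      "parse_icd10: malformed ICD-10 code(s): %s",
      paste(sQuote(unique(raw[!ok])), collapse = ", ")
    ), call. = FALSE)
  }
  toupper(substr(raw, 1L, 3L))
}

#' Map ICD-10 codes to disease-group labels
#'
#' Assigns each three-character code to exactly one of the 20 categories of
#' [disease_groups()]. X60-X84 always lands in "Intentional self-harm"; every
#' other code in S00-T98 or V01-Y98 lands in the pooled external
#' causes/injuries category.
#'
#' @param code Character vector of ICD-10 codes (parsed with [parse_icd10()]
#'   first if raw).
#' @param unmapped What to do with codes outside every block: `"error"`
#'   (default; dirty data should fail loudly) or `"unclassified"`, which
#'   buckets them under the label `"Unclassified"`.
#' @return Character vector of group labels.
#' @examples
#' icd10_group(c("F32", "X70", "V43", "C50"))
#' @export
icd10_group <- function(code, unmapped = c("error", "unclassified")) {
  unmapped <- match.arg(unmapped)
  code <- parse_icd10(code)
  disease_groups() # ensure ranges cached
  key <- range_key(code)
  out <- rep(NA_character_, length(code))
  for (g in the_groups$ranges) {
    inc <- rep(FALSE, length(key))
    for (i in seq_len(nrow(g$inc))) {
      inc <- inc | (key >= g$inc$lo[i] & key <= g$inc$hi[i])
    }
    for (i in seq_len(nrow(g$exc))) {
      inc <- inc & !(key >= g$exc$lo[i] & key <= g$exc$hi[i])
    }
    hit <- inc & is.na(out)
    out[hit] <- g$label
  }
  if (anyNA(out)) {
    if (unmapped == "error") {
      stop(sprintf(
        "icd10_group: code(s) outside every disease-group block: %s",
        paste(sQuote(unique(code[is.na(out)])), collapse = ", ")
      ), call. = FALSE)
    }
    out[is.na(out)] <- "Unclassified"
  }
  out
}
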