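#' Extract TICI grades from radiology report text
#'
#' Rule-based text mining of Thrombolysis In Cerebral Infarction (TICI)
#' grades. Grade tokens are matched case-insensitively for the spellings
#' `TICI`, `mTICI` and `eTICI` followed by a grade from
#' \{0, 1, 2a, 2b, 2c, 3\} with an optional space, hyphen or colon in
#' between. Repeated mentions of the same grade count once: a report is
#' `unique` when exactly one distinct grade is found, `none` when no grade
#' is found, and `multiple` when two or more distinct grades are found.
#' Reports with status `none` or `multiple` receive outcome `needs_manual`
#' (they would be routed to manual labeling); `unique` reports are
#' binarized with [tici_binarize()].
#'
#' @param reports A data frame with columns `patient_id` and `text`, or a
#'   character vector of report texts.
#' @return A tibble with one row per report: `patient_id`, `grades`
#'   (list-column of distinct grades in order of first mention), `n_grades`,
#'   `status` (`unique`/`none`/`multiple`) and `outcome`
#'   (`success`/`failure`/`needs_manual`).
#' @export
#' @examples
#' extract_tici("Final result: mTICI 2b after two passes")
#' extract_tici(c("TICI 2a initially, TICI 3 after aspiration", ""))
extract_tici <- function(reports) {
  if (is.character(reports)) {
    reports <- tibble::tibble(
      patient_id = sprintf("R%04d", seq_along(reports)),
      text = reports
    )
  }
  if (!all(c("patient_id", "text") %in% names(reports))) {
    stop_invalid("`reports` needs columns patient_id and text.")
  }
  if (any(is.na(reports$text))) {
    stop_invalid("report text must be non-null; got NA.")
  }
  pattern <- stringr::regex(
    "\\b[em]?TICI\\s*[-:]?\\s*(2[abc]|[013])\\b",
    ignore_case = TRUE
  )
  matches <- stringr::str_match_all(reports$text, pattern)
  grades <- purrr::map(matches, function(m) unique(tolower(m[, 2L])))
  n_grades <- lengths(grades)
  status <- dplyr::case_when(
    n_grades == 0L ~ "none",
    n_grades == 1L ~ "unique",
    TRUE ~ "multiple"
  )
  outcome <- rep("needs_manual", nrow(reports))
  uniq <- status == "unique"
  if (any(uniq)) {
    outcome[uniq] <- tici_binarize(purrr::map_chr(grades[uniq], 1L))
  }
  tibble::tibble(
    patient_id = reports$patient_id,
    grades = grades,
    n_grades = n_grades,
    status = status,
    outcome = outcome
  )
}

#' Binarize a TICI grade into the study outcome
#'
#' Grade 3 is successful recanalization; grades 0, 1, 2a, 2b and 2c are
#' unsuccessful. Note that 2b/2c are counted as failure here (some
#' literatures group 2b-3 as success); this dichotomy isolates complete
#' recanalization.
#'
#' @param grade Character vector of grades in \{0, 1, 2a, 2b, 2c, 3\}
#'   (case-insensitive).
#' @return Character vector, `"success"` or `"failure"`.
#' @export
#' @examples
#' tici_binarize(c("3", "2c", "0"))
tici_binarize <- function(grade) {
  grade <- tolower(as.character(grade))
  valid <- c("0", "1", "2a", "2b", "2c", "3")
  bad <- setdiff(unique(grade), valid)
  if (length(bad)) {
    rlang::abort(
      sprintf("unknown TICI grade token(s): %s", paste(bad, collapse = ", ")),
      class = "bccstrat_parse_error"
    )
  }
  ifelse(grade == "3", "success", "failure")
}
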