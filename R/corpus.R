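#' Segment a thought report into sentences
#'
#' Deterministic rule-based segmentation: reports are split at terminal
#' punctuation (`.`, `!`, `?`), with a guard list of common abbreviations
#' so that e.g. "Dr." does not end a sentence.  Fragments are
#' whitespace-trimmed and empty ones dropped.  The sentence is the unit
#' of all downstream semantic analysis.
#'
#' @param text a single character string (may be empty).
#' @return character vector of sentences, in source order.
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  guard <- c("Mr", "Mrs", "Ms", "Dr", "Prof", "St", "vs", "etc", "approx",
             "e.g", "i.e", "cf", "al")
  protected <- text
  for (ab in guard) {
    protected <- gsub(paste0("\\b", gsub(".", "\\.", ab, fixed = TRUE), "\\."),
                      paste0(gsub(".", "․", ab, fixed = TRUE), "․"),
                      protected, ignore.case = TRUE)
  }
  parts <- strsplit(protected, "(?<=[.!?])[.!?]*\\s+|(?<=[.!?])[.!?]*$",
                    perl = TRUE)[[1]]
  parts <- gsub("․", ".", parts, fixed = TRUE)
  parts <- trimws(gsub("[.!?]+$", "", parts))
  parts[nzchar(parts)]
}

#' Remove prompt words from report sentences
#'
#' Before computing prompt centrality, every token matching the cued
#' object's name (or its simple plural) is removed from every sentence,
#' case-insensitively, so that literal mentions of the cue cannot inflate
#' the similarity of a report to its own prompt.  Sentences emptied by the
#' filtering are dropped; order is preserved.
#'
#' @param sentences character vector of sentences.
#' @param cue_object `"Fork"` or `"Tree"`.
#' @param stem if `TRUE`, also remove simple derivational forms
#'   (tokens starting with the cue word); off by default — "prompt words"
#'   are matched literally.
#' @return filtered character vector.
#' @export
filter_prompt_words <- function(sentences, cue_object = c("Fork", "Tree"),
                                stem = FALSE) {
  cue_object <- match.arg(cue_object)
  if (length(sentences) == 0L) return(character(0))
  word <- tolower(cue_object)
  pat <- if (stem) paste0("\\b", word, "\\w*\\b") else paste0("\\b", word, "s?\\b")
  out <- gsub(pat, "", sentences, ignore.case = TRUE)
  out <- trimws(gsub("\\s+", " ", out))
  out[grepl("[[:alnum:]]", out)]
}

#' Read a table of thought reports
#'
#' One row per participant-by-condition report: `participant_id`,
#' `condition`, `cue_object`, `text`.  The `text` field is expected to
#' have been cleaned by the caller to contain only thought content (the
#' removal of meta-commentary addressed to the experimenter is a manual
#' step outside this package).
#'
#' @param path path to a CSV (`.csv`) or tab-separated (`.tsv`/`.txt`) file.
#' @return data frame of reports.
#' @export
read_reports <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  reports <- utils::read.table(path, sep = sep, header = TRUE,
                               stringsAsFactors = FALSE, quote = "\"",
                               comment.char = "")
  need <- c("participant_id", "condition", "cue_object", "text")
  if (!all(need %in% names(reports))) {
    stop("report table must have columns: ", paste(need, collapse = ", "))
  }
  reports$text[is.na(reports$text)] <- ""
  reports
}

#' @rdname read_reports
#' @param reports a report data frame.
#' @export
write_reports <- function(reports, path) {
  utils::write.csv(reports, path, row.names = FALSE)
  invisible(path)
}

#' Read reports from a directory of plain-text files
#'
#' Files named `<participant_id>_<condition>_<cue_object>.txt`, each
#' holding one report.
#'
#' @param dir directory path.
#' @return data frame as in [read_reports()].
#' @export
read_reports_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0L) stop("no .txt report files found in ", dir)
  parts <- strsplit(sub("\\.txt$", "", basename(files)), "_")
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("report file names must look like <id>_<condition>_<cue>.txt; bad: ",
         paste(basename(files)[bad], collapse = ", "))
  }
  data.frame(
    participant_id = vapply(parts, `[[`, character(1), 1L),
    condition = vapply(parts, `[[`, character(1), 2L),
    cue_object = vapply(parts, `[[`, character(1), 3L),
    text = vapply(files, function(f) paste(readLines(f, warn = FALSE),
                                           collapse = " "), character(1)),
    stringsAsFactors = FALSE)
}
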