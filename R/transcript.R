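#' Tokenize raw transcript text
#'
#' Splits UTF-8 text into word tokens: maximal runs of non-whitespace
#' characters, optionally lowercased and stripped of leading/trailing
#' punctuation. Intra-word hyphens and apostrophes are kept, since dropping
#' them would split or merge words the speaker actually produced. Filler
#' words and disfluencies, if present in the transcription, are treated as
#' ordinary words.
#'
#' @param raw_text character scalar (or vector, concatenated with spaces).
#' @param lowercase fold case before returning tokens (default `TRUE`).
#' @param strip_punct remove leading/trailing punctuation from each token
#'   (default `TRUE`). Tokens reduced to the empty string are dropped.
#' @return character vector of tokens, possibly empty for whitespace-only
#'   input.
#' @examples
#' tokenize("A dog. The dog ran")
#' @export
tokenize <- function(raw_text, lowercase = TRUE, strip_punct = TRUE) {
  stopifnot(is.character(raw_text))
  txt <- paste(raw_text, collapse = " ")
  if (lowercase) txt <- tolower(txt)
  toks <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
  if (length(toks) == 0L || identical(toks, "")) return(character(0))
  if (strip_punct) {
    # strip punctuation only at token boundaries; keep it word-internally
    toks <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", toks)
    toks <- toks[nzchar(toks)]
  }
  toks
}

#' Known report types for time-limited verbal reports
#' @keywords internal
.report_types <- c("dream", "yesterday", "oldest",
                   "image_negative", "image_neutral", "image_positive",
                   "other")

#' Construct a transcript object
#'
#' A transcript is the pipeline's atomic input: an ordered token sequence
#' with subject and report-type metadata. Token order is meaningful and
#' preserved; an empty token sequence is rejected at pipeline entry.
#'
#' @param x character vector of tokens, or a single string of raw text
#'   (tokenized with [tokenize()] defaults when it contains whitespace or
#'   `tokenize = TRUE`).
#' @param subject_id opaque subject identifier.
#' @param report_type one of `"dream"`, `"yesterday"`, `"oldest"`,
#'   `"image_negative"`, `"image_neutral"`, `"image_positive"`, `"other"`.
#' @param duration_s report duration in seconds (30 for the time-limited
#'   protocol) or `NA`.
#' @param tokenize force tokenization of `x` even if it has length > 1.
#' @return object of class `"transcript"` with fields `subject_id`,
#'   `report_type`, `tokens`, `duration_s`.
#' @export
transcript <- function(x, subject_id = "s1", report_type = "other",
                       duration_s = NA_real_, tokenize = FALSE) {
  report_type <- match.arg(report_type, .report_types)
  toks <- if (is.character(x) && (tokenize || length(x) == 1L)) {
    tokenize(x)
  } else {
    as.character(x)
  }
  if (length(toks) == 0L) {
    stop("empty transcript: no tokens after tokenization", call. = FALSE)
  }
  if (any(!nzchar(toks)) || any(grepl("[[:space:]]", toks))) {
    stop("tokens must be non-empty strings without internal whitespace",
         call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), report_type = report_type,
         tokens = toks, duration_s = duration_s),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> subject %s, %s report: %d tokens (%d distinct)\n",
              x$subject_id, x$report_type, length(x$tokens),
              length(unique(x$tokens))))
  preview <- paste(utils::head(x$tokens, 12L), collapse = " ")
  if (length(x$tokens) > 12L) preview <- paste(preview, "...")
  cat(" ", preview, "\n")
  invisible(x)
}

#' Read transcripts from a TSV table or a directory of text files
#'
#' The TSV must carry columns `subject_id`, `report_type` and `text`
#' (UTF-8). A directory is read as one report per `.txt` file named
#' `<subject_id>_<report_type>.txt`.
#'
#' @param path TSV file or directory.
#' @param ... passed to [tokenize()].
#' @return list of [transcript()] objects.
#' @export
read_transcripts <- function(path, ...) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    if (length(files) == 0L) stop("no .txt transcripts found in ", path)
    return(lapply(files, function(f) {
      base <- sub("\\.txt$", "", basename(f))
      parts <- strsplit(base, "_", fixed = TRUE)[[1]]
      rt <- paste(parts[-1], collapse = "_")
      if (!rt %in% .report_types) rt <- "other"
      transcript(tokenize(paste(readLines(f, warn = FALSE), collapse = " "),
                          ...),
                 subject_id = parts[1], report_type = rt)
    }))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  need <- c("subject_id", "report_type", "text")
  if (!all(need %in% names(tab))) {
    stop("transcript table must have columns: ",
         paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    transcript(tokenize(tab$text[i], ...),
               subject_id = tab$subject_id[i],
               report_type = tab$report_type[i])
  })
}
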