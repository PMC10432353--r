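# JSON-Lines interfaces: one record per line, span offsets 0-based half-open.

.to_json_line <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   dataframe = "rows")
}

.canon_record <- function(rec) {
  for (task in .span_tasks) {
    if (!is.null(rec[[task]]) || task != "evidence_spans") {
      rec[[task]] <- as_span_set(rec[[task]])
    }
  }
  if (!is.null(rec$adjudication_flags)) {
    rec$adjudication_flags <- as.character(unlist(rec$adjudication_flags))
  }
  rec
}

#' Write / read a corpus as JSON-Lines
#'
#' One note per line: `{note_id, specialty, dialect, raw_text, truth: {...},
#' annotations: [...]}` with span sets as arrays of `{start, end, text}`
#' objects (0-based half-open offsets into `raw_text`).
#'
#' @param corpus List of notes.
#' @param path File path.
#' @return `write_corpus_jsonl` returns `path` invisibly; `read_corpus_jsonl`
#'   returns the corpus list.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  writeLines(vapply(corpus, function(n) as.character(.to_json_line(n)), ""),
             path)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lapply(readLines(path, warn = FALSE), function(line) {
    note <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    note$truth <- .canon_record(note$truth)
    if (!is.null(note$annotations)) {
      note$annotations <- lapply(note$annotations, .canon_record)
    }
    note
  })
}

#' Write / read prediction or gold records as JSON-Lines
#'
#' @param records List of records (predictions or merged gold records).
#' @param path File path.
#' @return `write_records_jsonl` returns `path` invisibly;
#'   `read_records_jsonl` the list of records.
#' @export
write_records_jsonl <- function(records, path) {
  writeLines(vapply(records, function(r) as.character(.to_json_line(r)), ""),
             path)
  invisible(path)
}

#' @rdname write_records_jsonl
#' @export
read_records_jsonl <- function(path) {
  lapply(readLines(path, warn = FALSE), function(line) {
    .canon_record(jsonlite::fromJSON(line, simplifyVector = FALSE))
  })
}
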