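#' Construct a span set
#'
#' Spans are stored as a data frame with 0-based half-open character offsets
#' (`start`, `end`) and the referenced substring (`text`). A span set with no
#' rows represents "no answer" / absence of annotated text.
#'
#' @param start,end Integer vectors of equal length; `0 <= start < end`.
#' @param text Character vector of the referenced substrings.
#' @return A data frame with columns `start`, `end`, `text`.
#' @export
#' @examples
#' span_set(0L, 5L, "hello")
#' span_set()  # empty: no answer
span_set <- function(start = integer(), end = integer(), text = character()) {
  start <- as.integer(start)
  end <- as.integer(end)
  text <- as.character(text)
  if (length(start) != length(end) || length(start) != length(text)) {
    stop("start, end and text must have equal length")
  }
  if (any(start < 0L) || any(end <= start)) {
    stop("spans require 0 <= start < end")
  }
  data.frame(start = start, end = end, text = text, stringsAsFactors = FALSE)
}

#' Build spans from offsets into a text
#'
#' @param text The full text the offsets index into.
#' @param start,end 0-based half-open offsets.
#' @return A span set whose `text` column is sliced from `text`.
#' @export
spans_from_offsets <- function(text, start, end) {
  span_set(start, end, substring(text, start + 1L, end))
}

# Coerce arbitrary parsed input (e.g. from JSONL) to a canonical span set.
as_span_set <- function(x) {
  if (is.null(x) || (is.list(x) && length(x) == 0L) ||
      (is.data.frame(x) && nrow(x) == 0L)) {
    return(span_set())
  }
  if (is.data.frame(x)) {
    return(span_set(x$start, x$end, x$text))
  }
  if (is.list(x) && is.list(x[[1]])) {  # parsed JSON: list of {start,end,text}
    return(span_set(vapply(x, `[[`, 0, "start"),
                    vapply(x, `[[`, 0, "end"),
                    vapply(x, function(s) as.character(s$text), "")))
  }
  stop("cannot interpret span set")
}

# TRUE where span [s1,e1) overlaps [s2,e2) (0-based half-open).
spans_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
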