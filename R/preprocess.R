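# Passage isolation under institution dialect rules, and the rule-based
# sentence splitter used by the kernel/context decomposition.

#' Institution dialect rules for passage isolation
#'
#' Penn-style notes locate the epilepsy history by section header
#' ("History of Present Illness", "Interval History"); Michigan-style notes by
#' keyword phrases marking the beginning of the epilepsy history
#' ("the patient was last seen", "interval history", "interval events",
#' "hpi", "history of present illness"). In both dialects the passage is
#' truncated to `char_limit` characters (default 1506, the transformer input
#' budget), and when nothing matches the first `char_limit` characters of the
#' document are used.
#'
#' @param name `"penn"` or `"michigan"`.
#' @param header_names Section headers (penn), matched line-anchored,
#'   case-insensitively, with an optional trailing colon.
#' @param keyword_phrases Trigger phrases (michigan), matched
#'   case-insensitively with interior whitespace runs collapsed.
#' @param char_limit Positive integer character budget.
#' @return A list of class `dialect_rules`.
#' @export
dialect_rules <- function(name = c("penn", "michigan"),
                          header_names = c("History of Present Illness",
                                           "Interval History"),
                          keyword_phrases = c("the patient was last seen",
                                              "interval history",
                                              "interval events",
                                              "hpi",
                                              "history of present illness"),
                          char_limit = 1506L) {
  name <- match.arg(name)
  if (char_limit <= 0) stop("char_limit must be positive")
  if (name == "penn" && !length(header_names)) stop("penn rules need header_names")
  if (name == "michigan" && !length(keyword_phrases)) stop("michigan rules need keyword_phrases")
  structure(list(name = name, header_names = header_names,
                 keyword_phrases = keyword_phrases,
                 char_limit = as.integer(char_limit)),
            class = "dialect_rules")
}

#' Isolate the epilepsy-history passage from a raw note
#'
#' Under penn rules the passage begins immediately after the first line that
#' matches a section header (case-insensitive, optional trailing colon) and
#' runs — through any later section — up to the character budget. Under
#' michigan rules it begins at the first character of the first sentence
#' containing a keyword phrase (earliest match position wins). If nothing
#' matches, the first `char_limit` characters are taken (`fallback_head`).
#'
#' @param raw_text Non-empty note text.
#' @param rules A [dialect_rules()].
#' @param note_id Optional id carried through to the result.
#' @return A list (`passage`) with `note_id`, `text` (at most `char_limit`
#'   characters), `origin` (`header_match`, `keyword_match` or
#'   `fallback_head`) and `start_offset` (0-based offset into `raw_text`).
#' @export
isolate_passage <- function(raw_text, rules, note_id = NULL) {
  if (!inherits(rules, "dialect_rules")) stop("rules must be dialect_rules")
  if (!is.character(raw_text) || length(raw_text) != 1L || !nzchar(raw_text)) {
    stop("raw_text must be a non-empty string")
  }
  start <- NULL
  origin <- "fallback_head"
  if (rules$name == "penn") {
    hit <- .find_header(raw_text, rules$header_names)
    if (!is.null(hit)) {
      start <- hit
      origin <- "header_match"
    }
  } else {
    hit <- .find_keyword_sentence(raw_text, rules$keyword_phrases)
    if (!is.null(hit)) {
      start <- hit
      origin <- "keyword_match"
    }
  }
  if (is.null(start)) start <- 0L
  text <- substring(raw_text, start + 1L, start + rules$char_limit)
  list(note_id = note_id, text = text, origin = origin,
       start_offset = as.integer(start))
}

# 0-based offset of the first character after the first matching header line,
# or NULL. A line matches when, after trimming, it equals a header with an
# optional trailing colon, case-insensitively.
.find_header <- function(raw_text, headers) {
  lines <- strsplit(raw_text, "\n", fixed = TRUE)[[1]]
  offs <- cumsum(c(0L, nchar(lines) + 1L))  # 0-based start of each line
  want <- tolower(headers)
  for (k in seq_along(lines)) {
    trimmed <- tolower(trimws(lines[k]))
    trimmed <- sub(":$", "", trimmed)
    if (trimmed %in% want) {
      after <- offs[k] + nchar(lines[k]) + 1L  # skip the newline
      return(min(after, nchar(raw_text)))
    }
  }
  NULL
}

# 0-based offset of the start of the first sentence containing any keyword
# phrase (earliest match position across phrases wins), or NULL.
.find_keyword_sentence <- function(raw_text, phrases) {
  best <- Inf
  for (ph in phrases) {
    words <- strsplit(trimws(ph), "[ \t]+")[[1]]
    pat <- paste0("(?i)(?<![A-Za-z])",
                  paste(vapply(words, .rx_escape, ""), collapse = "\\s+"),
                  "(?![A-Za-z])")
    m <- regexpr(pat, raw_text, perl = TRUE)
    if (m[1] != -1L) best <- min(best, m[1])
  }
  if (!is.finite(best)) return(NULL)
  sents <- split_sentences(raw_text)
  pos0 <- best - 1L  # 0-based position of the match
  row <- which(sents$start <= pos0 & pos0 < sents$end)
  if (!length(row)) return(NULL)
  sents$start[row[1]]
}

.rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

.abbreviations <- c("dr.", "mr.", "mrs.", "q.d.", "b.i.d.", "vs.", "approx.")

#' Split text into sentences with character offsets
#'
#' Rule-based splitter: a sentence ends at a run of terminal punctuation
#' (`.!?`) followed by whitespace and an uppercase letter or digit, unless the
#' token ending in the punctuation is on the clinical abbreviation stoplist
#' (Dr., Mr., Mrs., q.d., b.i.d., vs., approx.). Deterministic and
#' dependency-free so downstream tests can be exact.
#'
#' @param text A string (possibly empty).
#' @return Data frame with one row per sentence: `start`, `end` (0-based
#'   half-open offsets into `text`, trimmed of surrounding whitespace) and
#'   `text`. Empty/whitespace-only input yields zero rows.
#' @export
split_sentences <- function(text) {
  empty <- data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(empty)

  m <- gregexpr("[.!?]+(?=[ \t\r\n]+[\"'(]?[A-Z0-9])", text, perl = TRUE)[[1]]
  breaks <- integer(0)
  if (m[1] != -1L) {
    after <- as.integer(m) + attr(m, "match.length")  # 1-based pos after punct
    keep <- vapply(seq_along(after), function(k) {
      upto <- substring(text, 1L, after[k] - 1L)
      tok <- sub(".*[ \t\r\n]", "", upto)
      !(tolower(tok) %in% .abbreviations)
    }, TRUE)
    breaks <- after[keep]
  }

  seg_start <- c(1L, breaks)                      # 1-based, inclusive
  seg_end <- c(breaks - 1L, nchar(text))          # 1-based, inclusive
  rows <- lapply(seq_along(seg_start), function(k) {
    seg <- substring(text, seg_start[k], seg_end[k])
    nw <- gregexpr("[^ \t\r\n]", seg)[[1]]
    if (nw[1] == -1L) return(NULL)
    first <- nw[1]
    last <- nw[length(nw)]
    s0 <- seg_start[k] + first - 2L               # 0-based
    e0 <- seg_start[k] + last - 1L                # 0-based half-open
    data.frame(start = s0, end = e0,
               text = substring(text, s0 + 1L, e0),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
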