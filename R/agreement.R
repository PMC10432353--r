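# Majority-vote merging of triplicate annotations and the agreement metrics:
# Cohen's kappa, token-overlap span F1 (single pair, paired set, overall set)
# and best-match percent agreement.

#' Merge triplicate annotations into a gold record
#'
#' The merged label is any value held by at least 2 of the 3 annotators; a
#' 3-way split is flagged for adjudication and recorded as `unclassifiable`
#' (a placeholder, never auto-resolved). Spans are merged at the character
#' level: a character belongs to the merged span set iff at least 2 annotators
#' covered it, and maximal runs of covered characters become merged spans.
#' Tasks where some annotator marked a span but the merge is empty are also
#' flagged.
#'
#' @param annotations List of exactly 3 annotation records (`label` plus span
#'   sets) over the same note.
#' @param text The note text the span offsets index into.
#' @param note_id Optional id (checked against the records when they carry
#'   one).
#' @return A gold record: `note_id`, `label`, `frequency_spans`,
#'   `last_seizure_spans`, `evidence_spans`, `adjudication_flags`.
#' @export
merge_annotations <- function(annotations, text, note_id = NULL) {
  if (length(annotations) != 3L) stop("exactly 3 annotation records required")
  ids <- unlist(lapply(annotations, function(a) a$note_id))
  if (length(unique(c(ids, note_id))) > 1L) {
    stop("annotation records reference different notes")
  }
  flags <- character(0)
  labels <- vapply(annotations, function(a) a$label, "")
  tab <- sort(table(labels), decreasing = TRUE)
  if (tab[1] >= 2L) {
    label <- names(tab)[1]
  } else {
    label <- "unclassifiable"
    flags <- c(flags, "label_no_majority")
  }
  gold <- list(note_id = note_id, label = label)
  nch <- nchar(text)
  for (task in .span_tasks) {
    votes <- integer(nch)
    n_marked <- 0L
    for (a in annotations) {
      sp <- a[[task]]
      if (is.null(sp)) sp <- span_set()
      n_marked <- n_marked + nrow(sp)
      for (r in seq_len(nrow(sp))) {
        lo <- max(1L, sp$start[r] + 1L)
        hi <- min(nch, sp$end[r])
        if (lo <= hi) votes[lo:hi] <- votes[lo:hi] + 1L
      }
    }
    runs <- rle(votes >= 2L)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    hit <- which(runs$values)
    gold[[task]] <- if (length(hit)) {
      spans_from_offsets(text, starts[hit] - 1L, ends[hit])
    } else {
      span_set()
    }
    if (n_marked > 0L && nrow(gold[[task]]) == 0L) {
      flags <- c(flags, paste0(task, "_merge_empty"))
    }
  }
  gold$adjudication_flags <- flags
  gold
}

#' Cohen's kappa for two label sequences
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed agreement and `p_e` the chance agreement from each rater's own
#' marginal label frequencies. Returns 1 when both raters agree everywhere,
#' including the degenerate single-category case.
#'
#' @param a,b Equal-length, non-empty label vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' cohens_kappa(c("x", "x", "y", "y"), c("y", "y", "x", "x"))  # -1
cohens_kappa <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b) || !length(a)) {
    stop("a and b must have equal, non-zero length")
  }
  n <- length(a)
  lev <- unique(c(a, b))
  po <- mean(a == b)
  pa <- table(factor(a, lev)) / n
  pb <- table(factor(b, lev)) / n
  pe <- sum(pa * pb)
  if (1 - pe < 1e-12) return(1)  # pe = 1 forces both raters constant & equal
  (po - pe) / (1 - pe)
}

# Reading-comprehension style normalization: lowercase, strip punctuation,
# whitespace-tokenize.
.tokens <- function(x) {
  x <- gsub("[[:punct:]]+", " ", tolower(x))
  toks <- strsplit(trimws(x), "[ \t\r\n]+")[[1]]
  toks[nzchar(toks)]
}

#' Token-overlap F1 between two span texts
#'
#' Both texts are normalized (lowercase, punctuation stripped,
#' whitespace-tokenized); precision is the shared-token multiset size over the
#' predicted token count, recall over the gold token count. Two empty texts
#' score (1, 1, 1); exactly one empty scores (0, 0, 0).
#'
#' @param gold_text,pred_text Strings (possibly empty).
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
span_f1 <- function(gold_text, pred_text) {
  g <- .tokens(gold_text)
  p <- .tokens(pred_text)
  if (!length(g) && !length(p)) {
    return(c(precision = 1, recall = 1, f1 = 1))
  }
  if (!length(g) || !length(p)) {
    return(c(precision = 0, recall = 0, f1 = 0))
  }
  tg <- table(g)
  tp <- table(p)
  common_lv <- intersect(names(tg), names(tp))
  shared <- sum(pmin(tg[common_lv], tp[common_lv]))
  prec <- shared / length(p)
  rec <- shared / length(g)
  f1 <- if (shared == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

# Greedy 1:1 matching of two span sets by descending pairwise token F1;
# zero-overlap pairs are never matched. Ties break by earliest gold start,
# then earliest pred start. Returns list(f1 = matched pair F1s,
# n_unmatched = count of spans left unmatched on either side).
.match_spans <- function(gold_spans, pred_spans) {
  ng <- nrow(gold_spans)
  np <- nrow(pred_spans)
  if (!ng || !np) return(list(f1 = numeric(0), n_unmatched = ng + np))
  pairs <- expand.grid(g = seq_len(ng), p = seq_len(np))
  pairs$f1 <- mapply(function(g, p) {
    unname(span_f1(gold_spans$text[g], pred_spans$text[p])["f1"])
  }, pairs$g, pairs$p)
  pairs <- pairs[pairs$f1 > 0, , drop = FALSE]
  pairs <- pairs[order(-pairs$f1, gold_spans$start[pairs$g],
                       pred_spans$start[pairs$p]), , drop = FALSE]
  used_g <- logical(ng)
  used_p <- logical(np)
  f1s <- numeric(0)
  for (r in seq_len(nrow(pairs))) {
    g <- pairs$g[r]
    p <- pairs$p[r]
    if (!used_g[g] && !used_p[p]) {
      used_g[g] <- TRUE
      used_p[p] <- TRUE
      f1s <- c(f1s, pairs$f1[r])
    }
  }
  list(f1 = f1s, n_unmatched = sum(!used_g) + sum(!used_p))
}

#' Span-set F1 between two sets of spans
#'
#' Spans are greedily matched 1:1 by descending pairwise token F1 (pairs with
#' no token overlap are never matched). `paired` mode is the mean F1 over
#' matched pairs — overlap where both sides marked some text; `overall` mode
#' additionally scores one 0 for every unmatched span on either side,
#' penalizing spans marked by only one side. Two empty sets score 1 in both
#' modes (mutual recognition of absence). `paired` is `NA` when exactly one
#' side is empty or no pair overlaps (undefined; callers record a flag).
#'
#' @param gold_spans,pred_spans Span sets ([span_set()]).
#' @param mode `"paired"` or `"overall"`.
#' @return A single F1 value (or `NA` for undefined paired cases).
#' @export
set_f1 <- function(gold_spans, pred_spans, mode = c("paired", "overall")) {
  mode <- match.arg(mode)
  ng <- nrow(gold_spans)
  np <- nrow(pred_spans)
  if (!ng && !np) return(1)
  if (mode == "paired" && (!ng || !np)) return(NA_real_)
  m <- .match_spans(gold_spans, pred_spans)
  if (mode == "paired") {
    if (!length(m$f1)) return(NA_real_)
    return(mean(m$f1))
  }
  sum(m$f1) / (length(m$f1) + m$n_unmatched)
}

#' Percent agreement between predictions and gold records
#'
#' For the classification task a prediction agrees iff the labels are equal.
#' For an extraction task it agrees iff gold and prediction are both empty
#' (mutual no-answer), or the best token F1 of any predicted span against any
#' gold span reaches `match_threshold` — when multiple correct answers exist
#' the most-well-matched one is used.
#'
#' @param predictions List of prediction records (one per note).
#' @param gold List of gold records.
#' @param task `"classification"`, `"frequency"` or `"last_seizure"`.
#' @param match_threshold Minimum best-match F1 counting as correct capture.
#' @return Fraction of notes in agreement.
#' @export
percent_agreement <- function(predictions, gold,
                              task = c("classification", "frequency",
                                       "last_seizure"),
                              match_threshold = 0.5) {
  task <- match.arg(task)
  gid <- vapply(gold, `[[`, "", "note_id")
  pid <- vapply(predictions, `[[`, "", "note_id")
  m <- match(gid, pid)
  if (anyNA(m)) {
    stop("missing prediction for note(s): ",
         paste(head(gid[is.na(m)], 3L), collapse = ", "))
  }
  agree <- vapply(seq_along(gold), function(i) {
    g <- gold[[i]]
    p <- predictions[[m[i]]]
    if (task == "classification") return(identical(g$label, p$label))
    field <- paste0(task, "_spans")
    .extraction_agrees(g[[field]], p[[field]], match_threshold)
  }, TRUE)
  mean(agree)
}

.best_f1 <- function(gold_spans, pred_spans) {
  if (!nrow(gold_spans) || !nrow(pred_spans)) return(0)
  max(vapply(seq_len(nrow(pred_spans)), function(p) {
    max(vapply(seq_len(nrow(gold_spans)), function(g) {
      unname(span_f1(gold_spans$text[g], pred_spans$text[p])["f1"])
    }, 0))
  }, 0))
}

.extraction_agrees <- function(gold_spans, pred_spans, threshold) {
  if (!nrow(gold_spans) && !nrow(pred_spans)) return(TRUE)
  if (!nrow(gold_spans) || !nrow(pred_spans)) return(FALSE)
  .best_f1(gold_spans, pred_spans) >= threshold
}

#' Inter-annotator agreement over an annotated corpus
#'
#' Computes, over the three annotator pairs (1,2), (1,3), (2,3): Cohen's kappa
#' of the class labels, and per-task mean paired and overall span F1
#' (per-note averaging; undefined paired cases are skipped and counted).
#'
#' @param corpus A corpus with `annotations` (see [annotate_corpus()]).
#' @param tasks Span tasks to score.
#' @return A list with `kappa` (mean over pairs), `per_pair` kappas, and per
#'   task `paired_f1`, `overall_f1` and `n_paired_undefined`.
#' @export
interrater_agreement <- function(corpus,
                                 tasks = c("frequency_spans",
                                           "last_seizure_spans")) {
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  kap <- vapply(pairs, function(pr) {
    a <- vapply(corpus, function(n) n$annotations[[pr[1]]]$label, "")
    b <- vapply(corpus, function(n) n$annotations[[pr[2]]]$label, "")
    cohens_kappa(a, b)
  }, 0)
  out <- list(kappa = mean(kap), per_pair_kappa = kap)
  for (task in tasks) {
    paired <- c()
    overall <- c()
    undef <- 0L
    for (pr in pairs) {
      for (n in corpus) {
        g <- n$annotations[[pr[1]]][[task]]
        p <- n$annotations[[pr[2]]][[task]]
        pf <- set_f1(g, p, "paired")
        if (is.na(pf)) undef <- undef + 1L else paired <- c(paired, pf)
        overall <- c(overall, set_f1(g, p, "overall"))
      }
    }
    out[[task]] <- list(paired_f1 = mean(paired), overall_f1 = mean(overall),
                        n_paired_undefined = undef)
  }
  out
}
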