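# Correctness stratification, two-sided Mann-Whitney U comparisons, and Q-Q
# tables of each test set against the within-training reference distribution.

#' Label per-note correctness of predictions against gold
#'
#' Classification is correct iff the predicted label equals the gold label.
#' Extraction succeeds iff, for every task where gold or prediction has spans,
#' the best token-overlap F1 reaches `threshold` (inclusive, default 0.50);
#' a task where both sides are empty is a vacuous success (mutual no-answer).
#' Notes where every task is vacuous are flagged.
#'
#' @param predictions,gold Aligned lists of records (matched by `note_id`).
#' @param threshold Extraction success threshold on best F1.
#' @return Data frame: `note_id`, `classification_correct`, per-task best F1
#'   (`NA` when vacuous), `extraction_success`, `extraction_vacuous`.
#' @export
label_correctness <- function(predictions, gold, threshold = 0.5) {
  gid <- vapply(gold, `[[`, "", "note_id")
  pid <- vapply(predictions, `[[`, "", "note_id")
  m <- match(gid, pid)
  if (anyNA(m)) {
    stop("missing prediction for note(s): ",
         paste(head(gid[is.na(m)], 3L), collapse = ", "))
  }
  rows <- lapply(seq_along(gold), function(i) {
    g <- gold[[i]]
    p <- predictions[[m[i]]]
    best <- vapply(c("frequency_spans", "last_seizure_spans"), function(task) {
      gs <- g[[task]]
      ps <- p[[task]]
      if (!nrow(gs) && !nrow(ps)) return(NA_real_)  # vacuous
      if (!nrow(gs) || !nrow(ps)) return(0)
      .best_f1(gs, ps)
    }, 0)
    vac <- all(is.na(best))
    success <- if (vac) TRUE else all(best[!is.na(best)] >= threshold)
    data.frame(note_id = g$note_id,
               classification_correct = identical(g$label, p$label),
               frequency_best_f1 = best[[1]],
               last_seizure_best_f1 = best[[2]],
               extraction_success = success,
               extraction_vacuous = vac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed by rank sums with midranks for ties. The p-value uses exact
#' enumeration of the null distribution when there are no ties and
#' `n_x * n_y <= 400`, and otherwise a normal approximation with tie-corrected
#' variance and continuity correction. When every pooled value is identical,
#' `U = n_x * n_y / 2` and `p = 1`.
#'
#' @param x,y Non-empty numeric samples.
#' @param method `"auto"` (default rule above), `"exact"` or
#'   `"normal_approx"`.
#' @return List with `U` (for the first sample), `p` (two-sided), `method`,
#'   `n_x`, `n_y`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal_approx")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (method == "auto") {
    method <- if (!ties && nx * ny <= 400) "exact" else "normal_approx"
  }
  if (method == "exact" && ties) {
    method <- "normal_approx"  # exact null distribution assumes no ties
  }
  if (method == "exact") {
    p <- 2 * min(pwilcox(U, nx, ny), 1 - pwilcox(U - 1, nx, ny))
    p <- min(1, p)
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    sig2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sig2)
      z <- max(z, 0)
      p <- min(1, 2 * pnorm(-z))
    }
  }
  list(U = U, p = p, method = method, n_x = nx, n_y = ny)
}

#' Correctness-stratified comparison of similarity measures
#'
#' For each similarity measure, splits the per-note mean similarities by a
#' correctness outcome and runs a two-sided Mann-Whitney U test of the
#' hypothesis that the correct and incorrect strata come from one
#' distribution. Notes with a missing measure (empty kernel or context) are
#' excluded per measure; an empty stratum marks that comparison
#' not-computable rather than raising.
#'
#' @param profiles Similarity profile data frame
#'   (see [profile_against_training()]).
#' @param correctness Data frame from [label_correctness()].
#' @param outcome Column of `correctness` to stratify on
#'   (`"classification_correct"` or `"extraction_success"`).
#' @param measures Measures to compare.
#' @return Data frame: `measure`, `n_correct`, `n_incorrect`, `U`, `p`,
#'   `median_correct`, `median_incorrect`, `computable`.
#' @export
stratified_comparison <- function(profiles, correctness,
                                  outcome = "classification_correct",
                                  measures = c("lev_kernel", "lev_context",
                                               "cos_kernel", "cos_context")) {
  m <- match(profiles$note_id, correctness$note_id)
  if (anyNA(m)) stop("profiles and correctness labels are misaligned")
  ok <- correctness[[outcome]][m]
  rows <- lapply(measures, function(ms) {
    v <- profiles[[ms]]
    keep <- !is.na(v)
    xc <- v[keep & ok]
    xi <- v[keep & !ok]
    if (!length(xc) || !length(xi)) {
      return(data.frame(measure = ms, n_correct = length(xc),
                        n_incorrect = length(xi), U = NA_real_, p = NA_real_,
                        median_correct = if (length(xc)) median(xc) else NA_real_,
                        median_incorrect = if (length(xi)) median(xi) else NA_real_,
                        computable = FALSE, stringsAsFactors = FALSE))
    }
    mw <- mann_whitney_u(xc, xi)
    data.frame(measure = ms, n_correct = length(xc), n_incorrect = length(xi),
               U = mw$U, p = mw$p, median_correct = median(xc),
               median_incorrect = median(xi), computable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Q-Q table of a sample against a reference distribution
#'
#' Linear-interpolation quantiles (type 7) of both inputs on a common
#' probability grid, for Q-Q comparison of a test set's similarity
#' distribution against the within-training reference. Following the source
#' analyses, no test or p-value accompanies these distribution comparisons
#' (p-values become arbitrarily small at pairwise-comparison sample sizes).
#'
#' @param sample,reference Non-empty numeric vectors.
#' @param probs Probability grid in (0, 1); default the 99 percentiles.
#' @return List with `table` (data frame `prob`, `sample_q`, `reference_q`),
#'   `sample_median`, `reference_median`.
#' @export
qq_table <- function(sample, reference, probs = seq(0.01, 0.99, by = 0.01)) {
  if (!length(sample) || !length(reference)) stop("inputs must be non-empty")
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie in (0,1)")
  data <- data.frame(
    prob = probs,
    sample_q = quantile(sample, probs, type = 7, names = FALSE),
    reference_q = quantile(reference, probs, type = 7, names = FALSE))
  list(table = data,
       sample_median = median(sample),
       reference_median = median(reference))
}
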