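make_ann <- function(label, freq = span_set(), last = span_set(),
                     ev = span_set()) {
  list(label = label, frequency_spans = freq, last_seizure_spans = last,
       evidence_spans = ev)
}

test_that("majority-vote merging recovers unanimity and forced majorities", {
  text <- strrep("abcde", 10)
  a <- make_ann("seizure_free", freq = spans_from_offsets(text, 3L, 12L))
  gold <- merge_annotations(list(a, a, a), text, note_id = "n1")
  expect_identical(gold$label, "seizure_free")
  expect_equal(gold$frequency_spans, a$frequency_spans, ignore_attr = TRUE)
  expect_length(gold$adjudication_flags, 0)

  b <- make_ann("having_seizures")
  gold2 <- merge_annotations(list(a, a, b), text)
  expect_identical(gold2$label, "seizure_free")

  # 3-way label split is flagged for adjudication
  c3 <- make_ann("unclassifiable")
  gold3 <- merge_annotations(list(a, b, c3), text)
  expect_true("label_no_majority" %in% gold3$adjudication_flags)
  expect_identical(gold3$label, "unclassifiable")

  expect_error(
    merge_annotations(list(c(a, note_id = "x"), c(a, note_id = "y"),
                           c(a, note_id = "x")), text),
    "different notes")
})

test_that("spans merge by character-level 2-of-3 vote into maximal runs", {
  text <- strrep("z", 30)
  a1 <- make_ann("seizure_free", freq = spans_from_offsets(text, 0L, 10L))
  a2 <- make_ann("seizure_free", freq = spans_from_offsets(text, 0L, 10L))
  a3 <- make_ann("seizure_free", freq = spans_from_offsets(text, 5L, 15L))
  gold <- merge_annotations(list(a1, a2, a3), text)
  # chars 0-4 get 2 votes, 5-9 get 3, 10-14 get 1 -> merged span [0, 10)
  expect_equal(gold$frequency_spans$start, 0L)
  expect_equal(gold$frequency_spans$end, 10L)

  # merge is invariant to annotator permutation
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(merge_annotations(list(a1, a2, a3)[perm], text), gold,
                 ignore_attr = TRUE)
  }

  # single-annotator span disappears and is flagged
  a4 <- make_ann("seizure_free", last = spans_from_offsets(text, 20L, 25L))
  gold2 <- merge_annotations(list(a4, make_ann("seizure_free"),
                                  make_ann("seizure_free")), text)
  expect_identical(nrow(gold2$last_seizure_spans), 0L)
  expect_true("last_seizure_spans_merge_empty" %in% gold2$adjudication_flags)
})

test_that("Cohen's kappa matches hand-computed and chance-level values", {
  expect_identical(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  expect_identical(cohens_kappa(rep("a", 5), rep("a", 5)), 1)
  # balanced complete disagreement: p_o = 0, p_e = 0.5
  expect_equal(cohens_kappa(c("F", "F", "S", "S"), c("S", "S", "F", "F")), -1)

  set.seed(101)
  a <- sample(c("x", "y", "z"), 10000, replace = TRUE)
  b <- sample(c("x", "y", "z"), 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(a, b)), 0.03)

  # symmetric and invariant to category relabeling
  set.seed(102)
  a <- sample(c("x", "y", "z"), 200, replace = TRUE)
  b <- sample(c("x", "y", "z"), 200, replace = TRUE)
  expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))
  relab <- c(x = "q", y = "r", z = "s")
  expect_equal(cohens_kappa(relab[a], relab[b]), cohens_kappa(a, b))

  expect_error(cohens_kappa(c("a"), c("a", "b")), "equal")
  expect_error(cohens_kappa(character(), character()), "non-zero")
})

test_that("token-overlap F1 matches hand counts and its conventions", {
  expect_equal(span_f1("3 seizures in May", "3 seizures in May")[["f1"]], 1)
  r <- span_f1("3 seizures in the last 6 months",
               "seizures in the last 6 months")
  expect_equal(r[["precision"]], 1)
  expect_equal(r[["recall"]], 6 / 7)
  expect_equal(r[["f1"]], 12 / 13)
  expect_equal(span_f1("alpha beta", "gamma delta")[["f1"]], 0)
  expect_equal(span_f1("", ""), c(precision = 1, recall = 1, f1 = 1))
  expect_equal(span_f1("words here", "")[["f1"]], 0)
  # normalization: case and punctuation are ignored
  expect_equal(span_f1("Last seizure: March, 2017.", "last seizure march 2017")[["f1"]], 1)
  # symmetry: P and R swap, F1 invariant
  a <- "three seizures last month"
  b <- "seizures last week"
  expect_equal(span_f1(a, b)[["f1"]], span_f1(b, a)[["f1"]])
  expect_equal(span_f1(a, b)[["precision"]], span_f1(b, a)[["recall"]])
})

test_that("set-level paired and overall F1 follow the declared conventions", {
  x <- span_set(0, 9, "3 attacks")
  y <- span_set(20, 32, "nothing else")
  expect_equal(set_f1(x, x, "paired"), 1)
  expect_equal(set_f1(x, x, "overall"), 1)
  expect_equal(set_f1(x, rbind(x, y), "paired"), 1)
  expect_equal(set_f1(x, rbind(x, y), "overall"), 0.5)
  expect_equal(set_f1(span_set(), span_set(), "paired"), 1)
  expect_equal(set_f1(span_set(), span_set(), "overall"), 1)
  expect_true(is.na(set_f1(x, span_set(), "paired")))
  expect_equal(set_f1(x, span_set(), "overall"), 0)
})

test_that("overall F1 never exceeds paired F1, strictly so with unmatched spans", {
  set.seed(301)
  n_strict_checked <- 0
  for (rep in 1:300) {
    gold <- random_span_set(sample(1:3, 1))
    pred <- random_span_set(sample(1:3, 1))
    paired <- set_f1(gold, pred, "paired")
    overall <- set_f1(gold, pred, "overall")
    if (is.na(paired)) next
    expect_lte(overall, paired)
    if (nrow(gold) + nrow(pred) > 2 * min(nrow(gold), nrow(pred)) &&
        paired > 0) {
      # at least one span must be unmatched
      expect_lt(overall, paired)
      n_strict_checked <- n_strict_checked + 1
    }
  }
  expect_gt(n_strict_checked, 20)
})

test_that("percent agreement uses the best-matched gold answer and mutual absence", {
  gold <- list(
    list(note_id = "a", label = "seizure_free",
         frequency_spans = span_set(c(0, 40), c(20, 70),
                                    c("4 seizures per month",
                                      "two events in the last year")),
         last_seizure_spans = span_set()),
    list(note_id = "b", label = "having_seizures",
         frequency_spans = span_set(), last_seizure_spans = span_set())
  )
  preds <- list(
    list(note_id = "a", label = "seizure_free",
         frequency_spans = span_set(45, 70, "events in the last year"),
         last_seizure_spans = span_set()),
    list(note_id = "b", label = "having_seizures",
         frequency_spans = span_set(), last_seizure_spans = span_set())
  )
  expect_equal(percent_agreement(preds, gold, "classification"), 1)
  # note a matches its second (best-matched) gold span; note b mutual absence
  expect_equal(percent_agreement(preds, gold, "frequency"), 1)
  expect_equal(percent_agreement(preds, gold, "last_seizure"), 1)

  # invariant to gold span enumeration order
  gold_rev <- gold
  gold_rev[[1]]$frequency_spans <- gold[[1]]$frequency_spans[2:1, ]
  expect_equal(percent_agreement(preds, gold_rev, "frequency"), 1)

  # non-answer against an existing answer is a miss
  preds2 <- preds
  preds2[[1]]$frequency_spans <- span_set()
  expect_equal(percent_agreement(preds2, gold, "frequency"), 0.5)

  expect_error(percent_agreement(preds[1], gold, "classification"),
               "missing prediction")
})
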