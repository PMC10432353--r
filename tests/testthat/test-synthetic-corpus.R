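test_that("generator handles the empty case and rejects invalid profiles", {
  expect_length(generate_corpus(tiny_profile(), 0, seed = 1), 0)
  expect_error(specialty_profile("epileptologist", c(0.5, 0.5, 0.5), 0.3, 0.5),
               "sum")
  expect_error(specialty_profile("epileptologist", c(0.3, 0.6, 0.1), 1.3, 0.5),
               "\\[0,1\\]")
  expect_error(generate_corpus(list(), 3, seed = 1), "specialty_profile")
})

test_that("generation is a pure function of (profile, n, seed)", {
  a <- generate_corpus(tiny_profile(), 25, seed = 11)
  b <- generate_corpus(tiny_profile(), 25, seed = 11)
  expect_identical(a, b)
  c <- generate_corpus(tiny_profile(), 25, seed = 12)
  expect_false(identical(a, c))
  ids <- vapply(a, `[[`, "", "note_id")
  expect_false(anyDuplicated(ids) > 0)
})

test_that("truth spans index raw_text correctly and notes carry dialect structure", {
  profs <- default_profiles()
  for (nm in c("epileptologist", "michigan_epileptologist")) {
    corpus <- generate_corpus(profs[[nm]], 40, seed = 3)
    for (note in corpus) {
      expect_gt(nchar(note$raw_text), 0)
      for (task in c("frequency_spans", "last_seizure_spans",
                     "evidence_spans")) {
        sp <- note$truth[[task]]
        if (nrow(sp)) {
          expect_identical(substring(note$raw_text, sp$start + 1, sp$end),
                           sp$text)
        }
      }
    }
  }
  penn <- generate_corpus(profs$epileptologist, 40, seed = 3)
  has_header <- vapply(penn, function(n) {
    grepl("history of present illness|interval history", tolower(n$raw_text))
  }, TRUE)
  expect_true(all(has_header))
  # history section always sits after at least one non-history section
  first_header_at <- vapply(penn, function(n) {
    regexpr("(?i)history", n$raw_text, perl = TRUE)[1]
  }, 0L)
  expect_true(all(first_header_at > 1))
})

test_that("context regeneration leaves truth and kernel sentences byte-identical", {
  a <- generate_corpus(tiny_profile(), 30, seed = 5, context_seed = 5)
  b <- generate_corpus(tiny_profile(), 30, seed = 5, context_seed = 99)
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$truth$label, b[[i]]$truth$label)
    for (task in c("frequency_spans", "last_seizure_spans", "evidence_spans")) {
      expect_identical(a[[i]]$truth[[task]]$text, b[[i]]$truth[[task]]$text)
    }
  }
  expect_false(identical(vapply(a, `[[`, "", "raw_text"),
                         vapply(b, `[[`, "", "raw_text")))
})

test_that("zero annotator noise reproduces the truth exactly", {
  corpus <- generate_corpus(tiny_profile(), 20, seed = 2)
  noise0 <- annotator_noise(0, 0, 0)
  for (note in corpus) {
    anns <- simulate_annotators(note, noise0, seed = 99)
    for (a in anns) {
      expect_identical(a$label, note$truth$label)
      for (task in c("frequency_spans", "last_seizure_spans",
                     "evidence_spans")) {
        expect_equal(a[[task]], note$truth[[task]], ignore_attr = TRUE)
      }
    }
  }
})

test_that("boundary jitter keeps annotated endpoints within the jitter radius", {
  corpus <- generate_corpus(tiny_profile(), 30, seed = 8)
  j <- 4L
  noise <- annotator_noise(p_label_flip = 0, p_span_miss = 0,
                           boundary_jitter_max = j)
  for (note in corpus) {
    anns <- simulate_annotators(note, noise, seed = 123)
    for (a in anns) {
      for (task in c("frequency_spans", "last_seizure_spans",
                     "evidence_spans")) {
        truth <- note$truth[[task]]
        got <- a[[task]]
        expect_identical(nrow(got), nrow(truth))
        if (nrow(truth)) {
          expect_true(all(abs(got$start - truth$start) <= j))
          expect_true(all(abs(got$end - truth$end) <= j))
          expect_true(all(got$end > got$start))
        }
      }
    }
  }
})

test_that("annotator label flips reproduce the kappa of an independent Monte-Carlo oracle", {
  # 10,000 light-weight notes, flip probability 0.5, 3 categories
  set.seed(41)
  labels <- sample(c("seizure_free", "having_seizures", "unclassifiable"),
                   10000, replace = TRUE, prob = c(0.3, 0.62, 0.08))
  notes <- lapply(seq_along(labels), function(i) {
    list(note_id = paste0("n", i), raw_text = "One sentence. Another one.",
         truth = list(label = labels[i], frequency_spans = span_set(),
                      last_seizure_spans = span_set(),
                      evidence_spans = span_set()))
  })
  noise <- annotator_noise(p_label_flip = 0.5, p_span_miss = 0,
                           boundary_jitter_max = 0)
  ann <- annotate_corpus(notes, noise, seed = 7)
  a1 <- vapply(ann, function(n) n$annotations[[1]]$label, "")
  a2 <- vapply(ann, function(n) n$annotations[[2]]$label, "")
  kappa_impl <- cohens_kappa(a1, a2)

  # oracle: direct Monte-Carlo of the same flip process, separate RNG stream
  set.seed(1234)
  flip <- function(l) {
    ifelse(runif(length(l)) < 0.5,
           vapply(l, function(x) {
             sample(setdiff(c("seizure_free", "having_seizures",
                              "unclassifiable"), x), 1)
           }, ""),
           l)
  }
  kappa_oracle <- cohens_kappa(flip(labels), flip(labels))
  expect_lt(abs(kappa_impl - kappa_oracle), 0.02)
})

test_that("simulated predictions honor the null effect, the seed, and the similarity mechanism", {
  corpus <- with_sentences(generate_corpus(tiny_profile(), 1000, seed = 21))
  ids <- vapply(corpus, `[[`, "", "note_id")
  set.seed(31)
  profiles <- data.frame(note_id = ids,
                         lev_kernel = runif(1000), lev_context = runif(1000),
                         cos_kernel = runif(1000), cos_context = runif(1000))

  # null effect: correctness rate ~ logistic(base_logit)
  eff0 <- predictor_effect(base_logit = 0.4, beta_kernel = 0,
                           beta_context = 0, seed = 5)
  preds <- simulate_predictions(corpus, profiles, eff0)
  correct <- vapply(seq_along(corpus), function(i) {
    preds[[i]]$label == corpus[[i]]$truth$label
  }, TRUE)
  p0 <- stats::plogis(0.4)
  expect_lt(abs(mean(correct) - p0), 3 * sqrt(p0 * (1 - p0) / 1000))

  # determinism
  expect_identical(preds, simulate_predictions(corpus, profiles, eff0))

  # strongly positive slopes: mean similarity higher among correct notes
  eff1 <- predictor_effect(base_logit = -4, beta_kernel = 4, beta_context = 4,
                           seed = 6)
  preds1 <- simulate_predictions(corpus, profiles, eff1)
  correct1 <- vapply(seq_along(corpus), function(i) {
    preds1[[i]]$label == corpus[[i]]$truth$label
  }, TRUE)
  score <- rowMeans(profiles[, c("lev_kernel", "cos_kernel", "lev_context",
                                 "cos_context")])
  expect_gt(mean(score[correct1]), mean(score[!correct1]))

  # missing profile is an error
  expect_error(simulate_predictions(corpus, profiles[-1, ], eff0),
               "missing similarity profile")
})

test_that("incorrect extractions emit decoys or spurious no-answers, correct ones the truth", {
  corpus <- with_sentences(generate_corpus(tiny_profile(), 200, seed = 13))
  ids <- vapply(corpus, `[[`, "", "note_id")
  profiles <- data.frame(note_id = ids, lev_kernel = 0, lev_context = 0,
                         cos_kernel = 0, cos_context = 0)
  always_right <- predictor_effect(base_logit = 50, beta_kernel = 0,
                                   beta_context = 0, seed = 2)
  preds <- simulate_predictions(corpus, profiles, always_right)
  for (i in seq_along(corpus)) {
    expect_identical(preds[[i]]$label, corpus[[i]]$truth$label)
    expect_equal(preds[[i]]$frequency_spans,
                 corpus[[i]]$truth$frequency_spans, ignore_attr = TRUE)
  }
  always_wrong <- predictor_effect(base_logit = -50, beta_kernel = 0,
                                   beta_context = 0, seed = 2)
  predsw <- simulate_predictions(corpus, profiles, always_wrong)
  for (i in seq_along(corpus)) {
    expect_false(predsw[[i]]$label == corpus[[i]]$truth$label)
    truth_sp <- corpus[[i]]$truth$frequency_spans
    got <- predsw[[i]]$frequency_spans
    if (nrow(truth_sp) && nrow(got)) {
      expect_false(identical(got$text, truth_sp$text))  # decoy, not the answer
    }
    if (!nrow(truth_sp)) expect_gt(nrow(got), 0)        # spurious span
  }
})

test_that("corpora round-trip through the JSON-Lines interface", {
  corpus <- annotate_corpus(generate_corpus(tiny_profile(), 8, seed = 4),
                            annotator_noise(), seed = 9)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corpus, path)
  back <- read_corpus_jsonl(path)
  for (i in seq_along(corpus)) {
    expect_identical(back[[i]]$note_id, corpus[[i]]$note_id)
    expect_identical(back[[i]]$raw_text, corpus[[i]]$raw_text)
    expect_equal(back[[i]]$truth, corpus[[i]]$truth, ignore_attr = TRUE)
    expect_equal(back[[i]]$annotations, corpus[[i]]$annotations,
                 ignore_attr = TRUE)
  }
})
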