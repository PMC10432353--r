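# End-to-end audit orchestration: generate -> annotate/merge -> preprocess ->
# predict -> agree -> similarity -> shift, from one config, with a manifest
# for seeded reproducibility.

#' Build an audit run configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master integer seed; every stage derives its randomness from it.
#' @param n_train Number of training notes (epileptologist profile).
#' @param n_test Named integer vector of test-set sizes, names drawn from
#'   [default_profiles()].
#' @param noise An [annotator_noise()].
#' @param effect A [predictor_effect()]; its `seed` field is ignored in favor
#'   of the per-seed replication below.
#' @param n_prediction_seeds Number of predictor replicates (seeds
#'   `seed + 0 .. n-1`), mirroring multi-seed evaluation.
#' @param char_limit Passage character budget.
#' @param extraction_threshold Best-F1 threshold for extraction success.
#' @param match_threshold Best-F1 threshold for percent agreement.
#' @param alpha,alpha_specialty Significance levels reported in the manifest
#'   (per-measure tests; specialty-wise threshold).
#' @param predictions_path Optional JSONL file of externally produced
#'   predictions (one record per note); when given, the simulated predictor is
#'   skipped and a single ingested seed is evaluated.
#' @return A list of class `audit_config`.
#' @export
audit_config <- function(out_dir,
                         seed = 1L,
                         n_train = 60L,
                         n_test = c(epileptologist = 30L, neurologist = 30L,
                                    non_neurologist = 30L,
                                    michigan_epileptologist = 30L),
                         noise = annotator_noise(),
                         effect = predictor_effect(),
                         n_prediction_seeds = 5L,
                         char_limit = 1506L,
                         extraction_threshold = 0.5,
                         match_threshold = 0.5,
                         alpha = 0.05,
                         alpha_specialty = 0.0167,
                         predictions_path = NULL) {
  if (!length(n_test) || is.null(names(n_test))) {
    stop("n_test must be a named vector of test-set sizes")
  }
  bad <- setdiff(names(n_test), names(default_profiles()))
  if (length(bad)) stop("unknown test profile(s): ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_train = as.integer(n_train), n_test = n_test,
                 noise = noise, effect = effect,
                 n_prediction_seeds = as.integer(n_prediction_seeds),
                 char_limit = as.integer(char_limit),
                 extraction_threshold = extraction_threshold,
                 match_threshold = match_threshold,
                 alpha = alpha, alpha_specialty = alpha_specialty,
                 predictions_path = predictions_path),
            class = "audit_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Merge the triplicate annotations of every note into gold records
#'
#' @param corpus An annotated corpus (see [annotate_corpus()]).
#' @return A list of gold records (see [merge_annotations()]).
#' @export
merge_corpus <- function(corpus) {
  lapply(corpus, function(n) {
    merge_annotations(n$annotations, n$raw_text, note_id = n$note_id)
  })
}

#' Kernel/context splits of a corpus under dialect rules
#'
#' Isolates each note's passage, shifts the gold spans into passage
#' coordinates (clipping spans that straddle the truncation boundary and
#' dropping spans wholly outside), and splits the passage into kernel and
#' context.
#'
#' @param corpus List of notes.
#' @param gold List of gold records aligned with `corpus`; defaults to each
#'   note's latent truth.
#' @param rules A [dialect_rules()].
#' @return List with `splits` (one per note), `passages` (one per note) and
#'   `n_spans_dropped`.
#' @export
kernel_context_splits <- function(corpus, gold = NULL, rules) {
  dropped <- 0L
  passages <- vector("list", length(corpus))
  splits <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    note <- corpus[[i]]
    g <- if (is.null(gold)) note$truth else gold[[i]]
    pas <- isolate_passage(note$raw_text, rules, note_id = note$note_id)
    passages[[i]] <- pas
    len <- nchar(pas$text)
    sp <- rbind(g$frequency_spans, g$last_seizure_spans,
                if (!is.null(g$evidence_spans)) g$evidence_spans)
    s <- pmax(sp$start - pas$start_offset, 0L)
    e <- pmin(sp$end - pas$start_offset, len)
    keep <- e > s & s < len & e > 0L
    dropped <- dropped + sum(!keep)
    sp <- if (any(keep)) {
      spans_from_offsets(pas$text, s[keep], e[keep])
    } else {
      span_set()
    }
    splits[[i]] <- split_kernel_context(pas$text, sp, note_id = note$note_id)
  }
  list(splits = splits, passages = passages, n_spans_dropped = dropped)
}

#' Run the end-to-end generalization audit
#'
#' Generates train and test corpora, simulates triplicate annotation and
#' merges gold standards, isolates passages under each dialect's rules,
#' computes similarity profiles and the within-training reference
#' distribution, simulates (or ingests) predictions, and writes agreement and
#' shift reports plus a manifest with content hashes. Rerunning with the same
#' config is bit-identical under the built-in embedding provider.
#'
#' @param config An [audit_config()], or the path to a JSON file mirroring
#'   its fields.
#' @return Invisibly, a list with all in-memory stage results (`train`,
#'   `test_sets`, `gold`, `profiles`, `reference`, `agreement`,
#'   `shift_report`, `manifest`).
#' @export
run_audit <- function(config) {
  if (is.character(config)) config <- .config_from_json(config)
  if (!inherits(config, "audit_config")) stop("config must be an audit_config")
  profiles_all <- default_profiles()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  train <- .stage("generate", {
    generate_corpus(profiles_all$epileptologist, config$n_train, config$seed)
  })
  test_sets <- .stage("generate", {
    out <- list()
    for (k in seq_along(config$n_test)) {
      nm <- names(config$n_test)[k]
      out[[nm]] <- generate_corpus(profiles_all[[nm]], config$n_test[[k]],
                                   config$seed + 1000L * k)
    }
    out
  })

  gold <- .stage("merge", {
    lapply(seq_along(test_sets), function(k) {
      ann <- annotate_corpus(test_sets[[k]], config$noise,
                             config$seed + 5000L + k)
      test_sets[[k]] <<- ann
      merge_corpus(ann)
    }) |> setNames(names(test_sets))
  })

  rules <- list(penn = dialect_rules("penn", char_limit = config$char_limit),
                michigan = dialect_rules("michigan",
                                         char_limit = config$char_limit))
  split_data <- .stage("preprocess", {
    train_splits <- kernel_context_splits(train, rules = rules$penn)
    test_splits <- lapply(names(test_sets), function(nm) {
      d <- profiles_all[[nm]]$dialect
      kernel_context_splits(test_sets[[nm]], gold[[nm]], rules[[d]])
    }) |> setNames(names(test_sets))
    list(train = train_splits, test = test_splits)
  })

  sim <- .stage("similarity", {
    provider <- hashed_embedding_provider()
    train_prof <- profile_against_training(split_data$train$splits,
                                           split_data$train$splits, provider)
    per_set <- lapply(split_data$test, function(ts) {
      profile_against_training(ts$splits, split_data$train$splits, provider)
    })
    list(reference = train_prof$reference, per_set = per_set)
  })

  pred_seeds <- config$seed + seq_len(config$n_prediction_seeds) - 1L
  predictions <- .stage("predict", {
    if (!is.null(config$predictions_path)) {
      if (!file.exists(config$predictions_path)) {
        stop("predictions file not found: ", config$predictions_path)
      }
      ing <- read_records_jsonl(config$predictions_path)
      list(ingested = list(ing))
    } else {
      lapply(names(test_sets), function(nm) {
        lapply(pred_seeds, function(s) {
          eff <- config$effect
          eff$seed <- as.integer(s)
          simulate_predictions(test_sets[[nm]], sim$per_set[[nm]]$profiles, eff)
        })
      }) |> setNames(names(test_sets))
    }
  })

  agreement <- .stage("agree", {
    lapply(names(test_sets), function(nm) {
      inter <- interrater_agreement(test_sets[[nm]])
      per_seed <- lapply(predictions[[nm]], function(pred) {
        list(classification = percent_agreement(pred, gold[[nm]],
                                                "classification"),
             frequency = percent_agreement(pred, gold[[nm]], "frequency",
                                           config$match_threshold),
             last_seizure = percent_agreement(pred, gold[[nm]], "last_seizure",
                                              config$match_threshold))
      })
      means <- vapply(c("classification", "frequency", "last_seizure"),
                      function(t) mean(vapply(per_seed, `[[`, 0, t)), 0)
      list(interrater = inter, per_seed = per_seed, mean = as.list(means))
    }) |> setNames(names(test_sets))
  })

  shift_report <- .stage("shift", {
    lapply(names(test_sets), function(nm) {
      prof <- sim$per_set[[nm]]$profiles
      per_seed <- lapply(predictions[[nm]], function(pred) {
        corr <- label_correctness(pred, gold[[nm]], config$extraction_threshold)
        list(classification = stratified_comparison(prof, corr,
                                                    "classification_correct"),
             extraction = stratified_comparison(prof, corr,
                                                "extraction_success"))
      })
      qq <- lapply(c("lev_kernel", "lev_context", "cos_kernel", "cos_context"),
                   function(ms) {
        v <- prof[[ms]]
        v <- v[!is.na(v)]
        ref <- sim$reference$value[sim$reference$measure == ms]
        if (!length(v) || !length(ref)) return(NULL)
        qq_table(v, ref)
      }) |> setNames(c("lev_kernel", "lev_context", "cos_kernel",
                       "cos_context"))
      list(per_seed = per_seed, qq = qq)
    }) |> setNames(names(test_sets))
  })

  manifest <- .stage("write", {
    .write_outputs(config, train, test_sets, gold, sim, predictions,
                   agreement, shift_report)
  })

  invisible(list(train = train, test_sets = test_sets, gold = gold,
                 profiles = lapply(sim$per_set, `[[`, "profiles"),
                 reference = sim$reference, predictions = predictions,
                 agreement = agreement, shift_report = shift_report,
                 manifest = manifest))
}

.write_outputs <- function(config, train, test_sets, gold, sim, predictions,
                           agreement, shift_report) {
  od <- config$out_dir
  written <- character(0)
  on.exit({
    # remove partial outputs if any write failed
    if (!is.null(attr(written, "failed"))) unlink(written)
  })
  wfile <- function(path) {
    written <<- c(written, path)
    path
  }
  tryCatch({
    write_corpus_jsonl(train, wfile(file.path(od, "train.jsonl")))
    for (nm in names(test_sets)) {
      write_corpus_jsonl(test_sets[[nm]],
                         wfile(file.path(od, paste0("test_", nm, ".jsonl"))))
      write_records_jsonl(gold[[nm]],
                          wfile(file.path(od, paste0("gold_", nm, ".jsonl"))))
      utils::write.csv(sim$per_set[[nm]]$profiles,
                       wfile(file.path(od, paste0("profiles_", nm, ".csv"))),
                       row.names = FALSE)
      for (k in seq_along(predictions[[nm]])) {
        write_records_jsonl(
          predictions[[nm]][[k]],
          wfile(file.path(od, sprintf("pred_%s_seed%d.jsonl", nm, k))))
      }
    }
    utils::write.csv(sim$reference, wfile(file.path(od, "reference.csv")),
                     row.names = FALSE)
    jsonlite::write_json(agreement, wfile(file.path(od, "agreement.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(shift_report,
                         wfile(file.path(od, "shift_report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", null = "null")
    cfg <- config
    cfg$noise <- unclass(cfg$noise)
    cfg$effect <- unclass(cfg$effect)
    manifest <- list(package = "noteshift",
                     version = as.character(utils::packageVersion("noteshift")),
                     config = unclass(cfg),
                     files = as.list(tools::md5sum(sort(written))))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    attr(written, "failed") <- TRUE
    written <<- written
    stop(e)
  })
}

.config_from_json <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- list(out_dir = raw$out_dir)
  for (f in c("seed", "n_train", "n_prediction_seeds", "char_limit",
              "extraction_threshold", "match_threshold", "alpha",
              "alpha_specialty", "predictions_path")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$n_test)) args$n_test <- unlist(raw$n_test)
  if (!is.null(raw$noise)) args$noise <- do.call(annotator_noise, as.list(raw$noise))
  if (!is.null(raw$effect)) args$effect <- do.call(predictor_effect, as.list(raw$effect))
  do.call(audit_config, args)
}
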