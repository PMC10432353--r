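# Shared tiny fixtures, built in code.

tiny_profile <- function() {
  specialty_profile("epileptologist", c(0.30, 0.62, 0.08), 0.36, 0.50,
                    context_topic_mix = c(0.8, 0.15, 0.05), dialect = "penn")
}

# Gold-record view of a note's latent truth (aligned interface for the
# agreement and diagnostics functions).
truth_as_gold <- function(corpus) {
  lapply(corpus, function(n) c(list(note_id = n$note_id), n$truth))
}

# Attach cached sentence tables (speeds decoy sampling in replicated
# prediction simulations).
with_sentences <- function(corpus) {
  lapply(corpus, function(n) {
    n$sentences <- split_sentences(n$raw_text)
    n
  })
}

penn_splits <- function(corpus, gold = NULL, char_limit = 1506L) {
  kernel_context_splits(corpus, gold,
                        dialect_rules("penn", char_limit = char_limit))$splits
}
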