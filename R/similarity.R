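# Kernel/context decomposition and the four similarity measures of each test
# note against a training corpus (Levenshtein and embedding-cosine, each on
# kernel and context blocks), plus the within-training reference distribution.

#' Split a passage into kernel and surrounding-context text
#'
#' The kernel is the concatenation (order preserved, single-space joined) of
#' all sentences overlapping any gold span — the outcome-bearing sentences the
#' extraction tasks target; the surrounding context is the concatenation of
#' every other sentence. Either side may be empty.
#'
#' @param passage_text The passage text.
#' @param spans A span set in passage coordinates (0-based half-open); spans
#'   outside the passage raise an error.
#' @param note_id Optional id carried through.
#' @return A list with `note_id`, `kernel_text`, `context_text`.
#' @export
split_kernel_context <- function(passage_text, spans, note_id = NULL) {
  nch <- nchar(passage_text)
  if (nrow(spans) && (any(spans$start < 0L) || any(spans$end > nch))) {
    stop("gold span outside passage bounds")
  }
  sents <- split_sentences(passage_text)
  in_kernel <- vapply(seq_len(nrow(sents)), function(k) {
    any(spans_overlap(sents$start[k], sents$end[k], spans$start, spans$end))
  }, TRUE)
  list(note_id = note_id,
       kernel_text = paste(sents$text[in_kernel], collapse = " "),
       context_text = paste(sents$text[!in_kernel], collapse = " "))
}

#' Normalized Levenshtein similarity of two texts
#'
#' `1 - d(a, b) / max(|a|, |b|)` with `d` the character-level edit distance
#' (insertions, deletions, substitutions at unit cost) computed on case-folded
#' text. Two empty strings score 1.
#'
#' @param a,b Strings.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' levenshtein_similarity("kitten", "sitting")  # 1 - 3/7
levenshtein_similarity <- function(a, b) {
  na <- nchar(a)
  nb <- nchar(b)
  if (na == 0L && nb == 0L) return(1)
  d <- drop(adist(tolower(a), tolower(b)))
  1 - d / max(na, nb)
}

#' Cosine similarity of two vectors
#'
#' @param u,v Equal-length numeric vectors; neither may be the zero vector
#'   (callers map empty text to a missing value instead).
#' @return `dot(u, v) / (||u|| ||v||)` in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal dimension")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vector")
  sum(u * v) / (nu * nv)
}

# djb2-style rolling hash -> bucket in 1..dim; fixed constants so embeddings
# are deterministic across sessions.
.hash_bucket <- function(token, dim) {
  h <- 5381
  for (c in utf8ToInt(token)) h <- (h * 33 + c) %% 1048573
  as.integer(h %% dim) + 1L
}

#' Deterministic hashed bag-of-words embedding provider
#'
#' Maps text to an L2-normalized term-frequency vector over `dimension`
#' hashed token buckets. Deterministic, dependency-free and fast, so the full
#' pipeline runs with no model download; any provider with the same contract
#' (a `dimension` and an `embed(text)` function returning a vector of that
#' dimension, zero only for empty text) can be substituted — e.g. a sentence
#' transformer served externally — for production parity with neural sentence
#' embeddings.
#'
#' @param dimension Positive integer vector dimension.
#' @return A list (`embedding_provider`) with `dimension` and `embed`.
#' @export
hashed_embedding_provider <- function(dimension = 512L) {
  if (dimension <= 0) stop("dimension must be positive")
  dimension <- as.integer(dimension)
  embed <- function(text) {
    v <- numeric(dimension)
    toks <- .tokens(text)
    if (!length(toks)) return(v)
    for (tok in toks) {
      i <- .hash_bucket(tok, dimension)
      v[i] <- v[i] + 1
    }
    v / sqrt(sum(v^2))
  }
  structure(list(dimension = dimension, embed = embed),
            class = "embedding_provider")
}

# Embedding matrix with one row per text; empty texts give zero rows.
# Embeddings are computed once per distinct text.
.embed_matrix <- function(texts, provider) {
  ut <- unique(texts)
  E <- t(vapply(ut, provider$embed, numeric(provider$dimension)))
  E[match(texts, ut), , drop = FALSE]
}

# Pairwise normalized Levenshtein similarity matrix (rows a, columns b).
.lev_matrix <- function(a, b) {
  D <- adist(tolower(a), tolower(b))
  M <- outer(nchar(a), nchar(b), pmax)
  S <- 1 - D / M
  S[M == 0] <- 1  # both strings empty
  S
}

#' Similarity profiles of test notes against a training corpus
#'
#' For each test note and each of the four measures (Levenshtein / cosine on
#' kernel / context), computes the arithmetic mean of the pairwise similarity
#' against every training note whose corresponding side is non-empty. Test
#' notes with an empty side get `NA` for that side's measures. Also returns
#' the reference distribution: the same four measures over all unordered
#' within-training pairs (self-pairs excluded).
#'
#' @param test_splits,train_splits Lists of kernel/context splits
#'   ([split_kernel_context()]) or data frames with columns `note_id`,
#'   `kernel_text`, `context_text`. The training corpus must be non-empty.
#' @param provider An embedding provider; defaults to the built-in hashed
#'   bag-of-words provider.
#' @return A list with `profiles` (data frame: `note_id`, `lev_kernel`,
#'   `lev_context`, `cos_kernel`, `cos_context`, `n_train`) and `reference`
#'   (long data frame: `measure`, `value`).
#' @export
profile_against_training <- function(test_splits, train_splits,
                                     provider = hashed_embedding_provider()) {
  test <- .as_split_df(test_splits)
  train <- .as_split_df(train_splits)
  if (!nrow(train)) stop("training corpus must be non-empty")

  profiles <- data.frame(note_id = test$note_id, stringsAsFactors = FALSE)
  ref <- list()
  for (side in c("kernel", "context")) {
    te <- test[[paste0(side, "_text")]]
    tr <- train[[paste0(side, "_text")]]
    te_ok <- nzchar(te)
    tr_ok <- nzchar(tr)

    lev_mean <- rep(NA_real_, nrow(test))
    cos_mean <- rep(NA_real_, nrow(test))
    if (any(te_ok) && any(tr_ok)) {
      L <- .lev_matrix(te[te_ok], tr[tr_ok])
      lev_mean[te_ok] <- rowMeans(L)
      Ete <- .embed_matrix(te[te_ok], provider)
      Etr <- .embed_matrix(tr[tr_ok], provider)
      cos_mean[te_ok] <- rowMeans(Ete %*% t(Etr))
    }
    profiles[[paste0("lev_", side)]] <- lev_mean
    profiles[[paste0("cos_", side)]] <- cos_mean

    if (sum(tr_ok) >= 2L) {
      Ltr <- .lev_matrix(tr[tr_ok], tr[tr_ok])
      Etr <- .embed_matrix(tr[tr_ok], provider)
      Ctr <- Etr %*% t(Etr)
      up <- upper.tri(Ltr)
      ref[[paste0("lev_", side)]] <- Ltr[up]
      ref[[paste0("cos_", side)]] <- Ctr[up]
    } else {
      ref[[paste0("lev_", side)]] <- numeric(0)
      ref[[paste0("cos_", side)]] <- numeric(0)
    }
  }
  profiles <- profiles[, c("note_id", "lev_kernel", "lev_context",
                           "cos_kernel", "cos_context")]
  profiles$n_train <- nrow(train)
  reference <- data.frame(
    measure = rep(names(ref), lengths(ref)),
    value = unlist(ref, use.names = FALSE),
    stringsAsFactors = FALSE)
  list(profiles = profiles, reference = reference)
}

.as_split_df <- function(x) {
  if (is.data.frame(x)) return(x)
  data.frame(
    note_id = vapply(x, function(s) as.character(s$note_id %||% NA_character_), ""),
    kernel_text = vapply(x, `[[`, "", "kernel_text"),
    context_text = vapply(x, `[[`, "", "context_text"),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
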