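# Independent oracles, deliberately implemented apart from the package code
# paths they check.

# Brute-force dynamic-programming Levenshtein distance on case-folded text.
lev_dp_oracle <- function(a, b) {
  ca <- strsplit(tolower(a), "")[[1]]
  cb <- strsplit(tolower(b), "")[[1]]
  na <- length(ca)
  nb <- length(cb)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1)
    cur[1] <- i
    for (j in seq_len(nb)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (ca[i] != cb[j]))
    }
    prev <- cur
  }
  prev[nb + 1]
}

lev_sim_oracle <- function(a, b) {
  na <- nchar(a)
  nb <- nchar(b)
  if (na == 0 && nb == 0) return(1)
  1 - lev_dp_oracle(a, b) / max(na, nb)
}

# Exhaustive-enumeration Mann-Whitney oracle for tie-free samples: U for the
# first sample and the two-sided p over all C(n, nx) equally likely
# assignments of the pooled ranks.
mw_enum_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(n, nx)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(U = u_obs, p = p)
}

random_string <- function(len, alphabet = letters[1:4]) {
  if (len == 0) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Random span set over a small word vocabulary; offsets are synthetic but
# valid (the token-F1 metrics only read the text field).
random_span_set <- function(n_spans, vocab = c("seizure", "three", "last",
                                               "month", "week", "free",
                                               "since", "daily")) {
  if (n_spans == 0) return(span_set())
  texts <- vapply(seq_len(n_spans), function(i) {
    paste(sample(vocab, sample(1:4, 1), replace = TRUE), collapse = " ")
  }, "")
  start <- cumsum(c(0L, nchar(texts[-n_spans]) + 1L))
  span_set(start, start + nchar(texts), texts)
}
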