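# Shared fixtures and independent oracles for the suite. Everything here is
# generated in code; oracles are deliberately naive and kept independent of
# the implementation paths they check.

DNA4 <- c("A", "C", "G", "T")
DNA5 <- c("A", "C", "G", "N", "T")

random_text <- function(n, alphabet = DNA4) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# the four standard trigger policies exercised throughout: (w, p)
std_policies <- function() {
  list(trigger_policy(2L, 1L), trigger_policy(2L, 5L),
       trigger_policy(4L, 11L), trigger_policy(10L, 101L))
}

# Independent add-one-drop-one rolling hash (the implementation evaluates
# each window directly; this recurrence is the second route).
rolling_hashes_incremental <- function(bytes, w, base = 256,
                                       modulus = 2147483647) {
  n <- length(bytes)
  if (n < w) return(numeric(0))
  k <- n - w + 1L
  h <- numeric(k)
  cur <- 0
  for (j in seq_len(w)) cur <- (cur * base + bytes[j]) %% modulus
  h[1L] <- cur
  dp <- 1
  for (j in seq_len(w - 1L)) dp <- (dp * base) %% modulus  # base^(w-1)
  for (s in seq_len(k - 1L) + 1L) {
    cur <- (cur - bytes[s - 1L] * dp) %% modulus
    cur <- (cur * base + bytes[s + w - 1L]) %% modulus
    h[s] <- cur
  }
  h
}

# extended text S' = S . $^w
ext_text <- function(text, w) paste0(text, strrep("$", w))

# All-occurrence scan through Biostrings: the established-library second
# route next to the package's own sliding-window naive_occurrences().
biostrings_occurrences <- function(text, pattern) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::BString(text))
  sort(BiocGenerics::start(hits)) - 1L
}
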