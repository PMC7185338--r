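# Prefix-free parsing: dictionary D of overlapping phrases delimited by
# trigger windows, parse P of phrase ranks, per-phrase occurrence counts.
#
# Coordinate convention (package-wide): 0-based positions, half-open
# intervals [s, e). Phrase ranks are stored 1-based (R indexing); the
# parse-BWT terminator is 0.

# Symbol order is plain byte order; '#' (35) and '$' (36) sort below every
# data character, so data characters must have byte value > 36.
.SEP <- "#"
.SENTINEL <- "$"
.SEP_BYTE <- 35L
.SENTINEL_BYTE <- 36L

# Rolling-hash constants recorded in the index header: polynomial hash over
# bytes with base 256, reduced modulo the Mersenne prime 2^31 - 1. All
# arithmetic stays below 2^53 so plain doubles are exact.
.HASH_BASE <- 256
.HASH_MOD <- 2147483647

.text_bytes <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("text must be a single character string")
  as.integer(charToRaw(text))
}

.check_alphabet <- function(bytes) {
  if (any(bytes <= .SENTINEL_BYTE))
    stop("alphabet error: text must not contain '#', '$', or any byte <= '$'")
  invisible(bytes)
}

#' Create a trigger-window policy
#'
#' A trigger policy decides, as a pure function of a window's `w` characters,
#' whether that window delimits phrases during prefix-free parsing. Two modes
#' are supported: `"hash"`, the production mode, where a window triggers iff
#' its polynomial rolling hash is congruent to 0 modulo `p`; and
#' `"explicit"`, a test-and-teaching mode where the trigger windows are given
#' literally as a set of length-`w` strings. The first and last window of a
#' text are always triggers regardless of mode.
#'
#' @param w Window size in characters (>= 1).
#' @param p Modulus for hash mode (>= 1). `p = 1` makes every window a
#'   trigger, the densest possible parse.
#' @param mode `"hash"` or `"explicit"`.
#' @param triggers Character vector of length-`w` windows (explicit mode).
#' @param base,modulus Hash parameters; the defaults (base 256, modulus
#'   2^31 - 1) are build-time constants recorded in the index header.
#' @return An object of class `trigger_policy`.
#' @examples
#' trigger_policy(w = 4, p = 11)
#' trigger_policy(w = 2, mode = "explicit", triggers = "AC")
#' @export
trigger_policy <- function(w, p = 1L, mode = c("hash", "explicit"),
                           triggers = character(),
                           base = .HASH_BASE, modulus = .HASH_MOD) {
  mode <- match.arg(mode)
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("window size w must be >= 1")
  if (mode == "hash") {
    p <- as.integer(p)
    if (is.na(p) || p < 1L) stop("modulus p must be >= 1")
  } else {
    if (length(triggers) && any(nchar(triggers) != w))
      stop("explicit triggers must all have length w")
  }
  structure(list(w = w, mode = mode, p = if (mode == "hash") p else NA_integer_,
                 triggers = triggers, base = base, modulus = modulus),
            class = "trigger_policy")
}

#' @export
print.trigger_policy <- function(x, ...) {
  if (x$mode == "hash")
    cat(sprintf("trigger_policy: w=%d, rolling hash (base %g mod %g) %%%% %d == 0\n",
                x$w, x$base, x$modulus, x$p))
  else
    cat(sprintf("trigger_policy: w=%d, explicit set of %d window(s)\n",
                x$w, length(x$triggers)))
  invisible(x)
}

# Hash of every length-w window of a byte vector, via w vectorized
# Horner steps (direct per-window evaluation; the incremental
# add-one-drop-one recurrence gives identical values and is used as the
# independent oracle in the tests).
.window_hashes <- function(bytes, w, base = .HASH_BASE, modulus = .HASH_MOD) {
  n <- length(bytes)
  if (n < w) return(numeric(0))
  k <- n - w + 1L
  h <- numeric(k)
  for (j in seq_len(w)) h <- (h * base + bytes[j:(j + k - 1L)]) %% modulus
  h
}

#' Test whether a window is a trigger
#'
#' Pure predicate on a single length-`w` window under a [trigger_policy()].
#' Note the parser additionally forces the first and last window of the
#' extended text to trigger; this function reports only the policy's own
#' decision.
#'
#' @param window A string of exactly `policy$w` characters.
#' @param policy A [trigger_policy()].
#' @return Logical flag.
#' @examples
#' pol <- trigger_policy(w = 2, mode = "explicit", triggers = "AC")
#' is_trigger("AC", pol)  # TRUE
#' is_trigger("CG", pol)  # FALSE
#' @export
is_trigger <- function(window, policy) {
  if (!inherits(policy, "trigger_policy")) stop("policy must be a trigger_policy")
  if (nchar(window) != policy$w)
    stop(sprintf("length error: window has %d characters, expected w=%d",
                 nchar(window), policy$w))
  if (policy$mode == "explicit") return(window %in% policy$triggers)
  b <- as.integer(charToRaw(window))
  h <- .window_hashes(b, policy$w, policy$base, policy$modulus)
  (h %% policy$p) == 0
}

# Trigger start positions (0-based) over the sentinel-extended text bytes.
# First and last windows are forced.
.trigger_positions <- function(bytes_ext, policy) {
  w <- policy$w
  np <- length(bytes_ext)
  last <- np - w  # 0-based start of the final (all-'$') window
  if (policy$mode == "hash") {
    h <- .window_hashes(bytes_ext, w, policy$base, policy$modulus)
    hit <- which((h %% policy$p) == 0) - 1L
  } else {
    k <- np - w + 1L
    wins <- substring(rawToChar(as.raw(bytes_ext)), seq_len(k), seq_len(k) + w - 1L)
    hit <- which(wins %in% policy$triggers) - 1L
  }
  sort(unique(c(0L, hit, last)))
}

#' Prefix-free parse of a text
#'
#' Appends `w` copies of the sentinel `'$'` to the input to form the extended
#' text S' of length `n + w`, slides a length-`w` window over S', and cuts a
#' phrase at every trigger window (the first and last windows always
#' trigger). Consecutive phrases overlap by exactly `w` characters: phrase i
#' spans from trigger i to the end of trigger i+1. The dictionary is the
#' sorted set of distinct phrases; the parse is the sequence of their
#' (1-based) lexicographic ranks in text order.
#'
#' @param text Input string; non-empty, must not contain `'#'` or `'$'`.
#' @param policy A [trigger_policy()].
#' @return An object of class `pfp` with fields `phrases` (sorted distinct
#'   phrase strings), `parse` (integer ranks), `occ` (per-phrase occurrence
#'   counts), `w`, `n_prime` (length of S'), and `last_input_char`.
#' @examples
#' p <- pfp_parse("ACGACG", trigger_policy(2, mode = "explicit", triggers = "AC"))
#' p$phrases  # "ACG$$" "ACGAC"
#' p$parse    # 2 1
#' @export
pfp_parse <- function(text, policy) {
  bytes <- .check_alphabet(.text_bytes(text))
  n <- length(bytes)
  if (n < 1L) stop("empty text")
  w <- policy$w
  ext <- c(bytes, rep(.SENTINEL_BYTE, w))
  np <- n + w
  s <- .trigger_positions(ext, policy)
  k <- length(s)  # >= 2 since 0 < np - w always
  ext_str <- rawToChar(as.raw(ext))
  # phrase i = S'[s_i .. s_{i+1} + w - 1], 0-based inclusive
  phr <- substring(ext_str, s[-k] + 1L, s[-1L] + w)
  phrases <- sort(unique(phr), method = "radix")
  parse <- match(phr, phrases)
  occ <- tabulate(parse, nbins = length(phrases))
  obj <- structure(list(phrases = phrases, parse = parse, occ = occ,
                        w = w, n_prime = np,
                        last_input_char = substr(text, n, n)),
                   class = "pfp")
  stopifnot(sum(nchar(phrases)[parse] - w) + w == np)
  obj
}

#' @export
print.pfp <- function(x, ...) {
  cat(sprintf("prefix-free parse: n'=%d, w=%d, d=%d phrases, |P|=%d\n",
              x$n_prime, x$w, length(x$phrases), length(x$parse)))
  invisible(x)
}

#' Reconstruct the text from its prefix-free parse
#'
#' Expands the parse by concatenating phrases while dropping the `w`-character
#' overlap after the first, then strips the `w` trailing sentinels.
#'
#' @param pfp A [pfp_parse()] result.
#' @param extended If `TRUE`, return the sentinel-extended text S' = S·$^w.
#' @return The original input string (or S' if `extended`).
#' @export
pfp_reconstruct <- function(pfp, extended = FALSE) {
  if (any(pfp$parse < 1L | pfp$parse > length(pfp$phrases)))
    stop("corrupt-parse error: phrase rank out of range")
  phr <- pfp$phrases[pfp$parse]
  if (length(phr) > 1L)
    phr[-1L] <- substring(phr[-1L], pfp$w + 1L)
  s <- paste(phr, collapse = "")
  if (extended) s else substr(s, 1L, nchar(s) - pfp$w)
}

#' Dictionary string t1#t2#...#td#
#'
#' Concatenation of the sorted dictionary phrases, each followed by the
#' separator `'#'`; the form over which the dictionary suffix array is built.
#'
#' @param pfp A [pfp_parse()] result.
#' @return A single string of length sum(nchar(phrases)) + d.
#' @export
pfp_dict_string <- function(pfp) {
  paste0(paste(pfp$phrases, collapse = .SEP), .SEP)
}
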