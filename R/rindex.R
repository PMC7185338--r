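# r-index: run-length compressed BWT + run-boundary SA samples.
#
# Count is plain backward search over the run-length representation; locate
# carries one known SA value (the "toehold", maintained at the bottom row of
# the interval) through the search and then enumerates the remaining
# occurrences with the phi function, a predecessor query over the
# run-boundary samples:
#   phi(SA[j])     = SA[j-1],  keys = SA values at run STARTS,
#                               satellite = SA at the preceding BWT position
#   phi_inv(SA[j]) = SA[j+1],  keys = SA values at run ENDS,
#                               satellite = SA at the following BWT position
# both circular at the ends of the suffix array, with
#   value = satellite(pred(x)) + (x - pred(x))  (mod n).

#' Build an r-index from a BWT and its run-boundary SA samples
#'
#' @param bwt The BWT as a single string (e.g. `pfp_build(...)$bwt`).
#' @param samples Run-boundary samples as produced by
#'   [pfp_build()] in `"samples"` mode: list of data frames `starts` and
#'   `ends` with columns `pos` (BWT position) and `sa` (SA value), one pair
#'   per run.
#' @param records Optional record table (see [read_fasta_collection()]);
#'   carried for position back-mapping and serialization.
#' @param meta Optional named list of build parameters (w, p, hash
#'   constants) recorded in the serialized header.
#' @return An object of class `rindex`.
#' @export
build_rindex <- function(bwt, samples, records = NULL, meta = list()) {
  rd <- run_decomposition(bwt)
  r <- rd$r
  if (nrow(samples$starts) != r || nrow(samples$ends) != r ||
      !identical(as.integer(samples$starts$pos), rd$starts) ||
      !identical(as.integer(samples$ends$pos), rd$ends))
    stop("build error: samples inconsistent with the BWT run structure")
  n <- sum(rd$lengths)
  alph <- sort(unique(rd$heads), method = "radix")
  counts <- vapply(alph, function(c) sum(rd$lengths[rd$heads == c]), numeric(1))
  c_table <- c(0, cumsum(counts))[seq_along(alph)]  # chars strictly smaller
  names(c_table) <- alph
  # per-run cumulative counts of each character over preceding runs
  cum <- matrix(0, nrow = r + 1L, ncol = length(alph),
                dimnames = list(NULL, alph))
  hidx <- match(rd$heads, alph)
  for (a in seq_along(alph)) {
    len <- ifelse(hidx == a, rd$lengths, 0L)
    cum[-1L, a] <- cumsum(len)
  }
  starts_sa <- as.integer(samples$starts$sa)
  ends_sa <- as.integer(samples$ends$sa)
  # phi over run-start keys, phi_inv over run-end keys
  phi_keys <- starts_sa
  phi_sat <- c(ends_sa[r], ends_sa[-r])          # SA at preceding position
  phi_inv_keys <- ends_sa
  phi_inv_sat <- c(starts_sa[-1L], starts_sa[1L])  # SA at following position
  po <- order(phi_keys)
  io <- order(phi_inv_keys)
  # per-character run directory for select queries
  runs_of <- lapply(seq_along(alph), function(a) which(hidx == a))
  structure(list(
    run_heads = rd$heads, run_starts = rd$starts, run_lengths = rd$lengths,
    n = n, r = r, alphabet = alph, c_table = c_table, cum = cum,
    head_idx = hidx, runs_of = runs_of,
    starts_sa = starts_sa, ends_sa = ends_sa,
    phi_keys = phi_keys[po], phi_sat = phi_sat[po],
    phi_inv_keys = phi_inv_keys[io], phi_inv_sat = phi_inv_sat[io],
    records = records, meta = meta), class = "rindex")
}

#' @export
print.rindex <- function(x, ...) {
  cat(sprintf("r-index: n=%d, r=%d runs, n/r=%.3f, alphabet {%s}%s\n",
              x$n, x$r, x$n / x$r, paste(x$alphabet, collapse = ""),
              if (!is.null(x$records))
                sprintf(", %d records", nrow(x$records)) else ""))
  invisible(x)
}

#' Rank query over the run-length BWT
#'
#' Number of occurrences of character `c` in `BWT[0..i)`, by binary search
#' on run starts plus the partial run: O(log r).
#'
#' @param x An [build_rindex()] object.
#' @param c A single character.
#' @param i Position, `0 <= i <= n` (half-open upper end).
#' @return Integer count.
#' @export
rindex_rank <- function(x, c, i) {
  if (i < 0L || i > x$n) stop("bounds error: i must be in [0, n]")
  a <- match(c, x$alphabet)
  if (is.na(a)) return(0L)
  if (i == 0L) return(0L)
  j <- findInterval(i - 1L, x$run_starts)  # run containing position i-1
  extra <- if (x$head_idx[j] == a) i - x$run_starts[j] else 0L
  as.integer(x$cum[j, a] + extra)
}

# position (0-based) of the k-th occurrence (1-based) of alphabet index a
.rindex_select <- function(x, a, k) {
  rs <- x$runs_of[[a]]
  cumlen <- x$cum[rs + 1L, a]              # occurrences up to end of each such run
  j <- rs[findInterval(k - 1L, c(0L, cumlen[-length(cumlen)])) ]
  # j = run holding the k-th occurrence
  prior <- x$cum[j, a]
  x$run_starts[j] + (k - prior) - 1L
}

#' Initial search state over the whole BWT interval
#'
#' @param x An r-index.
#' @return A `search_state`: list with `s`, `e` (half-open interval) and
#'   `toehold` = SA[e - 1].
#' @export
search_start <- function(x) {
  structure(list(s = 0L, e = x$n, toehold = x$ends_sa[x$r]),
            class = "search_state")
}

#' One backward-search step
#'
#' Maps the interval of pattern Q to the interval of cQ:
#' `s' = C[c] + rank(c, s)`, `e' = C[c] + rank(c, e)`; an empty interval is a
#' value, not an error. The toehold (SA of the bottom row) is maintained: if
#' `BWT[e-1] = c` it simply decreases by one (mod n); otherwise the bottom
#' row of cQ corresponds to the last run of `c` inside `[s, e)`, whose end is
#' a sampled position.
#'
#' @param x An r-index.
#' @param state A `search_state` (see [search_start()]).
#' @param c A single character.
#' @return Updated `search_state`.
#' @export
backward_step <- function(x, state, c) {
  if (state$s >= state$e) return(state)  # already empty
  a <- match(c, x$alphabet)
  if (is.na(a)) {
    state$s <- state$e <- 0L; state$toehold <- NA_integer_
    return(state)
  }
  rs <- rindex_rank(x, c, state$s)
  re <- rindex_rank(x, c, state$e)
  if (rs >= re) {
    state$s <- state$e <- 0L; state$toehold <- NA_integer_
    return(state)
  }
  cc <- unname(x$c_table[a])
  pos <- .rindex_select(x, a, re)         # last c in [s, e)
  if (pos == state$e - 1L) {
    toe <- (state$toehold - 1L) %% x$n
  } else {
    j <- findInterval(pos, x$run_starts)  # pos ends a run of c
    toe <- (x$ends_sa[j] - 1L) %% x$n
  }
  structure(list(s = as.integer(cc + rs), e = as.integer(cc + re),
                 toehold = as.integer(toe)), class = "search_state")
}

.check_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L)
    stop("query error: pattern must be a single non-empty string")
  if (grepl("[$#]", pattern))
    stop("query error: pattern must not contain '$' or '#'")
  invisible(pattern)
}

# full backward search; returns final state
.backward_search <- function(x, pattern) {
  ch <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  state <- search_start(x)
  for (c in rev(ch)) {
    state <- backward_step(x, state, c)
    if (state$s >= state$e) break
  }
  state
}

#' Count pattern occurrences
#'
#' Backward search: O(m) steps, each O(log r).
#'
#' @param x An r-index.
#' @param pattern Non-empty string without `'$'`/`'#'`.
#' @return Integer occurrence count.
#' @export
rindex_count <- function(x, pattern) {
  .check_pattern(pattern)
  st <- .backward_search(x, pattern)
  max(st$e - st$s, 0L)
}

#' Locate all pattern occurrences
#'
#' Backward search maintains the toehold SA[e-1]; the remaining entries of
#' SA[s..e) are enumerated bottom-up by repeated [rindex_phi()]. Positions in
#' the sentinel tail cannot match a legal pattern, so every result lies in
#' the input region.
#'
#' @param x An r-index.
#' @param pattern Non-empty string without `'$'`/`'#'`.
#' @return Sorted integer vector of 0-based text positions.
#' @export
rindex_locate <- function(x, pattern) {
  .check_pattern(pattern)
  st <- .backward_search(x, pattern)
  k <- st$e - st$s
  if (k <= 0L) return(integer(0))
  out <- integer(k)
  out[k] <- st$toehold
  if (k > 1L) for (i in (k - 1L):1L) out[i] <- rindex_phi(x, out[i + 1L])
  sort(out)
}

.pred_map <- function(keys, sat, pos, n) {
  j <- findInterval(pos, keys)
  if (j == 0L) j <- length(keys)          # circular fallback to the max key
  (sat[j] + ((pos - keys[j]) %% n)) %% n
}

#' phi: previous suffix-array entry
#'
#' `phi(SA[j]) = SA[j-1]` (circular), via a predecessor query on the
#' run-start sample keys.
#'
#' @param x An r-index.
#' @param pos A value appearing in SA.
#' @return Integer SA value.
#' @export
rindex_phi <- function(x, pos) {
  as.integer(.pred_map(x$phi_keys, x$phi_sat, pos, x$n))
}

#' phi_inv: next suffix-array entry
#'
#' `phi_inv(SA[j]) = SA[j+1]` (circular), via a predecessor query on the
#' run-end sample keys.
#'
#' @param x An r-index.
#' @param pos A value appearing in SA.
#' @return Integer SA value.
#' @export
rindex_phi_inv <- function(x, pos) {
  as.integer(.pred_map(x$phi_inv_keys, x$phi_inv_sat, pos, x$n))
}

#' Compression statistics
#'
#' @param x An r-index.
#' @return List with `n` (BWT length, sentinels included), `r` (number of
#'   BWT runs) and `n_over_r`, the repetitiveness-driven compressibility
#'   measure.
#' @export
rindex_stats <- function(x) {
  list(n = x$n, r = x$r, n_over_r = x$n / x$r)
}

#' Build an r-index straight from a text
#'
#' Convenience wrapper: prefix-free parse, BWT + run-boundary samples, then
#' [build_rindex()].
#'
#' @param text Input string (no `'$'`/`'#'`).
#' @param w Window size (default 10).
#' @param p Trigger modulus (default 100).
#' @param policy Optional [trigger_policy()] overriding `w`/`p`.
#' @param records Optional record table (see [build_rindex()]).
#' @return An `rindex`.
#' @examples
#' x <- rindex_from_text("ACGACG", policy =
#'   trigger_policy(2, mode = "explicit", triggers = "AC"))
#' rindex_count(x, "AC")   # 2
#' rindex_locate(x, "AC")  # 0 3
#' @export
rindex_from_text <- function(text, w = 10L, p = 100L, policy = NULL,
                             records = NULL) {
  if (is.null(policy)) policy <- trigger_policy(w, p)
  pfp <- pfp_parse(text, policy)
  b <- pfp_build(pfp, mode = "samples")
  build_rindex(b$bwt, b$samples, records = records,
               meta = list(w = policy$w, p = policy$p,
                           hash_base = policy$base, hash_modulus = policy$modulus))
}
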