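# BWT / SA / run-boundary SA-sample construction from a prefix-free parse.
#
# Every suffix of the extended text S' = S.$^w, other than the w
# sentinel-only suffixes, is prefixed by exactly one suffix alpha (length
# > w) of a dictionary phrase -- its representative prefix. Scanning the
# dictionary suffix array emits these alphas in lexicographic order; within
# one alpha the relative order of the text suffixes equals the order of the
# corresponding phrase occurrences in the BWT of the parse, recovered by
# merging per-phrase inverted lists. The preceding character comes from the
# dictionary (alpha a proper phrase suffix) or from the stored
# preceding-character array (alpha a full phrase); the SA value is
# end-position - |alpha| + 1. The w sentinel-only suffixes are a closed-form
# prefix block.

#' Suffix array by prefix doubling
#'
#' Positions (0-based) of a text's suffixes in increasing lexicographic
#' (byte) order, computed by rank doubling with radix sorts: O(n log n).
#' Accepts a character string or an integer symbol vector.
#'
#' @param x A single string, or an integer vector of symbols (compared
#'   numerically).
#' @return Integer vector: 0-based suffix start positions in sorted order.
#' @examples
#' plain_suffix_array("banana$")  # 6 5 3 1 0 4 2
#' @export
plain_suffix_array <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("text must be a single string")
    x <- as.integer(charToRaw(x))
  }
  n <- length(x)
  if (n == 0L) stop("empty input")
  if (n == 1L) return(0L)
  rk <- match(x, sort(unique(x)))
  k <- 1L
  repeat {
    k2 <- if (k < n) c(rk[-seq_len(k)], integer(k)) else integer(n)
    o <- order(rk, k2, method = "radix")
    nr <- integer(n)
    nr[o] <- cumsum(c(TRUE, rk[o[-1L]] != rk[o[-n]] | k2[o[-1L]] != k2[o[-n]]))
    rk <- nr
    if (rk[o[n]] == n) return(o - 1L)
    k <- k * 2L
  }
}

#' Dictionary string index
#'
#' The '#'-separated dictionary string together with its suffix array,
#' the structure scanned to enumerate representative prefixes.
#'
#' @param pfp A [pfp_parse()] result.
#' @return An object of class `dict_index`: list with `dict_str` and `sa_d`
#'   (0-based suffix array of `dict_str`).
#' @export
dict_index <- function(pfp) {
  ds <- pfp_dict_string(pfp)
  structure(list(dict_str = ds, sa_d = plain_suffix_array(ds)),
            class = "dict_index")
}

#' BWT of the parse
#'
#' The parse's phrase-rank sequence (ranks 1..d) with terminator 0 appended,
#' transformed by the circular BWT: `BWT[i] = seq[(SA[i] - 1) mod len]`.
#'
#' @param pfp A [pfp_parse()] result.
#' @return Integer vector over 0..d (0 = terminator).
#' @export
parse_bwt <- function(pfp) {
  parse_tables(pfp)$bwt_p
}

#' Parse-level occurrence tables
#'
#' For each dictionary phrase i, three aligned arrays over its `occ[i]`
#' occurrences, ordered by position in the parse BWT: `il[[i]]` the 0-based
#' positions in the parse BWT (inverted list), `pr[[i]]` the character of the
#' extended text immediately preceding the phrase occurrence (circular:
#' position 0 is preceded by the final sentinel), and `ep[[i]]` the 0-based
#' end position of the occurrence in the extended text.
#'
#' @param pfp A [pfp_parse()] result.
#' @return List with `bwt_p` (integer), `il`, `pr`, `ep` (lists of length d).
#' @export
parse_tables <- function(pfp) {
  plen <- nchar(pfp$phrases)
  parse <- pfp$parse
  k <- length(parse)
  # 0-based start of each phrase occurrence in S'; successive phrases
  # advance by len - w
  starts <- c(0L, cumsum(plen[parse[-k]] - pfp$w))
  ep_occ <- starts + plen[parse] - 1L
  ext <- pfp_reconstruct(pfp, extended = TRUE)
  pr_occ <- ifelse(starts == 0L, .SENTINEL,
                   substring(ext, starts, starts))  # char at 0-based starts-1
  seqp <- c(parse, 0L)
  len <- k + 1L
  sa_p <- plain_suffix_array(seqp)
  occ_idx <- (sa_p - 1L) %% len            # 0-based position whose symbol is BWT_P[j]
  bwt_p <- seqp[occ_idx + 1L]
  keep <- occ_idx != k                     # drop the terminator symbol
  f <- factor(bwt_p[keep], levels = seq_along(pfp$phrases))
  j0 <- (seq_len(len) - 1L)[keep]          # ascending, so lists come out sorted
  list(bwt_p = bwt_p,
       il = split(j0, f),
       pr = split(pr_occ[occ_idx[keep] + 1L], f),
       ep = split(ep_occ[occ_idx[keep] + 1L], f))
}

#' Representative prefixes from the dictionary suffix array
#'
#' Scans the dictionary suffix array; each dictionary suffix yields beta, its
#' longest prefix ending at the next '#' (i.e. a phrase suffix). Betas of
#' length <= w are discarded; consecutive equal betas are grouped. The
#' surviving groups are exactly the representative prefixes alpha_1 < alpha_2
#' < ... in strict lexicographic order.
#'
#' @param dindex A [dict_index()].
#' @param w Window size of the parse.
#' @return A data frame with one row per (group, source phrase): `grp` (group
#'   id, increasing with alpha), `alpha`, `alpha_len`, `phrase` (1-based
#'   phrase rank), `full` (alpha equals that whole phrase), `prev_char`
#'   (character preceding alpha inside the phrase; `NA` when `full`).
#' @export
representative_prefixes <- function(dindex, w) {
  ds <- dindex$dict_str
  b <- as.integer(charToRaw(ds))
  l <- length(b)
  hashpos <- which(b == .SEP_BYTE) - 1L    # 0-based '#' positions
  q <- dindex$sa_d
  # next '#' at or after q; phrase id = count of '#' before q, + 1
  nh <- hashpos[findInterval(q - 0.5, hashpos) + 1L]
  pid <- findInterval(q - 0.5, hashpos) + 1L
  pstart <- c(0L, hashpos[-length(hashpos)] + 1L)
  blen <- nh - q
  keep <- blen > w
  q <- q[keep]; blen <- blen[keep]; pid <- pid[keep]
  alpha <- substring(ds, q + 1L, q + blen)
  grp <- cumsum(c(TRUE, alpha[-1L] != alpha[-length(alpha)]))
  full <- q == pstart[pid]
  prev_char <- ifelse(full, NA_character_, substring(ds, q, q))
  data.frame(grp = grp, alpha = alpha, alpha_len = blen, phrase = pid,
             full = full, prev_char = prev_char, stringsAsFactors = FALSE)
}

#' Closed-form block for the sentinel-only suffixes
#'
#' The w suffixes of S' consisting only of sentinels have no representative
#' prefix longer than w; they sort below every other suffix, shortest first,
#' and occupy the first w rows of the suffix array.
#'
#' @param last_input_char Final character of the raw input (it precedes the
#'   first sentinel).
#' @param w Window size (>= 1).
#' @param n_prime Length of the extended text.
#' @return List with `sa` (integer, length w) and `bwt` (character, length w).
#' @examples
#' sentinel_block("G", 2, 8)  # sa 7 6, bwt "$" "G"
#' @export
sentinel_block <- function(last_input_char, w, n_prime) {
  stopifnot(w >= 1L)
  list(sa = as.integer(n_prime - seq_len(w)),
       bwt = c(rep(.SENTINEL, w - 1L), last_input_char))
}

#' Build BWT, SA, and/or the run-boundary SA sample from a prefix-free parse
#'
#' Emits the sentinel block, then walks the representative-prefix groups in
#' lexicographic order. For each group the member phrases' inverted lists are
#' merged by parse-BWT position; each merged element contributes one BWT
#' character (the stored preceding character if alpha is the full phrase,
#' else the dictionary character preceding alpha inside the phrase) and one
#' SA value (end position - |alpha| + 1). In `"samples"` mode, run boundaries
#' of the emitted BWT are paired with their SA values: whenever consecutive
#' characters differ the previous position closes a run (an end pair) and the
#' current one opens the next (a start pair).
#'
#' @param pfp A [pfp_parse()] result.
#' @param mode `"bwt"`, `"sa"` (BWT + full SA), or `"samples"` (BWT +
#'   run-boundary pairs).
#' @return An object of class `pfp_build`: list with `bwt` (single string),
#'   `sa` (0-based integer vector, `"sa"` mode), `samples` (list of `starts`
#'   and `ends` data frames with columns `pos`, `sa`; `"samples"` mode),
#'   `n_prime`, `w`.
#' @examples
#' pol <- trigger_policy(2, mode = "explicit", triggers = "AC")
#' b <- pfp_build(pfp_parse("ACGACG", pol), mode = "sa")
#' b$bwt  # "$GG$AACC"
#' b$sa   # 7 6 3 0 4 1 5 2
#' @export
pfp_build <- function(pfp, mode = c("bwt", "sa", "samples")) {
  mode <- match.arg(mode)
  tabs <- parse_tables(pfp)
  reps <- representative_prefixes(dict_index(pfp), pfp$w)
  # A full phrase can share its group with phrases it suffixes only in one
  # case: the text's opening phrase, whose first window is a forced (not
  # content-defined) trigger. Any other collision would break the parse's
  # prefix-free property.
  mixed <- reps$full & reps$grp %in% reps$grp[duplicated(reps$grp) |
                                              duplicated(reps$grp, fromLast = TRUE)]
  if (any(mixed) && any(reps$phrase[mixed] != pfp$parse[1L]))
    stop("invariant violation: a full phrase is a proper suffix of another phrase")
  cnt <- pfp$occ[reps$phrase]
  ilv <- unlist(tabs$il[reps$phrase], use.names = FALSE)
  epv <- unlist(tabs$ep[reps$phrase], use.names = FALSE)
  prv <- unlist(tabs$pr[reps$phrase], use.names = FALSE)
  gv <- rep.int(reps$grp, cnt)
  fullv <- rep.int(reps$full, cnt)
  chv <- rep.int(reps$prev_char, cnt)
  chv[fullv] <- prv[fullv]
  sav <- epv - rep.int(reps$alpha_len, cnt) + 1L
  o <- order(gv, ilv, method = "radix")
  sb <- sentinel_block(pfp$last_input_char, pfp$w, pfp$n_prime)
  bwt_chars <- c(sb$bwt, chv[o])
  sa <- c(sb$sa, sav[o])
  if (length(bwt_chars) != pfp$n_prime)
    stop("internal error: emitted length != n_prime")
  out <- list(bwt = paste(bwt_chars, collapse = ""), sa = NULL, samples = NULL,
              n_prime = pfp$n_prime, w = pfp$w)
  if (mode == "sa") out$sa <- sa
  if (mode == "samples") {
    r <- rle(bwt_chars)
    ends_pos <- cumsum(r$lengths) - 1L
    starts_pos <- c(0L, ends_pos[-length(ends_pos)] + 1L)
    out$samples <- list(
      starts = data.frame(pos = starts_pos, sa = sa[starts_pos + 1L]),
      ends = data.frame(pos = ends_pos, sa = sa[ends_pos + 1L]))
  }
  class(out) <- "pfp_build"
  out
}

#' @export
print.pfp_build <- function(x, ...) {
  cat(sprintf("pfp_build: n'=%d, w=%d%s%s\n", x$n_prime, x$w,
              if (!is.null(x$sa)) ", full SA" else "",
              if (!is.null(x$samples))
                sprintf(", %d run-boundary sample pairs", nrow(x$samples$starts))
              else ""))
  invisible(x)
}
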