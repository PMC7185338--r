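# Brute-force oracles and a synthetic pan-genome collection generator.
# The oracles are deliberately naive (direct suffix sort, sliding-window
# scan); they define ground truth for every other module's tests and are
# only ever run on desk-scale inputs.

#' Naive suffix array
#'
#' Suffix array by materializing every suffix and byte-sorting: the
#' brute-force ground truth against which the construction is validated.
#'
#' @param text A single non-empty string.
#' @return 0-based suffix positions in lexicographic order.
#' @examples
#' naive_sa("banana$")  # 6 5 3 1 0 4 2
#' @export
naive_sa <- function(text) {
  n <- nchar(text)
  if (n == 0L) stop("empty text")
  suf <- substring(text, seq_len(n), n)
  order(suf, method = "radix") - 1L
}

#' Naive BWT
#'
#' `BWT[i] = S[(SA[i] - 1) mod n]` over the naive suffix array.
#'
#' @param text A single non-empty string.
#' @return The BWT as a single string.
#' @examples
#' naive_bwt("banana$")  # "annb$aa"
#' @export
naive_bwt <- function(text) {
  n <- nchar(text)
  sa <- naive_sa(text)
  i <- ((sa - 1L) %% n) + 1L
  paste(substring(text, i, i), collapse = "")
}

#' All occurrences of a pattern by sliding-window comparison
#'
#' @param text,pattern Single strings; pattern non-empty.
#' @return Sorted 0-based start positions (possibly overlapping), integer(0)
#'   if absent.
#' @examples
#' naive_occurrences("ACGACG", "AC")  # 0 3
#' @export
naive_occurrences <- function(text, pattern) {
  n <- nchar(text); m <- nchar(pattern)
  if (m == 0L) stop("empty pattern")
  if (m > n) return(integer(0))
  s <- seq_len(n - m + 1L)
  which(substring(text, s, s + m - 1L) == pattern) - 1L
}

#' Run decomposition of a BWT
#'
#' Maximal blocks of equal characters with their 0-based start and end
#' positions; r = number of runs.
#'
#' @param bwt A single non-empty string.
#' @return List with `heads` (character), `lengths`, `starts`, `ends`, `r`.
#' @examples
#' run_decomposition("$GG$AACC")$starts  # 0 1 3 4 6
#' @export
run_decomposition <- function(bwt) {
  ch <- strsplit(bwt, "", fixed = TRUE)[[1L]]
  if (length(ch) == 0L) stop("empty input")
  r <- rle(ch)
  ends <- cumsum(r$lengths) - 1L
  list(heads = r$values, lengths = r$lengths,
       starts = c(0L, ends[-length(ends)] + 1L), ends = ends,
       r = length(r$values))
}

#' Synthetic pan-genome collection
#'
#' One random base sequence over {A,C,G,T} plus `m - 1` derived haplotype
#' copies, each carrying independent substitutions (uniform over the three
#' other bases) and short indels (deletion or insertion with equal
#' probability; lengths geometric with the given mean; inserted bases
#' uniform). Emulates a collection of near-identical haplotypes of one
#' chromosome, the regime in which run-length BWT compression pays off.
#'
#' Defaults are the package's reference conditions: 50 kb base, per-base
#' substitution rate 1e-3 and indel initiation rate 1e-4 with mean length 3,
#' roughly the within-species divergence of human haplotypes.
#'
#' @param base_length Base sequence length in characters.
#' @param m Number of records (base + m - 1 mutated copies).
#' @param sub_rate Per-base substitution probability in [0, 1].
#' @param indel_rate Per-base indel initiation probability in [0, 1].
#' @param indel_mean_len Mean indel length (geometric, >= 1).
#' @param seed Optional integer; if given, `set.seed(seed)` is called so the
#'   collection is reproducible.
#' @return Named character vector of m sequences (`seq1` is the base).
#' @examples
#' synth_collection(base_length = 100, m = 3, seed = 1)
#' @export
synth_collection <- function(base_length = 50000L, m = 10L,
                             sub_rate = 0.001, indel_rate = 1e-4,
                             indel_mean_len = 3, seed = NULL) {
  stopifnot(base_length >= 1L, m >= 1L,
            sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            indel_mean_len >= 1)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  base <- sample(bases, base_length, replace = TRUE)
  recs <- vector("list", m)
  recs[[1L]] <- base
  for (i in seq_len(m - 1L)) {
    s <- base
    hit <- which(stats::runif(length(s)) < sub_rate)
    if (length(hit)) {
      # uniform over the three other bases
      shift <- sample.int(3L, length(hit), replace = TRUE)
      s[hit] <- bases[((match(s[hit], bases) - 1L + shift) %% 4L) + 1L]
    }
    idx <- which(stats::runif(length(s)) < indel_rate)
    if (length(idx)) {
      lens <- stats::rgeom(length(idx), prob = 1 / indel_mean_len) + 1L
      del <- stats::runif(length(idx)) < 0.5
      pieces <- vector("list", length(idx))
      for (j in seq_along(idx)) {
        pieces[[j]] <- if (del[j]) character(0)
                       else sample(bases, lens[j], replace = TRUE)
      }
      # apply right-to-left so earlier positions stay valid
      for (j in rev(seq_along(idx))) {
        p <- idx[j]
        if (del[j]) {
          drop <- p:min(p + lens[j] - 1L, length(s))
          s <- s[-drop]
        } else {
          s <- append(s, pieces[[j]], after = p)
        }
      }
    }
    recs[[i + 1L]] <- s
  }
  out <- vapply(recs, paste, character(1L), collapse = "")
  names(out) <- paste0("seq", seq_len(m))
  out
}
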