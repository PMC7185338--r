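# BWT/SA/sample construction from the parse, module by module, each piece
# checked against brute force.

test_that("prefix-doubling suffix array matches hand-derived and brute-force answers", {
  expect_identical(plain_suffix_array("banana$"), c(6L, 5L, 3L, 1L, 0L, 4L, 2L))
  expect_identical(plain_suffix_array("AAA$"), c(3L, 2L, 1L, 0L))
  expect_identical(plain_suffix_array("ACGACG$$"), c(7L, 6L, 3L, 0L, 4L, 1L, 5L, 2L))
  set.seed(303)
  for (i in 1:30) {
    txt <- random_text(sample(1:300, 1L), if (i %% 2) DNA4 else DNA5)
    expect_identical(plain_suffix_array(txt), naive_sa(txt))
  }
  # integer-symbol input sorts by plain suffix order too
  expect_identical(plain_suffix_array(c(2L, 1L, 0L)), c(2L, 1L, 0L))
})

test_that("BWT of the parse follows the circular definition over ranks", {
  pol <- trigger_policy(2, mode = "explicit", triggers = "AC")
  p <- pfp_parse("ACGACG", pol)  # parse ranks [2, 1], terminator 0
  expect_identical(parse_bwt(p), c(1L, 2L, 0L))
  p1 <- pfp_parse("GTGTG", trigger_policy(2, mode = "explicit"))  # single phrase
  expect_identical(parse_bwt(p1), c(1L, 0L))
  # permutation multiset of ranks + terminator
  p2 <- pfp_parse(random_text(500), trigger_policy(2, 5))
  expect_identical(sort(parse_bwt(p2)), sort(c(p2$parse, 0L)))
})

test_that("inverted lists, preceding chars and end positions match the hand trace", {
  pol <- trigger_policy(2, mode = "explicit", triggers = "AC")
  p <- pfp_parse("ACGACG", pol)
  tb <- parse_tables(p)
  i_dollar <- match("ACG$$", p$phrases); i_ac <- match("ACGAC", p$phrases)
  expect_equal(tb$il[[i_dollar]], 0L, ignore_attr = TRUE)
  expect_equal(tb$ep[[i_dollar]], 7L, ignore_attr = TRUE)
  expect_equal(tb$pr[[i_dollar]], "G", ignore_attr = TRUE)
  expect_equal(tb$il[[i_ac]], 1L, ignore_attr = TRUE)
  expect_equal(tb$ep[[i_ac]], 4L, ignore_attr = TRUE)
  expect_equal(tb$pr[[i_ac]], "$", ignore_attr = TRUE)  # circular predecessor of pos 0

  # length law and tiling law on a repetitive input
  p2 <- pfp_parse("ACGACGACG", pol)
  tb2 <- parse_tables(p2)
  expect_identical(lengths(tb2$il, use.names = FALSE), p2$occ)
  expect_identical(lengths(tb2$ep, use.names = FALSE), p2$occ)
  ep_in_parse_order <- sort(unlist(tb2$ep, use.names = FALSE))
  expect_true(all(diff(ep_in_parse_order) > 0))
  expect_identical(max(ep_in_parse_order), p2$n_prime - 1L)
})

test_that("representative prefixes are the phrase suffixes longer than w, grouped and sorted", {
  pol <- trigger_policy(2, mode = "explicit", triggers = "AC")
  di <- dict_index(pfp_parse("ACGACG", pol))
  expect_identical(di$dict_str, "ACG$$#ACGAC#")
  reps <- representative_prefixes(di, 2L)
  expect_identical(reps$alpha,
                   c("ACG$$", "ACGAC", "CG$$", "CGAC", "G$$", "GAC"))
  expect_identical(reps$full, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(all(reps$alpha_len > 2L))
  expect_true(all(diff(reps$grp) %in% 0:1))

  # two phrases sharing a suffix fall into one group
  di2 <- structure(list(dict_str = "GAC#TAC#",
                        sa_d = plain_suffix_array("GAC#TAC#")),
                   class = "dict_index")
  r2 <- representative_prefixes(di2, 1L)
  ac <- r2[r2$alpha == "AC", ]
  expect_identical(nrow(ac), 2L)
  expect_identical(length(unique(ac$grp)), 1L)
  expect_setequal(ac$phrase, c(1L, 2L))
})

test_that("the sentinel block is the first w rows of the oracle suffix array", {
  sb <- sentinel_block("G", 2L, 8L)
  expect_identical(sb$sa, c(7L, 6L))
  expect_identical(sb$bwt, c("$", "G"))
  sb1 <- sentinel_block("T", 1L, 5L)
  expect_identical(sb1$sa, 4L)
  expect_identical(sb1$bwt, "T")
  set.seed(404)
  for (i in 1:10) {
    txt <- random_text(sample(2:50, 1L))
    w <- sample(1:4, 1L)
    ext <- ext_text(txt, w)
    sa <- naive_sa(ext)
    bw <- strsplit(naive_bwt(ext), "")[[1L]]
    sb <- sentinel_block(substr(txt, nchar(txt), nchar(txt)), w, nchar(ext))
    expect_identical(sb$sa, sa[seq_len(w)])
    expect_identical(sb$bwt, bw[seq_len(w)])
  }
})

test_that("full build reproduces the worked example bit for bit", {
  pol <- trigger_policy(2, mode = "explicit", triggers = "AC")
  b <- pfp_build(pfp_parse("ACGACG", pol), mode = "sa")
  expect_identical(b$bwt, "$GG$AACC")
  expect_identical(b$sa, c(7L, 6L, 3L, 0L, 4L, 1L, 5L, 2L))
  bs <- pfp_build(pfp_parse("ACGACG", pol), mode = "samples")
  expect_identical(bs$samples$starts$pos, c(0L, 1L, 3L, 4L, 6L))
  expect_identical(bs$samples$starts$sa, c(7L, 6L, 0L, 4L, 5L))
  expect_identical(bs$samples$ends$pos, c(0L, 2L, 3L, 5L, 7L))
  expect_identical(bs$samples$ends$sa, c(7L, 3L, 0L, 1L, 2L))
  # the GAC group contributes SA = ep - |alpha| + 1 = 4 - 3 + 1 = 2
  expect_identical(b$sa[8L], 2L)
})

test_that("build equals brute force and is invariant to the trigger policy", {
  set.seed(505)
  pols <- std_policies()
  for (i in 1:25) {
    txt <- random_text(sample(1:400, 1L), if (i %% 2) DNA5 else DNA4)
    ref <- NULL
    for (pol in pols) {
      b <- pfp_build(pfp_parse(txt, pol), mode = "sa")
      ext <- ext_text(txt, pol$w)
      expect_identical(b$bwt, naive_bwt(ext))
      expect_identical(b$sa, naive_sa(ext))
      # multiset law
      expect_identical(sort(strsplit(b$bwt, "")[[1L]]),
                       sort(strsplit(ext, "")[[1L]]))
      if (pol$w == 2L) {
        if (is.null(ref)) ref <- b else {
          expect_identical(b$bwt, ref$bwt)
          expect_identical(b$sa, ref$sa)
        }
      }
    }
  }
})

test_that("samples mode equals run boundaries of the full output", {
  set.seed(606)
  for (i in 1:15) {
    txt <- random_text(sample(2:300, 1L))
    pol <- trigger_policy(4, 11)
    p <- pfp_parse(txt, pol)
    full <- pfp_build(p, mode = "sa")
    smp <- pfp_build(p, mode = "samples")$samples
    rd <- run_decomposition(full$bwt)
    expect_identical(smp$starts$pos, rd$starts)
    expect_identical(smp$ends$pos, rd$ends)
    expect_identical(smp$starts$sa, full$sa[rd$starts + 1L])
    expect_identical(smp$ends$sa, full$sa[rd$ends + 1L])
  }
})
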