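# Enhanced-suffix-array matching statistics, extensions, and the spectrum
# with its deduplication rule, validated against brute-force oracles.

test_that("worked string example: banana vs ananas", {
  ms <- matching_stats("banana", "ananas", query = 2, mask_nonacgt = FALSE)
  # longest substring of banana matching a substring starting at position 3
  # (1-based) of ananas has length 3 ("ana")
  expect_identical(ms$x[3], 3L)
  # both occurrences of "ana" in banana are found as partners
  expect_identical(sort(ms$partners[[3]]), c(2L, 4L))
  # the full matching statistics agree with the quadratic scan
  nv <- naive_matching_stats("ananas", "banana", mask = FALSE)
  expect_identical(ms$x, nv$x)
  expect_identical(lapply(ms$partners, sort), lapply(nv$partners, sort))
})

test_that("identical sequences have X_i = L - i + 1", {
  set.seed(21)
  s <- rand_dna(80)
  ms <- matching_stats(s, s)
  expect_identical(ms$x, rev(seq_len(80)))
})

test_that("ESA matching statistics equal the naive quadratic scan", {
  set.seed(22)
  for (rep in 1:8) {
    L1 <- sample(40:200, 1)
    L2 <- sample(40:200, 1)
    s1 <- rand_dna(L1); s2 <- rand_dna(L2)
    ms <- matching_stats(s1, s2)
    nv <- naive_matching_stats(s1, s2)
    expect_identical(ms$x, nv$x)
    expect_identical(lapply(ms$partners, sort), lapply(nv$partners, sort))
  }
  # one larger instance
  s1 <- rand_dna(500); s2 <- rand_dna(500)
  expect_identical(matching_stats(s1, s2)$x, naive_matching_stats(s1, s2)$x)
})

test_that("non-ACGT characters never match under masking", {
  # the N run is shared verbatim, but masked characters match nothing
  s1 <- "ACGTNNNNACGT"
  s2 <- "TTTTNNNNTTTT"
  ms <- matching_stats(s1, s2)
  expect_true(all(ms$x[5:8] == 0L))
  # unmasked literal matching does align the N run
  ms2 <- matching_stats(s1, s2, mask_nonacgt = FALSE)
  expect_identical(ms2$x[5], 4L)
})

test_that("k-mismatch extension length matches a direct scan", {
  # identical tails with k = 0: full tail, truncated at the end
  r <- k_mismatch_extension("ACGTACGT", "ACGTACGT", 3, 3, k = 0)
  expect_identical(r$length, 6L)
  expect_true(r$truncated)
  # constructed mismatch pattern: stop just before the (k+1)-st mismatch
  r <- k_mismatch_extension("TTTTTTTTTT", "TTATTATTAT", 1, 1, k = 2)
  expect_identical(r$length, 8L)
  expect_false(r$truncated)
  # out-of-bounds start
  r <- k_mismatch_extension("ACGT", "ACGT", 9, 1, k = 1)
  expect_identical(r$length, 0L)
  expect_true(r$truncated)
  # random instances vs the R scan oracle
  set.seed(23)
  for (rep in 1:20) {
    s1 <- rand_dna(60); s2 <- rand_dna(60)
    i <- sample(55, 1); j <- sample(55, 1); k <- sample(0:4, 1)
    expect_identical(unclass(k_mismatch_extension(s1, s2, i, j, k)),
                     naive_extension(s1, s2, i, j, k))
  }
})

test_that("extension geometry: starts after the first mismatch ending the exact match", {
  # exact match of length 5 at (1,1), mismatch at position 6, then extension
  # with k = 2 ending just before the third later mismatch
  s1 <- "ACGTA T ACGTACGT A CC"; s1 <- gsub(" ", "", s1)
  s2 <- "ACGTA G ACGTACGT G CA"; s2 <- gsub(" ", "", s2)
  ms <- matching_stats(s1, s2)
  expect_identical(ms$x[1], 5L)
  ext <- k_mismatch_extension(s1, s2, 7, 7, k = 2)
  # 9 matching sites and 2 mismatches up to the end, end reached first
  expect_identical(ext$length, 11L)
  expect_true(ext$truncated)
  ext1 <- k_mismatch_extension(s1, s2, 7, 7, k = 1)
  expect_identical(ext1$length, 10L)  # stops before the second mismatch
  expect_false(ext1$truncated)
})

test_that("spectrum counts each distinct extension start pair once", {
  set.seed(24)
  # a shared 150 nt block between masked (never-matching) flanks: every
  # query position inside the block funnels into the same extension start,
  # so without dedup one isolated length collects hundreds of counts
  block <- rand_dna(150)
  N <- function(n) strrep("N", n)
  s1 <- paste0(N(75), block, N(75))
  s2 <- paste0(N(120), block, N(30))
  with_dd <- match_spectrum(s1, s2, k = 3)
  no_dd <- match_spectrum(s1, s2, k = 3, dedup = FALSE)
  spike <- which.max(no_dd$count)
  expect_gt(no_dd$count[spike], 300)
  # isolated: neighbouring lengths are empty
  expect_identical(max(no_dd$count[c(spike - 2, spike - 1, spike + 1, spike + 2)]), 0)
  # dedup collapses the ~150 per-position repetitions of the block extension
  # to one per direction; what remains are distinct short-match pairs near
  # the block end, not repetitions
  expect_gte(no_dd$count[spike] - with_dd$count[spike], 250)
  expect_lte(with_dd$count[spike], no_dd$count[spike] / 4)
  # conservation: total mass equals the number of distinct counted pairs
  expect_equal(sum(with_dd$count), with_dd$n_extensions)
  expect_gt(no_dd$n_extensions, with_dd$n_extensions)
})

test_that("unrelated sequences put the spectrum mass at the background peak", {
  set.seed(25)
  s1 <- rand_dna(2000); s2 <- rand_dna(2000)
  sp <- match_spectrum(s1, s2, k = 6)
  m_B <- peak_positions(model_params(p = 0.26, q = 0.25, L = 2000, k = 6))$m_B
  sm <- smooth_spectrum(sp, 5)
  expect_lte(abs(sm$m[which.max(sm$count)] - m_B), 3)
})
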