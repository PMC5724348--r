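# Closed-form length laws: fixed values, normalizations, shapes, and
# Monte-Carlo agreement with the heuristic run on simulated pairs.

test_that("negative binomial match-length pmf matches direct arithmetic", {
  expect_equal(negbin_match_pmf(0, 0.5, 0), 0.5)
  expect_equal(negbin_match_pmf(5, 0.25, 2), choose(5, 2) * 0.25^3 * 0.75^3)
  # independent direct formula over a grid
  for (k in c(0, 1, 3, 8)) for (p in c(0.25, 0.5, 0.9)) {
    n <- k:(k + 60)
    expect_equal(negbin_match_pmf(n, p, k),
                 choose(n, k) * p^(n - k) * (1 - p)^(k + 1),
                 tolerance = 1e-12)
    expect_lt(abs(sum(negbin_match_pmf(k:2000, p, k)) - 1), 1e-6)
  }
  expect_equal(negbin_match_pmf(2, 0.5, 5), 0)  # n < k
  expect_error(negbin_match_pmf(3, 1, 1), "match_prob")
})

test_that("longest exact match law sums to one and degenerates to background", {
  pars <- model_params(p = 0.6, q = 0.25, L = 1e4, k = 0)
  expect_lt(abs(sum(exact_longest_pmf(1:200, pars)) - 1), 1e-6)
  # p -> q: the law reduces to the pure background difference form
  pars_bg <- model_params(p = 0.25 + 1e-12, q = 0.25, L = 1e4, k = 0)
  n <- 1:60
  bg_cdf <- function(n, q, L) (1 - q^n)^(L - n + 1)
  expect_equal(exact_longest_pmf(n, pars_bg),
               bg_cdf(n + 1, 0.25, 1e4) - bg_cdf(n, 0.25, 1e4),
               tolerance = 1e-6)
})

test_that("longest exact match law matches Monte-Carlo matching statistics", {
  set.seed(61)
  L <- 2000; nrep <- 120; win <- L - 200
  pars <- model_params(p = 0.7, q = 0.25, L = L, k = 0)
  bins <- 1:40
  theory <- exact_longest_pmf(bins, pars)
  keep <- theory >= 1e-3          # compare bins carrying real mass
  freq <- t(vapply(seq_len(nrep), function(r) {
    pair <- simulate_pair(L = L, p = 0.7, seed = 9000 + r)
    x <- matching_stats(pair$s1, pair$s2)$x[seq_len(win)]
    tabulate(factor(x, levels = bins), nbins = length(bins)) / win
  }, numeric(length(bins))))
  expect_within_3se(freq[, keep], theory[keep], "exact longest")
})

test_that("k-mismatch longest match law: boundaries, monotonicity, Monte-Carlo", {
  pars <- model_params(p = 0.7, q = 0.25, L = 2000, k = 3)
  expect_equal(kmismatch_longest_cdf(0:3, pars), rep(0, 4))
  cdf <- kmismatch_longest_cdf(4:300, pars)
  expect_true(all(diff(cdf) >= -1e-12))
  expect_equal(kmismatch_longest_cdf(2001, pars), 1)
  # Monte-Carlo via the naive quadratic scan (independent of the heuristic)
  set.seed(62)
  L <- 2000; nrep <- 60; win <- L - 200
  bins <- 4:60
  theory <- kmismatch_longest_pmf(bins, pars)
  keep <- theory >= 1e-3
  freq <- t(vapply(seq_len(nrep), function(r) {
    pair <- simulate_pair(L = L, p = 0.7, seed = 11000 + r)
    x <- kmatchdist:::cpp_naive_kmismatch_longest(pair$s1, pair$s2, 3L, TRUE)
    tabulate(factor(x[seq_len(win)], levels = bins), nbins = length(bins)) / win
  }, numeric(length(bins))))
  expect_within_3se(freq[, keep], theory[keep], "kmismatch longest")
})

test_that("heuristic hit length law is bimodal and matches Monte-Carlo", {
  # bimodal expected-count curve, background maximum left of homologous
  pars <- model_params(p = 0.6, q = 0.25, L = 1e5, k = 20)
  sp <- kmacs_hit_pmf(20:120, pars)
  expect_true(all(sp$total >= 0))
  expect_equal(sp$total, sp$homologous + sp$background)
  m_bg <- sp$m[which.max(sp$background)]
  m_hom <- sp$m[which.max(sp$homologous)]
  expect_gt(m_hom, m_bg)
  expect_error(kmacs_hit_pmf(10, model_params(p = 0.6, L = 100, k = 0)), "k >= 1")

  # Monte-Carlo: full heuristic hits on simulated pairs; ties between the
  # homologous and a background partner go to the homologous one, the
  # convention of this closed form
  set.seed(63)
  L <- 2000; nrep <- 200; win <- L - 200
  pars2 <- model_params(p = 0.7, q = 0.25, L = L, k = 5)
  theo <- kmacs_hit_pmf(5:70, pars2)
  keep <- theo$total >= 1e-3
  res <- lapply(seq_len(nrep), function(r) {
    pair <- simulate_pair(L = L, p = 0.7, seed = 13000 + r)
    pp <- kmatchdist:::.per_position(pair$s1, pair$s2, k = 5,
                                     tie = "homologous")
    pp <- pp[seq_len(win), ]
    pp <- pp[pp$valid & !pp$hit_truncated, ]
    list(tot = tabulate(factor(pp$hit, levels = theo$m), nbins = nrow(theo)) / win,
         hom = tabulate(factor(pp$hit[pp$homologous], levels = theo$m),
                        nbins = nrow(theo)) / win)
  })
  tot <- do.call(rbind, lapply(res, `[[`, "tot"))
  hom <- do.call(rbind, lapply(res, `[[`, "hom"))
  expect_within_3se(tot[, keep], theo$total[keep], "hit total")
  expect_within_3se(hom[, keep], theo$homologous[keep], "hit homologous")
})

test_that("extension length law: normalization, recursion, Monte-Carlo", {
  pars <- model_params(p = 0.7, q = 0.25, L = 2000, k = 5)
  sp <- extension_pmf(5:500, pars)
  expect_lt(abs(sum(sp$total) - 1), 1e-9)
  # homologous-part recursion H(m+1) = (m+1)/(m+1-k) * p * H(m)
  H <- sp$homologous
  m <- sp$m
  expect_equal(H[-1], (m[-1]) / (m[-1] - 5) * 0.7 * H[-length(H)],
               tolerance = 1e-12)
  # each component unimodal: one sign change in first differences
  sgn_changes <- function(v) sum(diff(sign(diff(v[v > 1e-300]))) != 0)
  expect_lte(sgn_changes(sp$homologous), 1)
  expect_lte(sgn_changes(sp$background), 1)

  # Monte-Carlo: extensions after the first mismatch; ties select a
  # background partner, the convention of the mixture weight P(j* = i)
  set.seed(64)
  L <- 2000; nrep <- 200; win <- L - 200
  theo <- extension_pmf(5:60, pars)
  keep <- theo$total >= 1e-3
  res <- lapply(seq_len(nrep), function(r) {
    pair <- simulate_pair(L = L, p = 0.7, seed = 13000 + r)
    pp <- kmatchdist:::.per_position(pair$s1, pair$s2, k = 5,
                                     tie = "background")
    pp <- pp[seq_len(win), ]
    pp <- pp[pp$valid & !pp$ext_truncated, ]
    list(tot = tabulate(factor(pp$ext, levels = theo$m), nbins = nrow(theo)) / win,
         hom = tabulate(factor(pp$ext[pp$homologous], levels = theo$m),
                        nbins = nrow(theo)) / win)
  })
  tot <- do.call(rbind, lapply(res, `[[`, "tot"))
  hom <- do.call(rbind, lapply(res, `[[`, "hom"))
  expect_within_3se(tot[, keep], theo$total[keep], "ext total")
  expect_within_3se(hom[, keep], theo$homologous[keep], "ext homologous")
})

test_that("a large enough k separates the homologous peak", {
  # at L = 500 kb, p = 0.5: k = 10 leaves no separate homologous maximum in
  # the total law, k = 70 separates it
  for (cfg in list(list(k = 10, separated = FALSE),
                   list(k = 70, separated = TRUE))) {
    pars <- model_params(p = 0.5, q = 0.25, L = 5e5, k = cfg$k)
    sp <- extension_pmf(cfg$k:400, pars)
    pk <- peak_positions(pars)
    # local maxima of the total curve
    d1 <- diff(sp$total)
    lm <- which(diff(sign(d1)) < 0) + 1
    near_hom <- any(abs(sp$m[lm] - pk$m_H) <= 2)
    expect_identical(near_hom, cfg$separated)
  }
})

test_that("peak position formula equals brute-force argmax", {
  expect_identical(peak_positions(model_params(p = 0.5, L = 5e5, k = 90))$m_H, 179L)
  expect_identical(peak_positions(model_params(p = 0.5, L = 5e5, k = 90))$m_B, 119L)
  # m_B by brute force for the reference setting
  bg <- negbin_match_pmf(90:400, 0.25, 90)
  expect_identical(90L + which.max(bg) - 1L, 119L)
  # exhaustive grid; which.max takes the leftmost of a plateau, matching the
  # ceiling form of the mode
  for (k in c(1L, 2L, 5L, 10L, 25L, 50L)) for (p in seq(0.1, 0.9, by = 0.1)) {
    pars <- model_params(p = p, q = min(0.25, p / 2), L = 1e6, k = k)
    m_up <- as.integer(ceiling(3 * k / (1 - p))) + 50L
    hom <- negbin_match_pmf(k:m_up, p, k)
    # exact mode ties (k/(1-p) integer) form two-bin plateaus; take the
    # leftmost maximum up to float noise, the convention of the ceiling form
    argmax <- k + which(hom >= max(hom) * (1 - 1e-9))[1] - 1L
    expect_identical(argmax, peak_positions(pars)$m_H,
                     label = sprintf("k=%d p=%.1f", k, p))
  }
  expect_error(peak_positions(model_params(p = 1, q = 0.25, L = 100, k = 5)),
               "diverges")
})

test_that("probability of a homologous longest match behaves as expected", {
  p6 <- prob_homologous(model_params(p = 0.6, q = 0.25, L = 1e5, k = 20))
  expect_lt(abs(p6 - 0.01), 0.002)
  # approaches 1 as p -> 1 at fixed L, q
  expect_gt(prob_homologous(model_params(p = 0.9999, q = 0.25, L = 1e5, k = 20)),
            0.99)
  # monotone increasing in p
  ps <- seq(0.3, 0.9, by = 0.1)
  vals <- vapply(ps, function(p)
    prob_homologous(model_params(p = p, q = 0.25, L = 1e5, k = 20)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("Jukes-Cantor correction and its inverse", {
  expect_equal(round(jukes_cantor_distance(0.5), 3), 0.824)
  expect_equal(round(jukes_cantor_distance(0.6), 2), 0.57)
  expect_equal(jukes_cantor_distance(1), 0)
  expect_error(jukes_cantor_distance(0.25), "saturation")
  d <- c(0.01, 0.2, 0.8, 2)
  expect_equal(jukes_cantor_distance(jukes_cantor_match_prob(d)), d)
})

test_that("theoretical spectrum TSV export round-trips", {
  pars <- model_params(p = 0.6, q = 0.25, L = 1e5, k = 20)
  sp <- kmacs_hit_pmf(20:40, pars)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_theoretical_spectrum(sp, path)
  back <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(back$total, sp$total, tolerance = 1e-12)
  expect_equal(back$m, sp$m)
})
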