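# Closed-form length distributions of exact and k-mismatch common substrings
# under the gap-free Jukes-Cantor pair model.  Edge effects at the sequence
# ends are ignored throughout, which is accurate for L much larger than the
# lengths carrying probability mass; tests renormalize explicitly where a
# truncated support is compared.

#' Negative binomial law of a k-mismatch match at a fixed position pair
#'
#' Probability that the maximal gap-free match with exactly `k` mismatches
#' between two fixed starting positions has length `n`, i.e. the (k+1)-st
#' mismatch occurs right after `n` sites of which exactly `k` mismatch:
#' `choose(n, k) * prob^(n-k) * (1-prob)^(k+1)`.
#'
#' @param n match length(s), integer, `n >= k` (0 returned below `k`).
#' @param match_prob per-site match probability in (0, 1): `p` for a
#'   homologous position pair, `q` for background.
#' @param k number of allowed mismatches, `k >= 0`.
#' @return Vector of probabilities, same length as `n`.
#' @examples
#' negbin_match_pmf(0, 0.5, 0)            # 0.5
#' negbin_match_pmf(5, 0.25, 2)           # choose(5,2) * 0.25^3 * 0.75^3
#' @export
negbin_match_pmf <- function(n, match_prob, k) {
  stopifnot(is.numeric(n), length(match_prob) == 1L, length(k) == 1L,
            k >= 0, k == floor(k))
  if (match_prob <= 0 || match_prob >= 1)
    stop("match_prob must lie strictly in (0, 1)")
  out <- numeric(length(n))
  ok <- n >= k
  # length n with k mismatches = k+1 runs of matches: negative binomial in
  # the n - k matching sites with k+1 "failures" (mismatches incl. the
  # terminating one)
  out[ok] <- dnbinom(n[ok] - k, size = k + 1, prob = 1 - match_prob)
  out
}

#' Length law of the longest exact match at a position
#'
#' Probability that the longest substring starting at a fixed position of one
#' sequence and matching anywhere in the other sequence has length `n`:
#' the difference of the cumulative law
#' `P(X_i < n) = (1 - q^n)^(L-n) * (1 - p^n)`.
#'
#' @param n length(s), `1 <= n <= L`.
#' @param params a [model_params()] object (`k` unused here).
#' @return Vector of probabilities.
#' @export
exact_longest_pmf <- function(n, params) {
  stopifnot(inherits(params, "model_params"))
  p <- params$p; q <- params$q; L <- params$L
  cdf <- function(n) exp((L - n) * log1p(-q^n)) * (1 - p^n)
  cdf(n + 1) - cdf(n)
}

#' Cumulative length law of the longest k-mismatch match at a position
#'
#' `P(X_i^(k) < n)`, the probability that no substring starting at a fixed
#' position matches anywhere in the other sequence with at most `k`
#' mismatches over `n` or more sites.  Boundary cases: 0 for `n <= k`, 1 for
#' `n > L`.
#'
#' @param n length(s), `n > k` for the non-trivial branch.
#' @param params a [model_params()] object.
#' @return Vector of probabilities, non-decreasing in `n`.
#' @seealso [kmismatch_longest_pmf()] for the first-difference pmf.
#' @export
kmismatch_longest_cdf <- function(n, params) {
  stopifnot(inherits(params, "model_params"))
  p <- params$p; q <- params$q; L <- params$L; k <- params$k
  # S(n, prob) = P(X_{i,j}^(k) >= n) = sum_{k' <= k} C(n,k') prob^(n-k') (1-prob)^k'
  S <- function(n, prob) {
    s <- numeric(length(n))
    for (kp in 0:k)
      s <- s + exp(lchoose(n, kp) + (n - kp) * log(prob) + kp * log(1 - prob))
    pmin(s, 1)
  }
  out <- numeric(length(n))
  lo <- n <= k
  hi <- n > L
  mid <- !lo & !hi
  out[hi] <- 1
  nm <- n[mid]
  out[mid] <- exp((L - nm) * log1p(-S(nm, q))) * (1 - S(nm, p))
  out
}

#' @rdname kmismatch_longest_cdf
#' @export
kmismatch_longest_pmf <- function(n, params) {
  kmismatch_longest_cdf(n + 1, params) - kmismatch_longest_cdf(n, params)
}

.new_theoretical_spectrum <- function(m, homologous, background, params, kind) {
  structure(data.frame(m = m, homologous = homologous, background = background,
                       total = homologous + background),
            params = params, kind = kind,
            class = c("theoretical_spectrum", "data.frame"))
}

#' Length law of the heuristic k-mismatch common substring (full hit)
#'
#' Distribution of the length of the full heuristic hit at a position: the
#' longest exact match, the first mismatch, and the gap-free extension with
#' `k - 1` further mismatches.  Returned decomposed into the homologous part
#' (the selected partner is the homologous position) and the background part,
#' whose sum is the total probability.  For long sequences the expected
#' number of hits of length `m` is `L * total(m)`.
#'
#' The closed form assigns ties between the homologous match and the best
#' background match to the homologous component; see the package vignette.
#'
#' @param m hit length(s), `k <= m <= L`.
#' @param params a [model_params()] object with `k >= 1`.
#' @return A `theoretical_spectrum` data frame with columns `m`,
#'   `homologous`, `background`, `total`.
#' @export
kmacs_hit_pmf <- function(m, params) {
  stopifnot(inherits(params, "model_params"))
  p <- params$p; q <- params$q; L <- params$L; k <- params$k
  if (k < 1) stop("the heuristic hit law requires k >= 1 (uses a k-1 extension)")
  hom <- bg <- numeric(length(m))
  lq1 <- log(1 - q)
  for (t in seq_along(m)) {
    mm <- m[t]
    if (mm < k) next
    m1 <- 0:(mm - 1)           # exact-match length
    m2 <- mm - 1 - m1          # extension length (k-1 mismatches)
    lb <- lchoose(m2, k - 1)   # -Inf where m2 < k-1
    # homologous: exact match at the homologous position (p^m1 (1-p), all
    # background matches no longer), then a (k-1)-mismatch homologous
    # extension (C(m2,k-1) p^(m2-k+1) (1-p)^k); the p-exponents collapse to
    # m1 + m2 - k + 1 = m - k
    hom[t] <- sum(exp((mm - k) * log(p) + (k + 1) * log1p(-p) +
                        (L - m1) * log1p(-q^(m1 + 1)) + lb))
    # background: best background match of length m1 strictly exceeds the
    # homologous match, then a (k-1)-mismatch background extension
    amax <- exp((L - m1) * log1p(-q^(m1 + 1)))
    amin <- exp((L - m1) * log1p(-q^m1))      # 0 at m1 = 0
    bg[t] <- sum((amax - amin) * (1 - p^m1) *
                   exp(lb + (m2 - k + 1) * log(q) + k * lq1))
  }
  .new_theoretical_spectrum(m, hom, bg, params, "hit")
}

#' Probability that the longest exact match at a position is homologous
#'
#' `P(j* = i) = sum_m (1 - q^m)^(L-1) * p^m * (1 - p)`: the homologous match
#' has some length m and every background match is strictly shorter.  Ties
#' count as background, matching the convention that a background partner is
#' selected when one attains the maximum.  The series is truncated once a
#' term falls below `tol` (terms decay geometrically).
#'
#' @param params a [model_params()] object.
#' @param tol truncation threshold for the series terms.
#' @return A probability.
#' @examples
#' prob_homologous(model_params(p = 0.6, L = 1e5, k = 20))  # about 0.01
#' @export
prob_homologous <- function(params, tol = 1e-15) {
  stopifnot(inherits(params, "model_params"))
  p <- params$p; q <- params$q; L <- params$L
  if (p == 1) return(1)
  total <- 0
  m <- 1
  repeat {
    term <- exp((L - 1) * log1p(-q^m) + m * log(p) + log1p(-p))
    total <- total + term
    # terms first grow with (1-q^m)^(L-1), then decay like p^m
    if (term < tol && m > log(1 / tol) / log(1 / q)) break
    m <- m + 1
    if (m > 1e7) break
  }
  total
}

#' Length law of the k-mismatch extension after the first mismatch
#'
#' Distribution of the extension variable used by the distance estimator: the
#' gap-free match with exactly `k` mismatches starting just after the first
#' mismatch that ends the longest exact match.  A two-component negative
#' binomial mixture: with probability `P(j* = i)` (see [prob_homologous()])
#' the extension is homologous, `H_k(m)`, otherwise background, `B_k(m)`.
#'
#' @param m extension length(s), `m >= k`.
#' @param params a [model_params()] object.
#' @return A `theoretical_spectrum` data frame with columns `m`,
#'   `homologous`, `background`, `total`.  For long sequences the expected
#'   spectrum count at `m` is approximately `n_extensions * total(m)`.
#' @export
extension_pmf <- function(m, params) {
  stopifnot(inherits(params, "model_params"))
  ph <- prob_homologous(params)
  hom <- ph * negbin_match_pmf(m, params$p, params$k)
  bg <- (1 - ph) * negbin_match_pmf(m, params$q, params$k)
  .new_theoretical_spectrum(m, hom, bg, params, "extension")
}

#' Modes of the homologous and background extension-length components
#'
#' The homologous component of the extension-length mixture is maximal at
#' `m_H = ceiling(k/(1-p) - 1)` and the background component at
#' `m_B = ceiling(k/(1-q) - 1)`; `m_H > m_B` whenever `p > q`, which is what
#' makes the homologous peak detectable to the right of the background peak.
#'
#' @param params a [model_params()] object with `k >= 1` and `p, q < 1`.
#' @return A list with integer elements `m_H` and `m_B`.
#' @examples
#' peak_positions(model_params(p = 0.5, L = 5e5, k = 90))  # m_H = 179
#' @export
peak_positions <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$p >= 1) stop("p = 1: homologous peak position diverges")
  if (params$k < 1) stop("peak positions require k >= 1")
  up <- function(prob) as.integer(ceiling(params$k / (1 - prob) - 1 - 1e-9))
  list(m_H = up(params$p), m_B = up(params$q))
}

#' @export
print.theoretical_spectrum <- function(x, ...) {
  pa <- attr(x, "params")
  cat(sprintf("Theoretical %s-length spectrum (p = %g, q = %g, L = %g, k = %d)\n",
              attr(x, "kind"), pa$p, pa$q, pa$L, pa$k))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("...", nrow(x), "lengths\n")
  invisible(x)
}

#' @export
#' @method plot theoretical_spectrum
plot.theoretical_spectrum <- function(x, ...) {
  plot(x$m, x$total, type = "l", xlab = "length m", ylab = "probability", ...)
  lines(x$m, x$homologous, col = "firebrick")
  lines(x$m, x$background, col = "steelblue")
  legend("topright", c("total", "homologous", "background"), lty = 1,
         col = c("black", "firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Export a theoretical spectrum as TSV
#'
#' Writes columns `m`, `total`, `homologous`, `background`, preceded by
#' comment lines recording the model parameters and package version.
#'
#' @param spec a `theoretical_spectrum` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_theoretical_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "theoretical_spectrum"))
  pa <- attr(spec, "params")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kmatchdist %s theoretical %s spectrum",
                       as.character(packageVersion("kmatchdist")), attr(spec, "kind")),
               sprintf("# p=%g q=%g L=%g k=%d", pa$p, pa$q, pa$L, pa$k)), con)
  write.table(as.data.frame(spec)[, c("m", "total", "homologous", "background")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
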