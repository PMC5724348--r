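# Distance estimation: peak position -> match probability -> Jukes-Cantor
# distance, the per-pair model object, and the all-vs-all matrix.

#' Match probability from the homologous peak position
#'
#' The homologous component of the extension-length mixture is maximal at
#' `ceiling(k/(1-p) - 1)`, which brackets `p` between `(m_E - k)/m_E` and
#' `(m_E + 1 - k)/(m_E + 1)`; the upper end is used as the point estimate
#' `p-hat = (m_E + 1 - k)/(m_E + 1)`.
#'
#' @param m_E observed position of the homologous (second) peak, `m_E >= k`.
#' @param k mismatch count used when collecting the spectrum.
#' @return Estimated match probability.
#' @examples
#' estimate_p(179, 90)  # 0.5
#' @export
estimate_p <- function(m_E, k) {
  stopifnot(is.numeric(m_E), is.numeric(k), k >= 1)
  if (any(m_E < k)) stop("m_E < k: impossible peak position")
  (m_E + 1 - k) / (m_E + 1)
}

.new_estimate <- function(status, m_star = NA_integer_, p_hat = NA_real_,
                          d_hat = NA_real_, peak = NULL, k, w, ratio, x) {
  structure(list(status = status, m_star = m_star, p_hat = p_hat,
                 d_hat = d_hat, peak = peak, k = k, w = w, ratio = ratio,
                 x = x),
            class = "distance_estimate")
}

#' Distance estimate from an extension-length spectrum
#'
#' Smooths the raw spectrum with a window of width `w`, locates the second
#' peak under the side constraints of [find_second_peak()], converts its
#' position into a match probability and applies the Jukes-Cantor
#' correction.  All failure modes are reported as statuses, never errors:
#' `"no_peak"` when no qualifying second peak exists (no distance can be
#' estimated) and `"saturated"` when the implied match probability is at or
#' below 1/4.
#'
#' @param spec a [match_spectrum()].
#' @param w smoothing window width (odd).
#' @param ratio,x side-constraint parameters of [find_second_peak()].
#' @param k mismatch count; defaults to the one recorded in `spec`.
#' @return An object of class `"distance_estimate"`: list with `status`
#'   (`"ok"`, `"no_peak"` or `"saturated"`), `m_star`, `p_hat`, `d_hat`, and
#'   the `peak` call.
#' @export
estimate_distance <- function(spec, w = 31, ratio = 10, x = 4, k = spec$k) {
  sm <- smooth_spectrum(spec, w)
  pk <- find_second_peak(sm, ratio = ratio, x = x)
  if (!pk$found)
    return(.new_estimate("no_peak", peak = pk, k = k, w = w, ratio = ratio, x = x))
  p_hat <- estimate_p(pk$m_star, k)
  if (p_hat <= 0.25)
    return(.new_estimate("saturated", m_star = pk$m_star, p_hat = p_hat,
                         peak = pk, k = k, w = w, ratio = ratio, x = x))
  .new_estimate("ok", m_star = pk$m_star, p_hat = p_hat,
                d_hat = jukes_cantor_distance(p_hat), peak = pk,
                k = k, w = w, ratio = ratio, x = x)
}

#' @export
print.distance_estimate <- function(x, ...) {
  switch(x$status,
         ok = cat(sprintf("m* = %d  =>  p-hat = %.4f, d-hat = %.4f substitutions/site\n",
                          x$m_star, x$p_hat, x$d_hat)),
         no_peak = cat("no second peak found; no distance estimated\n"),
         saturated = cat(sprintf("m* = %d implies p-hat = %.4f <= 0.25: distance saturated\n",
                                 x$m_star, x$p_hat)))
  invisible(x)
}

#' Fit the k-mismatch common substring distance model to a sequence pair
#'
#' The main per-pair fitting function: collects the k-mismatch extension
#' length spectrum of the two sequences ([match_spectrum()]), smooths it,
#' locates the homologous peak and estimates the per-site match probability
#' and Jukes-Cantor distance ([estimate_distance()]).
#'
#' The defaults `k = 90`, `w = 31` are the operating point for sequences of
#' around 500 kb; for substantially shorter sequences both should be scaled
#' down (see [suggest_k()] and the package vignette).
#'
#' @param s1,s2 DNA sequences: character strings, `DNAString`s, or (if `s2`
#'   is missing) a length-2 `DNAStringSet`, list, character vector, or a
#'   [simulate_pair()] result.
#' @param k number of mismatches in the extensions.
#' @param w smoothing window width (odd).
#' @param ratio,x peak side constraints, see [find_second_peak()].
#' @param pool_directions use both sequences as query and pool the spectra.
#' @param mask_nonacgt treat non-ACGT characters as never matching.
#' @return An object of class `"kcs_fit"` with components `spectrum`,
#'   `smoothed`, `peak`, `status`, `m_star`, `p_hat`, `d_hat` and the call;
#'   methods: `print`, `summary`, `coef`, `plot`, `simulate`.
#' @examples
#' pair <- simulate_pair(L = 20000, d = 0.3, seed = 7)
#' fit <- kcs_fit(pair, k = 25, w = 7)
#' fit
#' coef(fit)
#' @export
kcs_fit <- function(s1, s2 = NULL, k = 90, w = 31, ratio = 10, x = 4,
                    pool_directions = TRUE, mask_nonacgt = TRUE) {
  cl <- match.call()
  if (is.null(s2)) {
    if (inherits(s1, "sim_pair")) { s2 <- s1$s2; s1 <- s1$s1 }
    else if (length(s1) == 2L) { s2 <- s1[[2]]; s1 <- s1[[1]] }
    else stop("supply two sequences, or one object holding a pair")
  }
  spec <- match_spectrum(s1, s2, k = k, pool_directions = pool_directions,
                         mask_nonacgt = mask_nonacgt)
  est <- estimate_distance(spec, w = w, ratio = ratio, x = x)
  structure(list(spectrum = spec, smoothed = smooth_spectrum(spec, w),
                 peak = est$peak, status = est$status, m_star = est$m_star,
                 p_hat = est$p_hat, d_hat = est$d_hat, k = k, w = w,
                 ratio = ratio, x = x,
                 L = c(nchar(.as_seq(s1)), nchar(.as_seq(s2))), call = cl),
            class = "kcs_fit")
}

#' @export
print.kcs_fit <- function(x, ...) {
  cat(sprintf("k-mismatch common substring distance fit (k = %d, w = %d)\n",
              x$k, x$w))
  cat(sprintf("sequence lengths: %d, %d nt\n", x$L[1], x$L[2]))
  print(structure(x[c("status", "m_star", "p_hat", "d_hat", "peak",
                      "k", "w", "ratio", "x")], class = "distance_estimate"))
  invisible(x)
}

#' @export
#' @method summary kcs_fit
summary.kcs_fit <- function(object, ...) {
  x <- object
  cat("k-mismatch common substring distance fit\n")
  cat(sprintf("  call: %s\n", deparse(x$call)))
  cat(sprintf("  sequences: %d and %d nt; k = %d, w = %d, ratio = %g, x = %d\n",
              x$L[1], x$L[2], x$k, x$w, x$ratio, x$x))
  cat(sprintf("  extensions counted: %s (%s truncated at a sequence end)\n",
              format(x$spectrum$n_extensions, big.mark = ","),
              format(x$spectrum$n_truncated, big.mark = ",")))
  cat(sprintf("  background peak: m = %d, height %.4g (smoothed)\n",
              x$peak$global_max_pos, x$peak$global_max_val))
  if (x$status == "ok") {
    cat(sprintf("  homologous peak: m* = %d, height %.4g\n",
                x$m_star, x$peak$peak_val))
    cat(sprintf("  p-hat = %.4f  [bracket %.4f .. %.4f]\n", x$p_hat,
                (x$m_star - x$k) / x$m_star, x$p_hat))
    cat(sprintf("  d-hat = %.4f substitutions/site\n", x$d_hat))
  } else {
    cat(sprintf("  status: %s\n", x$status))
  }
  invisible(x)
}

#' @export
#' @method coef kcs_fit
coef.kcs_fit <- function(object, ...) {
  c(p_hat = object$p_hat, d_hat = object$d_hat)
}

#' @export
#' @method plot kcs_fit
plot.kcs_fit <- function(x, xlim = NULL, log = "", ...) {
  raw <- x$spectrum
  if (is.null(xlim)) {
    nz <- which(raw$count > 0)
    xlim <- c(raw$m[min(nz)], raw$m[max(nz)])
  }
  plot(raw$m, raw$count, type = "h", col = "grey70", xlim = xlim, log = log,
       xlab = "extension length m", ylab = "N(m)", ...)
  lines(x$smoothed$m, x$smoothed$count, col = "steelblue", lwd = 2)
  if (x$status != "no_peak")
    abline(v = x$m_star, col = "firebrick", lty = 2)
  legend("topright", c("raw", sprintf("smoothed (w = %d)", x$w),
                       if (x$status != "no_peak") "m*"),
         col = c("grey70", "steelblue", if (x$status != "no_peak") "firebrick"),
         lty = c(1, 1, if (x$status != "no_peak") 2), bty = "n")
  invisible(x)
}

#' Simulate sequence pairs from a fitted distance
#'
#' Draws new sequence pairs under the gap-free Jukes-Cantor model at the
#' fitted distance, with the same (first) sequence length.
#'
#' @param object a [kcs_fit()] with `status == "ok"`.
#' @param nsim number of pairs.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of [simulate_pair()] results (a single pair if `nsim = 1`).
#' @export
simulate.kcs_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$status != "ok")
    stop("cannot simulate from a fit without a distance estimate")
  out <- lapply(seq_len(nsim), function(i)
    simulate_pair(L = object$L[1], d = object$d_hat,
                  seed = if (is.null(seed)) NULL else seed + i - 1L))
  if (nsim == 1L) out[[1]] else out
}

#' Heuristic mismatch parameter for a given sequence length
#'
#' The operating point k = 90 was established for 500 kb sequences; no rule
#' for other lengths is established, so this heuristic scales k with the
#' logarithm of the length (k grows slowly: the peak separation is
#' proportional to k while peak widths grow like sqrt(k), but the number of
#' homologous extensions shrinks with shorter sequences).  Clearly labelled
#' a heuristic; inspect the spectrum plot when in doubt.
#'
#' @param L sequence length in nucleotides.
#' @return A list with suggested `k` and odd window width `w`.
#' @export
suggest_k <- function(L) {
  stopifnot(L >= 1)
  k <- max(10L, as.integer(round(90 * log(L) / log(5e5))))
  w <- as.integer(round(31 * sqrt(k / 90)))
  if (w %% 2 == 0) w <- w + 1L
  list(k = k, w = max(3L, w))
}

#' All-vs-all distance matrix
#'
#' Runs the full pipeline on every unordered pair of sequences.  Pairs for
#' which no second peak is found (or whose estimate is saturated) are
#' recorded as `NA` with an explicit status in the diagnostics table.
#'
#' @param seqs a `DNAStringSet`, a named character vector of sequences, or
#'   the path of a FASTA file.
#' @inheritParams kcs_fit
#' @return An object of class `"kcs_dist"`: list with `d` (symmetric matrix
#'   of distances, zero diagonal, `NA` for failed pairs), `diagnostics`
#'   (one row per pair: labels, `m_star`, `p_hat`, `d_hat`, `status`), and
#'   the run parameters.  Methods: `print`, `summary`, `as.matrix`,
#'   `as.dist`; write with [write_phylip()].
#' @export
kcs_dist <- function(seqs, k = 90, w = 31, ratio = 10, x = 4,
                     pool_directions = TRUE, mask_nonacgt = TRUE) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_fasta(seqs)
  if (inherits(seqs, "XStringSet")) {
    labels <- names(seqs)
    seqs <- as.character(seqs)
  } else if (is.list(seqs) || is.character(seqs)) {
    labels <- names(seqs)
    seqs <- vapply(seqs, .as_seq, character(1))
  } else stop("unsupported input for 'seqs'")
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  if (anyDuplicated(labels)) stop("duplicate sequence labels")
  d <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(d) <- 0
  rows <- vector("list", n * (n - 1) / 2)
  r <- 0L
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    fit <- kcs_fit(seqs[[i]], seqs[[j]], k = k, w = w, ratio = ratio, x = x,
                   pool_directions = pool_directions,
                   mask_nonacgt = mask_nonacgt)
    if (fit$status == "ok") d[i, j] <- d[j, i] <- fit$d_hat
    r <- r + 1L
    rows[[r]] <- data.frame(label1 = labels[i], label2 = labels[j],
                            m_star = fit$m_star, p_hat = fit$p_hat,
                            d_hat = fit$d_hat, status = fit$status,
                            stringsAsFactors = FALSE)
  }
  structure(list(d = d, diagnostics = do.call(rbind, rows), k = k, w = w,
                 ratio = ratio, x = x, pool_directions = pool_directions),
            class = "kcs_dist")
}

#' @export
print.kcs_dist <- function(x, ...) {
  n <- nrow(x$d)
  failed <- sum(x$diagnostics$status != "ok")
  cat(sprintf("k-mismatch common substring distances: %d sequences, %d pairs (k = %d, w = %d)\n",
              n, n * (n - 1) / 2, x$k, x$w))
  if (failed) cat(sprintf("%d pair(s) without a distance (see $diagnostics)\n", failed))
  print(round(x$d, 4))
  invisible(x)
}

#' @export
#' @method summary kcs_dist
summary.kcs_dist <- function(object, ...) {
  print(object)
  cat("\nper-pair diagnostics:\n")
  print(object$diagnostics, row.names = FALSE)
  invisible(object)
}

#' @export
#' @method as.matrix kcs_dist
as.matrix.kcs_dist <- function(x, ...) x$d

#' @export
as.dist.kcs_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}
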