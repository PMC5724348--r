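# Smoothing of the raw extension-length histogram and detection of the
# second (homologous) peak.

.spectrum_counts <- function(spec) {
  if (inherits(spec, "match_spectrum") || inherits(spec, "smoothed_spectrum"))
    return(list(m = spec$m, count = spec$count))
  if (is.data.frame(spec)) return(list(m = spec$m, count = spec$count))
  if (is.numeric(spec)) {
    m <- if (!is.null(names(spec))) as.integer(names(spec)) else seq_along(spec) - 1L
    return(list(m = m, count = as.numeric(spec)))
  }
  stop("unsupported spectrum representation")
}

#' Smooth a length spectrum with a centered moving average
#'
#' Replaces each count by the mean over a window of width `w` centered at it.
#' At the boundaries the window shrinks symmetrically to the available
#' support, so `w = 1` is the identity and a constant histogram is left
#' unchanged for any `w`.
#'
#' @param spec a [match_spectrum()], a data frame with columns `m` and
#'   `count`, or a numeric vector of counts.
#' @param w window width, an odd positive integer.
#' @return An object of class `"smoothed_spectrum"`: list with `m`, `count`
#'   (smoothed, real-valued), and `w`.
#' @export
smooth_spectrum <- function(spec, w) {
  stopifnot(length(w) == 1L, w >= 1, w == floor(w))
  if (w %% 2 == 0) stop("w must be odd (centered window)")
  sc <- .spectrum_counts(spec)
  v <- sc$count
  n <- length(v)
  half <- (w - 1) / 2
  idx <- seq_len(n)
  h <- pmin(half, idx - 1L, n - idx)
  cs <- c(0, cumsum(v))
  out <- (cs[idx + h + 1] - cs[idx - h]) / (2 * h + 1)
  structure(list(m = sc$m, count = out, w = as.integer(w),
                 k = if (is.list(spec)) spec$k %||% NA_integer_ else NA_integer_),
            class = "smoothed_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.smoothed_spectrum <- function(x, ...) {
  cat(sprintf("smoothed spectrum (w = %d), support %d..%d\n",
              x$w, min(x$m), max(x$m)))
  invisible(x)
}

# leftmost indices of local maxima (value >= both neighbours, strictly
# greater than at least one); plateaus contribute their leftmost index;
# boundary runs count when they exceed their single neighbour.
.local_maxima <- function(v) {
  r <- rle(v)
  nr <- length(r$values)
  if (nr == 1L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-nr]))
  left <- c(-Inf, r$values[-nr])    # adjacent rle values always differ,
  right <- c(r$values[-1L], -Inf)   # so ">" is the whole condition
  starts[r$values > left & r$values > right]
}

#' Locate the second (homologous) peak of a smoothed spectrum
#'
#' Scans the local maxima strictly to the right of the global maximum (the
#' background peak) and returns the highest one `m*` satisfying both side
#' constraints: (a) `N(m*) <= global_max / ratio`, so shoulders of the
#' background peak are excluded, and (b) `N(m*) > N(m* - x)`, so bumps on a
#' monotone tail are excluded.  Failure to find a qualifying peak is a valid
#' result (`found = FALSE`): for very distant sequences the homologous peak
#' is swallowed by the background peak and no distance can be estimated.
#'
#' @param s a smoothed (or raw) spectrum; see [smooth_spectrum()].
#' @param ratio required height ratio between the global maximum and the
#'   second peak.
#' @param x offset (in length units) for the rising-flank condition (b).
#' @return An object of class `"peak_call"`: list with `found`, `m_star`,
#'   `global_max_pos`, `global_max_val`, `peak_val`.
#' @export
find_second_peak <- function(s, ratio = 10, x = 4) {
  sc <- .spectrum_counts(s)
  v <- sc$count
  m <- sc$m
  if (!length(v)) stop("empty spectrum")
  g <- which.max(v)
  cand <- .local_maxima(v)
  cand <- cand[cand > g]
  if (length(cand)) {
    ok_ratio <- v[cand] <= v[g] / ratio
    prev <- cand - x                       # support is contiguous in m,
    ok_rise <- rep(FALSE, length(cand))    # so index offset == length offset
    sel <- prev >= 1
    ok_rise[sel] <- v[cand[sel]] > v[prev[sel]]
    cand <- cand[ok_ratio & ok_rise]
  }
  if (!length(cand)) {
    return(structure(list(found = FALSE, m_star = NA_integer_,
                          global_max_pos = m[g], global_max_val = v[g],
                          peak_val = NA_real_), class = "peak_call"))
  }
  best <- cand[which.max(v[cand])]
  structure(list(found = TRUE, m_star = as.integer(m[best]),
                 global_max_pos = m[g], global_max_val = v[g],
                 peak_val = v[best]), class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  if (x$found)
    cat(sprintf("second peak at m* = %d (height %.3g; global maximum %.3g at m = %d)\n",
                x$m_star, x$peak_val, x$global_max_val, x$global_max_pos))
  else
    cat(sprintf("no second peak found (global maximum %.3g at m = %d)\n",
                x$global_max_val, x$global_max_pos))
  invisible(x)
}
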