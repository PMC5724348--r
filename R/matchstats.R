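# Matching statistics and k-mismatch extensions over an enhanced suffix
# array.  The heavy lifting lives in src/esa.cpp; these wrappers normalize
# inputs and wrap results in small classed containers.

.as_seq <- function(x, arg = "sequence") {
  if (inherits(x, "XStringSet")) {
    if (length(x) != 1L) stop(arg, ": expected a single sequence")
    x <- as.character(x)
  }
  if (inherits(x, "XString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop(arg, " must be a single character string")
  if (nchar(x) < 1L) stop(arg, " must be non-empty")
  toupper(x)
}

#' Matching statistics of one sequence against another
#'
#' For every position `i` of the query sequence, the length `X_i` of the
#' longest substring starting at `i` that exactly matches a substring of the
#' other sequence anywhere, together with *all* start positions in the other
#' sequence achieving that length.  Computed over an enhanced suffix array of
#' the concatenation: from the rank of the query suffix, the scan proceeds
#' up and down until the first suffix of the other sequence, recording the
#' minimum LCP; the larger of the two minima is `X_i`, and the scan continues
#' while the running minimum stays at `X_i` to collect every partner.
#'
#' @param s1,s2 character strings (or length-1 `XStringSet`s).
#' @param query which sequence is the query: 1 or 2.
#' @param mask_nonacgt if `TRUE` (the default, for DNA), characters outside
#'   A/C/G/T never match anything, including themselves; if `FALSE`,
#'   arbitrary characters match literally.
#' @return A list with `x` (integer vector of `X_i` per query position) and
#'   `partners` (list of sorted 1-based start positions in the other
#'   sequence).
#' @examples
#' ms <- matching_stats("banana", "ananas", query = 2, mask_nonacgt = FALSE)
#' ms$x[3]          # 3: "ana" at position 3 of "ananas"
#' ms$partners[[3]] # both occurrences of "ana" in "banana"
#' @export
matching_stats <- function(s1, s2, query = 1, mask_nonacgt = TRUE) {
  s1 <- .as_seq(s1, "s1"); s2 <- .as_seq(s2, "s2")
  stopifnot(query %in% c(1, 2))
  cpp_matching_stats(s1, s2, query == 2, mask_nonacgt)
}

#' Length of the gap-free k-mismatch extension at a start-position pair
#'
#' The maximal length `l` such that the substrings of length `l` starting at
#' `i_start` (in `s1`) and `j_start` (in `s2`) contain exactly `k`
#' mismatches; the scan stops just before the (k+1)-st mismatch.  If a
#' sequence end is reached first, the observed length is returned and
#' flagged `truncated`; an out-of-bounds start yields length 0, truncated.
#'
#' @param s1,s2 character strings.
#' @param i_start,j_start 1-based start positions (one past the mismatch
#'   ending the preceding exact match).
#' @param k number of allowed mismatches.
#' @inheritParams matching_stats
#' @return A list with `length` and `truncated`.
#' @export
k_mismatch_extension <- function(s1, s2, i_start, j_start, k,
                                 mask_nonacgt = TRUE) {
  s1 <- .as_seq(s1, "s1"); s2 <- .as_seq(s2, "s2")
  stopifnot(k >= 0, k == floor(k))
  cpp_extension(s1, s2, as.integer(i_start) - 1L, as.integer(j_start) - 1L,
                as.integer(k), mask_nonacgt)
}

#' Spectrum of k-mismatch extension lengths for a sequence pair
#'
#' Runs the full heuristic: for every query position `i` and every partner
#' `j*` achieving the longest exact match `X_i`, the extension start pair
#' `(i', j') = (i + X_i + 1, j* + X_i + 1)` is formed; each *distinct*
#' `(i', j')` contributes one count at its k-mismatch extension length.
#' Without this deduplication, a long shared substring spawns one identical
#' extension per covered position and the histogram shows isolated spikes.
#' By default both directions (each sequence as query) are computed, each
#' deduplicated separately, and the histograms summed.
#'
#' @inheritParams matching_stats
#' @param k number of mismatches in the extension, `k >= 1`.
#' @param pool_directions sum the spectra of both query directions.
#' @param dedup count each distinct extension start pair once (the default;
#'   `FALSE` exists to demonstrate the artifact it prevents).
#' @return An object of class `"match_spectrum"`: a list with `m` (lengths,
#'   from 0), `count` (number of extensions per length `N(m)`), `k`,
#'   `n_extensions` (sum of counts), and `n_truncated` (extensions that hit
#'   a sequence end before the (k+1)-st mismatch; counted at their observed
#'   length).
#' @examples
#' pair <- simulate_pair(L = 2000, p = 0.7, seed = 1)
#' sp <- match_spectrum(pair$s1, pair$s2, k = 5)
#' sp
#' @export
match_spectrum <- function(s1, s2, k, pool_directions = TRUE,
                           mask_nonacgt = TRUE, dedup = TRUE) {
  s1 <- .as_seq(s1, "s1"); s2 <- .as_seq(s2, "s2")
  stopifnot(k >= 1, k == floor(k))
  res <- cpp_spectrum(s1, s2, as.integer(k), pool_directions, mask_nonacgt,
                      dedup)
  # the histogram support does not end at the largest observation: keep a
  # margin of empty bins so that smoothing windows stay full over the
  # observed range instead of shrinking onto tail noise
  res$counts <- c(res$counts, numeric(max(100L, k)))
  structure(list(m = seq_along(res$counts) - 1L, count = res$counts,
                 k = as.integer(k), n_extensions = res$n_extensions,
                 n_truncated = res$n_truncated, pooled = pool_directions),
            class = "match_spectrum")
}

#' @export
print.match_spectrum <- function(x, ...) {
  cat(sprintf("k-mismatch extension spectrum: k = %d, %s extensions (%s truncated)%s\n",
              x$k, format(x$n_extensions, big.mark = ","),
              format(x$n_truncated, big.mark = ","),
              if (isTRUE(x$pooled)) ", both directions pooled" else ""))
  nz <- which(x$count > 0)
  if (length(nz))
    cat(sprintf("lengths %d..%d, mode at m = %d\n",
                x$m[min(nz)], x$m[max(nz)], x$m[which.max(x$count)]))
  invisible(x)
}

#' @export
#' @method as.data.frame match_spectrum
as.data.frame.match_spectrum <- function(x, ...) {
  data.frame(m = x$m, count = x$count)
}

#' @export
#' @method plot match_spectrum
plot.match_spectrum <- function(x, ...) {
  plot(x$m, x$count, type = "h", xlab = "extension length m",
       ylab = "N(m)", ...)
  invisible(x)
}

# Per-position heuristic records (one query direction, one selected partner
# per position) used for Monte-Carlo validation of the closed-form laws.
# tie: which partner is selected when several attain X_i -- "background"
# matches the convention of the extension mixture weights, "homologous" the
# convention of the full-hit law.
.per_position <- function(s1, s2, k, mask_nonacgt = TRUE,
                          tie = c("background", "homologous")) {
  s1 <- .as_seq(s1, "s1"); s2 <- .as_seq(s2, "s2")
  tie <- match.arg(tie)
  cpp_per_position(s1, s2, as.integer(k), mask_nonacgt, tie == "homologous")
}
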