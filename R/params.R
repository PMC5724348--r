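#' Model parameters for the gap-free Jukes-Cantor pair model
#'
#' Bundles the parameters of the sequence-pair model: two equal-length DNA
#' sequences descended from a common ancestor without indels, so that
#' positions i of both sequences are homologous.  Homologous positions match
#' with probability `p`, all other position pairs with the background
#' probability `q` (0.25 under uniform base composition).
#'
#' @param p per-site match probability of homologous positions.
#' @param q background per-site match probability; defaults to 0.25
#'   (uniform base composition), estimable from observed base frequencies as
#'   `sum(f1 * f2)`.
#' @param L sequence length in nucleotides.
#' @param k number of mismatches allowed in an extension.
#' @return An object of class `"model_params"` (a named list).
#' @examples
#' model_params(p = 0.5, L = 5e5, k = 90)
#' @export
model_params <- function(p, q = 0.25, L, k) {
  stopifnot(is.numeric(p), length(p) == 1L, is.numeric(q), length(q) == 1L,
            is.numeric(L), length(L) == 1L, is.numeric(k), length(k) == 1L)
  if (!(q > 0 && q < p && p <= 1))
    stop("parameters must satisfy 0 < q < p <= 1")
  if (L < 1 || L != floor(L)) stop("L must be a positive integer")
  if (k < 0 || k >= L || k != floor(k)) stop("k must satisfy 0 <= k < L")
  structure(list(p = p, q = q, L = as.numeric(L), k = as.integer(k)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Gap-free Jukes-Cantor pair model: p = %g, q = %g, L = %g, k = %d\n",
              x$p, x$q, x$L, x$k))
  invisible(x)
}

#' Jukes-Cantor distance from a match probability
#'
#' Converts an (estimated) per-site match probability into the expected
#' number of substitutions per site, `d = -3/4 * log(1 - 4/3 * (1 - p))`.
#' Undefined at or below the saturation point p = 1/4.
#'
#' @param p_hat match probability, must exceed 0.25.
#' @return Distance in substitutions per site.
#' @examples
#' jukes_cantor_distance(0.5)   # 0.824
#' jukes_cantor_distance(0.6)   # 0.57
#' @seealso [jukes_cantor_match_prob()] for the inverse.
#' @export
jukes_cantor_distance <- function(p_hat) {
  stopifnot(is.numeric(p_hat))
  if (any(p_hat <= 0.25))
    stop("match probability <= 0.25: Jukes-Cantor distance is undefined (saturation)")
  if (any(p_hat > 1)) stop("p_hat must be a probability")
  -0.75 * log(1 - (4 / 3) * (1 - p_hat))
}

#' Match probability implied by a Jukes-Cantor distance
#'
#' Inverse of [jukes_cantor_distance()]:
#' `p = 1 - 3/4 * (1 - exp(-4/3 * d))`.
#'
#' @param d distance in substitutions per site, `d >= 0`.
#' @return Per-site match probability in (0.25, 1].
#' @examples
#' jukes_cantor_match_prob(0.824)  # ~0.5
#' @export
jukes_cantor_match_prob <- function(d) {
  stopifnot(is.numeric(d))
  if (any(d < 0)) stop("d must be non-negative")
  1 - 0.75 * (1 - exp(-(4 / 3) * d))
}
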