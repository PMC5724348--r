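# Sequence-pair simulator under the gap-free Jukes-Cantor model, and the
# replicate study driver.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a pair of sequences under the gap-free Jukes-Cantor model
#'
#' Draws an ancestral sequence with the given base composition; the first
#' descendant is the ancestor itself and the second is obtained by applying
#' the whole divergence to one lineage (equivalent under time reversibility):
#' each site is replaced, with probability `1 - p`, by one of the three
#' other bases chosen uniformly, so `P(s1[i] == s2[i]) = p` exactly.
#' Substitutions at different sites are independent.
#'
#' With `indel_rate > 0` an experimental indel mode additionally applies
#' insertions and deletions of geometrically distributed length to the
#' second sequence; the two sequences then differ in length and positional
#' homology is no longer `i == i`.  With the default `indel_rate = 0` the
#' model is exactly gap-free.
#'
#' @param L ancestral sequence length in nucleotides.
#' @param d true distance in substitutions per site (exactly one of `d`,
#'   `p` must be given).
#' @param p per-site match probability; implied by `d` via
#'   [jukes_cantor_match_prob()] when missing.
#' @param seed optional seed; the global RNG state is restored afterwards.
#' @param indel_rate per-site probability of starting an indel
#'   (experimental; default 0).
#' @param base_freqs ancestral base frequencies (A, C, G, T), default
#'   uniform.
#' @return An object of class `"sim_pair"`: list with `s1`, `s2` (character
#'   strings), `L`, `p`, `d`, `seed`.
#' @examples
#' pair <- simulate_pair(L = 1000, d = 0.2, seed = 42)
#' mean(strsplit(pair$s1, "")[[1]] == strsplit(pair$s2, "")[[1]])
#' @export
simulate_pair <- function(L, d = NULL, p = NULL, seed = NULL, indel_rate = 0,
                          base_freqs = rep(0.25, 4)) {
  stopifnot(L >= 1, L == floor(L))
  if (is.null(p) && is.null(d)) stop("supply d or p")
  if (!is.null(p) && !is.null(d)) stop("supply only one of d, p")
  if (is.null(p)) {
    stopifnot(d >= 0)
    p <- jukes_cantor_match_prob(d)
  } else {
    stopifnot(p > 0, p <= 1)
    d <- if (p > 0.25) jukes_cantor_distance(p) else Inf
  }
  stopifnot(length(base_freqs) == 4, all(base_freqs > 0))
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    anc <- sample.int(4L, L, replace = TRUE, prob = base_freqs)
    s2 <- anc
    mut <- which(runif(L) > p)
    if (length(mut)) {
      # replace by one of the three other bases, uniformly
      s2[mut] <- ((anc[mut] - 1L + sample.int(3L, length(mut), replace = TRUE)) %% 4L) + 1L
    }
    s1c <- bases[anc]
    s2c <- bases[s2]
    if (indel_rate > 0) {
      ev <- which(runif(L) < indel_rate)
      if (length(ev)) {
        lens <- rgeom(length(ev), 0.5) + 1L
        ins <- runif(length(ev)) < 0.5
        pieces <- character(0)
        last <- 1L
        for (t in seq_along(ev)) {
          pos <- ev[t]
          if (pos < last) next
          pieces <- c(pieces, s2c[last:pos])
          if (ins[t]) {
            pieces <- c(pieces, bases[sample.int(4L, lens[t], replace = TRUE,
                                                 prob = base_freqs)])
            last <- pos + 1L
          } else {
            last <- min(L + 1L, pos + lens[t] + 1L)
          }
        }
        if (last <= L) pieces <- c(pieces, s2c[last:L])
        s2c <- pieces
      }
    }
    structure(list(s1 = paste(s1c, collapse = ""),
                   s2 = paste(s2c, collapse = ""),
                   L = as.integer(L), p = p, d = d, seed = seed,
                   indel_rate = indel_rate),
              class = "sim_pair")
  })
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf("simulated pair: L = %d nt, p = %.4f (d = %.4f)%s\n",
              x$L, x$p, x$d,
              if (x$indel_rate > 0)
                sprintf(", indel_rate = %g [experimental]", x$indel_rate)
              else ""))
  invisible(x)
}

#' Replicate study of estimator accuracy over a distance grid
#'
#' For each true distance, simulates `n_replicates` independent sequence
#' pairs, runs the full pipeline on each, and summarizes the estimates.
#' A distance value is `reported` only when the pipeline succeeded for at
#' least a fraction `min_success` of its replicates (the homologous peak is
#' legitimately undetectable for very distant pairs).
#'
#' @param d_values vector of true distances (substitutions/site).
#' @param L sequence length per pair.
#' @param n_replicates pairs per distance value.
#' @param k,w,ratio,x pipeline parameters, see [kcs_fit()].
#' @param seed base seed; the replicate and grid indices are folded in so
#'   each pair is independently reproducible.
#' @param min_success minimal fraction of successful replicates for a row
#'   to be reported.
#' @return A data frame with one row per distance: `d_true`, `n_ok`,
#'   `n_failed`, `mean_d_hat`, `sd_d_hat`, `reported`.
#' @export
run_replicate_study <- function(d_values, L = 5e5, n_replicates = 100,
                                k = 90, w = 31, ratio = 10, x = 4,
                                seed = 1, min_success = 0.75) {
  rows <- lapply(seq_along(d_values), function(di) {
    d_true <- d_values[di]
    est <- vapply(seq_len(n_replicates), function(r) {
      pair <- simulate_pair(L = L, d = d_true,
                            seed = seed + 7919L * di + r)
      fit <- kcs_fit(pair, k = k, w = w, ratio = ratio, x = x)
      if (fit$status == "ok") fit$d_hat else NA_real_
    }, numeric(1))
    ok <- !is.na(est)
    data.frame(d_true = d_true, n_ok = sum(ok), n_failed = sum(!ok),
               mean_d_hat = if (any(ok)) mean(est[ok]) else NA_real_,
               sd_d_hat = if (sum(ok) > 1) sd(est[ok]) else NA_real_,
               reported = mean(ok) >= min_success)
  })
  do.call(rbind, rows)
}
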