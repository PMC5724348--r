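# Independent brute-force oracles and small generators used across tests.

rand_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                              collapse = "")

# quadratic-scan matching statistics: for every position of s1, the longest
# exact match anywhere in s2 and all start positions achieving it
naive_matching_stats <- function(s1, s2, mask = TRUE) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  acgt <- c("A", "C", "G", "T")
  ok1 <- a %in% acgt
  ok2 <- b %in% acgt
  n1 <- length(a); n2 <- length(b)
  x <- integer(n1)
  partners <- vector("list", n1)
  for (i in seq_len(n1)) {
    best <- 0L; pb <- integer(0)
    for (j in seq_len(n2)) {
      l <- 0L
      while (i + l <= n1 && j + l <= n2 && a[i + l] == b[j + l] &&
             (!mask || (ok1[i + l] && ok2[j + l])))
        l <- l + 1L
      if (l > best) { best <- l; pb <- j }
      else if (l == best && l > 0L) pb <- c(pb, j)
    }
    x[i] <- best
    partners[[i]] <- pb
  }
  list(x = x, partners = partners)
}

# direct scan of the k-mismatch extension length at a start pair (1-based)
naive_extension <- function(s1, s2, i, j, k) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  if (i < 1 || j < 1 || i > length(a) || j > length(b))
    return(list(length = 0L, truncated = TRUE))
  mism <- 0L; l <- 0L
  while (i + l <= length(a) && j + l <= length(b)) {
    if (a[i + l] != b[j + l]) {
      if (mism == k) return(list(length = l, truncated = FALSE))
      mism <- mism + 1L
    }
    l <- l + 1L
  }
  list(length = l, truncated = TRUE)
}

# per-bin Monte-Carlo comparison: freq_by_rep is a replicates x bins matrix
# of per-replicate frequencies; checks the mean against the theory per bin
# at the 3-SE level.  Under the null ~0.3% of bins land beyond 3 SE by
# chance, so across the dozens of bins compared one isolated excursion in
# (3, 4] SE is tolerated family-wise; any bin beyond 4 SE, or two beyond
# 3 SE, fails.
expect_within_3se <- function(freq_by_rep, theory, info = "") {
  mu <- colMeans(freq_by_rep)
  se <- apply(freq_by_rep, 2, sd) / sqrt(nrow(freq_by_rep))
  z <- abs(mu - theory) / se
  expect_true(sum(z > 3) <= 1 && all(z <= 4),
              info = paste0(info, " bins off (|z|>3): ",
                            paste(which(z > 3), collapse = ","),
                            " max z = ", round(max(z), 2)))
}
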