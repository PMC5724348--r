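# FASTA input, PHYLIP distance-matrix output, TSV spectra.

#' Read a (possibly gzipped) FASTA file of DNA sequences
#'
#' Thin wrapper around `Biostrings::readDNAStringSet`: sequences are
#' uppercased, labels are truncated at the first whitespace, duplicate
#' labels and empty files are errors.
#'
#' @param path path to a FASTA file (gzip transparent).
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("malformed FASTA '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence labels in ", path)
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write a distance matrix in square PHYLIP format
#'
#' Writes the matrix with relaxed labels (labels longer than the strict
#' 10-character PHYLIP limit are kept as-is, separated from the values by
#' whitespace).  Failed pairs are written as the token `NA`, which standard
#' PHYLIP programs do not accept; use `drop_failed = TRUE` to instead remove
#' every taxon involved in a failed pair.
#'
#' @param x a [kcs_dist()] object or a symmetric numeric matrix with
#'   dimnames.
#' @param path output file path.
#' @param digits number of decimals (fixed notation).
#' @param drop_failed drop taxa with any `NA` distance instead of writing
#'   `NA` tokens.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(x, path, digits = 6, drop_failed = FALSE) {
  m <- if (inherits(x, "kcs_dist")) x$d else as.matrix(x)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  if (drop_failed) {
    keep <- !apply(is.na(m), 1, any)
    m <- m[keep, keep, drop = FALSE]
    if (nrow(m) < 2L) stop("fewer than two taxa left after dropping failed pairs")
  } else if (anyNA(m)) {
    warning("matrix contains NA distances; output is not strict PHYLIP")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  lab <- rownames(m)
  for (i in seq_len(nrow(m))) {
    vals <- ifelse(is.na(m[i, ]), "NA", sprintf("%.*f", digits, m[i, ]))
    writeLines(paste(c(lab[i], vals), collapse = "  "), con)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' Counterpart of [write_phylip()] for relaxed single-line rows; `NA`
#' tokens are read as missing values.
#'
#' @param path input file path.
#' @return A numeric matrix with dimnames.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1L) stop("malformed PHYLIP file: ", path)
  lab <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(tok) != n + 1L)
      stop("malformed PHYLIP row ", i, " in ", path)
    lab[i] <- tok[1]
    m[i, ] <- suppressWarnings(as.numeric(tok[-1]))
  }
  dimnames(m) <- list(lab, lab)
  m
}

#' Write or read a raw/smoothed spectrum as TSV
#'
#' Two columns `m` and `count`, preceded by `#` comment lines recording the
#' package version and run parameters for provenance.
#'
#' @param spec a [match_spectrum()] or [smooth_spectrum()] result.
#' @param path file path.
#' @param config optional named list echoed into the header.
#' @return `path` (write) or a data frame with columns `m`, `count` (read).
#' @export
write_spectrum_tsv <- function(spec, path, config = NULL) {
  sc <- .spectrum_counts(spec)
  hdr <- sprintf("# kmatchdist %s spectrum",
                 as.character(packageVersion("kmatchdist")))
  info <- c(if (inherits(spec, "match_spectrum"))
              sprintf("# k=%d pooled=%s n_extensions=%g", spec$k,
                      isTRUE(spec$pooled), spec$n_extensions),
            if (inherits(spec, "smoothed_spectrum"))
              sprintf("# w=%d", spec$w),
            if (!is.null(config))
              paste0("# ", paste(names(config), unlist(config), sep = "=",
                                 collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, info), con)
  write.table(data.frame(m = sc$m, count = sc$count), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}
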