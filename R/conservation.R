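#' Read a multiple protein alignment from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a plain
#' character matrix (rows = sequences, columns = alignment positions),
#' which is the representation the rate estimator works on.
#'
#' @param path FASTA file with aligned (equal-length, possibly gapped)
#'   protein sequences.
#' @return Character matrix with one row per record, rownames = record ids.
#' @export
read_alignment_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  alignment_matrix(as.character(seqs))
}

# character vector of aligned sequences -> residue matrix, with validation
alignment_matrix <- function(seqs) {
  if (length(seqs) < 2L) {
    stop("alignment must contain at least 2 sequences", call. = FALSE)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequences have unequal aligned lengths",
         call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Estimate raw per-site evolutionary rates from a multiple alignment
#'
#' A simplified stand-in for phylogenetic rate estimation: the raw rate of a
#' column is `1 - f_max`, where `f_max` is the (optionally Henikoff
#' position-weighted) frequency of the most common residue among non-gap
#' characters. Invariant columns get rate 0; more diverse columns get
#' strictly larger rates. Columns where the reference sequence is gapped are
#' skipped, so the result has one rate per reference residue. Externally
#' computed rates (e.g. Rate4Site output) can be substituted via
#' [read_rate_table()].
#'
#' @param alignment Character matrix from [read_alignment_fasta()], or a
#'   character vector of aligned sequences.
#' @param reference Row index of the reference sequence (default 1).
#' @param henikoff Use Henikoff position-based sequence weights.
#' @return Numeric vector of raw nonnegative rates, one per ungapped
#'   reference position.
#' @export
estimate_site_rates <- function(alignment, reference = 1L, henikoff = FALSE) {
  if (!is.matrix(alignment)) alignment <- alignment_matrix(alignment)
  n_seq <- nrow(alignment)
  if (reference < 1L || reference > n_seq) {
    stop("reference index out of range", call. = FALSE)
  }
  gap <- alignment %in% c("-", ".")
  dim(gap) <- dim(alignment)
  ref_cols <- which(!gap[reference, ])
  w <- if (henikoff) henikoff_weights(alignment) else rep(1, n_seq)
  vapply(ref_cols, function(j) {
    col <- alignment[, j]
    ok <- !gap[, j]
    if (!any(ok)) return(0)
    freq <- tapply(w[ok], col[ok], sum)
    1 - max(freq) / sum(freq)
  }, numeric(1))
}

# Henikoff & Henikoff position-based sequence weights, gaps treated as a
# residue type; weights normalized to mean 1
henikoff_weights <- function(alignment) {
  n_seq <- nrow(alignment)
  w <- numeric(n_seq)
  for (j in seq_len(ncol(alignment))) {
    col <- alignment[, j]
    counts <- table(col)
    r <- length(counts)
    w <- w + 1 / (r * as.numeric(counts[col]))
  }
  w / mean(w)
}

#' Normalize raw site rates to a conservation profile
#'
#' Z-scores the raw rates to mean 0 and sample (n-1) standard deviation 1,
#' the usual convention for relative evolutionary rates. Lower values mean
#' more conserved sites. Normalization is strictly monotone, so site
#' ordering is preserved.
#'
#' @param raw Numeric vector of per-site rates, length >= 2.
#' @param protein_id Optional identifier stored on the profile.
#' @return Object of class `conservation_profile`: list with `protein_id`
#'   and `rates` (named by 1-based reference position).
#' @export
normalize_rates <- function(raw, protein_id = NA_character_) {
  raw <- as.numeric(raw)
  if (length(raw) < 2L) {
    stop("need at least 2 sites to normalize", call. = FALSE)
  }
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) {
    stop("degenerate variance: all site rates identical", call. = FALSE)
  }
  rates <- (raw - mean(raw)) / s
  names(rates) <- seq_along(rates)
  structure(list(protein_id = protein_id, rates = rates),
            class = "conservation_profile")
}

#' Conservation profile straight from an alignment
#'
#' Convenience composition of [estimate_site_rates()] and
#' [normalize_rates()].
#'
#' @inheritParams estimate_site_rates
#' @param protein_id Identifier stored on the profile.
#' @return A `conservation_profile`.
#' @export
conservation_profile <- function(alignment, reference = 1L,
                                 henikoff = FALSE,
                                 protein_id = NA_character_) {
  normalize_rates(estimate_site_rates(alignment, reference, henikoff),
                  protein_id = protein_id)
}

#' Read externally computed site rates
#'
#' Two-column `position,rate` text format (CSV or whitespace separated,
#' optional header) for dropping in rates from an external estimator such
#' as Rate4Site.
#'
#' @param path Text file path.
#' @return Numeric vector of raw rates ordered by position.
#' @export
read_rate_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  d <- utils::read.table(path, sep = sep, header = header,
                         col.names = c("position", "rate"))
  d <- d[order(d$position), ]
  stats::setNames(d$rate, d$position)
}
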