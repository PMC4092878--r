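#' Optimal global alignment between two protein sequences
#'
#' Needleman-Wunsch global-global alignment (end gaps penalized, as in the
#' FASTA suite's ggsearch) used to reconcile coordinate frames, e.g. a PDB
#' chain's observed sequence against the canonical UniProt sequence. Backed
#' by [Biostrings::pairwiseAlignment()]; a gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param seq_a,seq_b Non-empty protein sequences over the 20-letter
#'   alphabet; `X` is tolerated and scored by the matrix's X column.
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive penalties (default 10 and 1).
#' @return Object of class `alignment_map`: list with `pairs` (two-column
#'   integer matrix of 1-based matched positions, strictly increasing in
#'   both columns), `score`, and the input lengths.
#' @export
align_global <- function(seq_a, seq_b, matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 1) {
  check_protein(seq_a, "seq_a")
  check_protein(seq_b, "seq_b")
  data(list = matrix, package = "Biostrings", envir = environment())
  submat <- get(matrix, envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  a_aln <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b_aln <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- cumsum(a_aln != "-")
  ib <- cumsum(b_aln != "-")
  matched <- a_aln != "-" & b_aln != "-"
  pairs <- cbind(a = ia[matched], b = ib[matched])
  structure(
    list(pairs = pairs, score = Biostrings::score(pa),
         len_a = nchar(seq_a), len_b = nchar(seq_b)),
    class = "alignment_map"
  )
}

check_protein <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop(what, " must be a non-empty protein sequence", call. = FALSE)
  }
  bad <- setdiff(strsplit(toupper(seq), "")[[1]],
                 c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"))
  if (length(bad)) {
    stop(what, " contains illegal residue code(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Map a position through an alignment map
#'
#' @param map An `alignment_map` from [align_global()].
#' @param pos 1-based position(s) in sequence A.
#' @return Integer vector: the paired position in sequence B, or `NA`
#'   (absent marker) where the position aligns to a gap. Positions outside
#'   `[1, length(A)]` raise a range error.
#' @export
map_position <- function(map, pos) {
  if (!inherits(map, "alignment_map")) {
    stop("map must be an alignment_map", call. = FALSE)
  }
  pos <- as.integer(pos)
  if (any(pos < 1L) || any(pos > map$len_a)) {
    stop("position out of range of sequence A", call. = FALSE)
  }
  idx <- match(pos, map$pairs[, "a"])
  as.integer(map$pairs[idx, "b"])
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("alignment_map: %d matched pairs, score %.1f (A len %d, B len %d)\n",
              nrow(x$pairs), x$score, x$len_a, x$len_b))
  invisible(x)
}
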