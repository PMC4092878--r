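# Independent oracles used across the suite. These deliberately use naive
# O(n^2) / exhaustive formulations so they stay independent of the package
# implementations they check.

# pairwise Mann-Whitney AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Kendall tau-b by explicit pair enumeration
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tie_x <- tie_x + 1
      else if (dy == 0) tie_y <- tie_y + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) / sqrt((conc + disc + tie_x) * (conc + disc + tie_y))
}

# brute-force centroid neighbour map (all-pairs distances)
oracle_neighbors <- function(model, radius = 8.0) {
  cm <- pgxvar::centroid_matrix(model)
  ids <- rownames(cm)
  d <- as.matrix(dist(cm))
  out <- lapply(seq_along(ids), function(i) {
    ids[d[i, ] <= radius & seq_along(ids) != i]
  })
  names(out) <- ids
  out
}

# exhaustive global alignment score: enumerate every alignment of a and b,
# scoring with a substitution matrix and affine gaps (a run of length L
# costs gap_open + L * gap_extend, end gaps included)
oracle_global_score <- function(a, b, submat, gap_open = 10,
                                gap_extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- -Inf
  # state: 0 none, 1 gap in b (consumed a), 2 gap in a (consumed b)
  rec <- function(i, j, score, state) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      rec(i + 1, j + 1, score + submat[a[i], b[j]], 0L)
    }
    if (i <= length(a)) {
      open <- if (state == 1L) 0 else gap_open
      rec(i + 1, j, score - open - gap_extend, 1L)
    }
    if (j <= length(b)) {
      open <- if (state == 2L) 0 else gap_open
      rec(i, j + 1, score - open - gap_extend, 2L)
    }
  }
  rec(1L, 1L, 0, 0L)
  best
}

blosum62 <- local({
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# a bare structure_model with one CB atom per residue at given coordinates
make_point_model <- function(coords) {
  n <- nrow(coords)
  atoms <- data.frame(
    res_id = as.character(seq_len(n)), res_seq = seq_len(n), ins = " ",
    res_name = "ALA", aa = "A", atom = "CB", element = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3], occupancy = 1,
    stringsAsFactors = FALSE
  )
  structure(list(chain = "A", residues = atoms),
            class = c("structure_model"))
}

# correctly column-aligned classic DSSP text
make_dssp_text <- function(res_seq, aa, ss8, acc, chain = "A",
                           breaks = integer(0)) {
  # columns: 6-10 resSeq, 12 chain, 14 AA, 17 SS, 35-38 ACC
  line <- function(num, rs, a, s, ac) {
    sprintf("%5d%5d %s %s  %s%s%4d", num, rs, chain, a, s,
            strrep(" ", 17), ac)
  }
  rows <- character(0)
  num <- 0
  for (i in seq_along(res_seq)) {
    num <- num + 1
    if (i %in% breaks) {
      rows <- c(rows, sprintf("%5d        !%s", num, strrep(" ", 27)))
      num <- num + 1
    }
    rows <- c(rows, line(num, res_seq[i], aa[i], ss8[i], acc[i]))
  }
  c("==== Secondary Structure Definition (toy) ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O",
    rows)
}
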