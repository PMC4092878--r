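# Synthetic-data generator ------------------------------------------------
#
# Emulates the statistical structure of the curated variant sets (class-
# conditional feature distributions, ~5:1 class imbalance, class-specific
# MAF missingness, monotone pathogenicity-score gradients) plus toy
# structures and alignments with known ground truth, so the full pipeline
# is testable without any external download.

#' Specification of one synthetic variant class
#'
#' @param label `"neutral"`, `"disease"` or `"pgx"`.
#' @param n Number of variants (>= 1).
#' @param feature_params Named list of per-feature parameter lists; each
#'   element has a `mean` plus family-specific spread/shape entries
#'   (`sd` for Gaussian, `shape` for gamma).
#' @param maf_observed_frac Fraction of variants with non-missing MAF.
#' @param maf_mean Mean minor allele frequency of observed variants, in
#'   `[0, 0.5]`.
#' @param score_params Named list of `mean`/`precision` for the beta-
#'   distributed predictor scores (`sift`, `polyphen2`, `mutpred`).
#' @return A `class_spec` object.
#' @export
class_spec <- function(label, n, feature_params = list(),
                       maf_observed_frac = NA_real_, maf_mean = NA_real_,
                       score_params = list()) {
  if (!label %in% c("neutral", "disease", "pgx")) {
    stop("label must be neutral, disease or pgx", call. = FALSE)
  }
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.na(maf_observed_frac) &&
      (maf_observed_frac < 0 || maf_observed_frac > 1)) {
    stop("maf_observed_frac must be in [0, 1]", call. = FALSE)
  }
  if (!is.na(maf_mean) && (maf_mean < 0 || maf_mean > 0.5)) {
    stop("maf_mean must be in [0, 0.5]", call. = FALSE)
  }
  structure(list(label = label, n = as.integer(n),
                 feature_params = feature_params,
                 maf_observed_frac = maf_observed_frac,
                 maf_mean = maf_mean, score_params = score_params),
            class = "class_spec")
}

#' Default class specifications calibrated to the curated variant sets
#'
#' The stated world of the generator. Class sizes and per-class feature
#' means reproduce the reported composition of the curated data:
#' structure set 174 disease / 55 PGx / 187 neutral with class means
#' Conservation -0.474/0.000/0.209, ConsNG -0.316/-0.152/-0.021,
#' NNG 10.0/9.4/8.3, ACC 30.4/42.0/52.8 (disease/PGx/neutral); sequence
#' set 652/126/487 with Conservation -0.323/0.145/0.340. Conservation
#' spreads follow the reported dispersion ordering (disease narrowest:
#' sd 0.3/0.5/0.6). MAF: observed fractions 0.04/0.74/0.57 with means
#' 0.004/0.139/0.061. Predictor-score gradients are monotone
#' (disease most pathogenic, neutral least, PGx intermediate).
#'
#' @param schema `"structure"` or `"sequence"`.
#' @return List of three `class_spec` objects (disease, pgx, neutral).
#' @export
default_class_specs <- function(schema = c("structure", "sequence")) {
  schema <- match.arg(schema)
  sds <- c(disease = 0.3, pgx = 0.5, neutral = 0.6)
  cons <- if (schema == "structure") {
    c(disease = -0.474, pgx = 0.000, neutral = 0.209)
  } else {
    c(disease = -0.323, pgx = 0.145, neutral = 0.340)
  }
  n <- if (schema == "structure") {
    c(disease = 174L, pgx = 55L, neutral = 187L)
  } else {
    c(disease = 652L, pgx = 126L, neutral = 487L)
  }
  consng <- c(disease = -0.316, pgx = -0.152, neutral = -0.021)
  nng <- c(disease = 10.0, pgx = 9.4, neutral = 8.3)
  acc <- c(disease = 30.4, pgx = 42.0, neutral = 52.8)
  maf_frac <- c(disease = 0.04, pgx = 0.74, neutral = 0.57)
  maf_mean <- c(disease = 0.004, pgx = 0.139, neutral = 0.061)
  # beta means chosen once for the stated monotone pathogenicity gradient;
  # SIFT is tolerance-oriented (lower = more pathogenic)
  score_mean <- list(
    sift = c(disease = 0.10, pgx = 0.35, neutral = 0.42),
    polyphen2 = c(disease = 0.72, pgx = 0.50, neutral = 0.44),
    mutpred = c(disease = 0.80, pgx = 0.48, neutral = 0.38)
  )
  lapply(c("disease", "pgx", "neutral"), function(cl) {
    fp <- list(conservation = list(mean = cons[[cl]], sd = sds[[cl]]))
    if (schema == "structure") {
      fp$consng <- list(mean = consng[[cl]], sd = sds[[cl]])
      fp$nng <- list(mean = nng[[cl]])
      fp$acc <- list(mean = acc[[cl]], shape = 2)
    }
    class_spec(
      label = cl, n = n[[cl]], feature_params = fp,
      maf_observed_frac = maf_frac[[cl]], maf_mean = maf_mean[[cl]],
      score_params = lapply(score_mean, function(m)
        list(mean = m[[cl]], precision = 4))
    )
  })
}

check_specs <- function(specs) {
  if (!length(specs)) stop("specs must be non-empty", call. = FALSE)
  labs <- vapply(specs, function(s) s$label, character(1))
  if (anyDuplicated(labs)) {
    stop("duplicate class labels in specs", call. = FALSE)
  }
  invisible(labs)
}

#' Generate a synthetic variant feature table
#'
#' Draws class-conditional features: Gaussian for conservation and
#' neighbour conservation, Poisson for neighbour count, gamma for
#' accessibility, plus class-independent filler columns (secondary
#' structure, predicted B-value, stability, substitution deltas computed
#' from randomly drawn ref/alt residues).
#'
#' @param specs List of [class_spec()] objects (no duplicate labels).
#' @param schema `"structure"` (14 columns) or `"sequence"` (8 columns).
#' @param seed Integer random seed; identical (specs, schema, seed) give
#'   identical tables.
#' @return A `synthetic_bundle`: list with `feature_table` (data.frame in
#'   the canonical schema), `truth` (the generating class specifications),
#'   `schema` and `seed`.
#' @export
gen_feature_table <- function(specs = default_class_specs(schema),
                              schema = c("structure", "sequence"),
                              seed = 1L) {
  schema <- match.arg(schema)
  check_specs(specs)
  tab <- with_seed(seed, {
    do.call(rbind, lapply(specs, function(sp) gen_class_rows(sp, schema)))
  })
  rownames(tab) <- NULL
  structure(list(feature_table = tab, truth = specs, schema = schema,
                 seed = as.integer(seed)),
            class = "synthetic_bundle")
}

gen_class_rows <- function(sp, schema) {
  n <- sp$n
  fp <- sp$feature_params
  gauss <- function(p, fallback_mean = 0, fallback_sd = 1) {
    if (is.null(p)) p <- list(mean = fallback_mean, sd = fallback_sd)
    stats::rnorm(n, p$mean, if (is.null(p$sd)) fallback_sd else p$sd)
  }
  ref <- sample(names(RESIDUE_MASS), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(names(RESIDUE_MASS), r), 1L), character(1))
  deltas <- mapply(function(r, a) unlist(substitution_delta(r, a)), ref, alt)
  base <- data.frame(
    protein_id = sprintf("SYN%04d", sample.int(64L, n, replace = TRUE)),
    position = sample.int(500L, n, replace = TRUE),
    ref = ref, alt = alt,
    label = rep(sp$label, n),
    conservation = gauss(fp$conservation),
    stringsAsFactors = FALSE
  )
  if (schema == "structure") {
    accp <- if (is.null(fp$acc)) list(mean = 40, shape = 2) else fp$acc
    shape <- if (is.null(accp$shape)) 2 else accp$shape
    nng_mean <- if (is.null(fp$nng)) 9 else fp$nng$mean
    base$consng <- gauss(fp$consng)
    base$nng <- stats::rpois(n, nng_mean)
    base$acc <- stats::rgamma(n, shape = shape, scale = accp$mean / shape)
    base$ss <- sample(c("helix", "strand", "coil"), n, replace = TRUE,
                      prob = c(0.35, 0.2, 0.45))
    base$bvalue <- stats::rnorm(n, 0, 1)
    base$stability <- stats::rnorm(n, -0.5, 1)
    base$d_hydro <- deltas["d_hydro", ]
    base$d_mw <- deltas["d_mw", ]
    base[, structure_schema_cols()]
  } else {
    data.frame(
      variant_id = paste0(base$protein_id, "_", base$ref,
                          base$position, base$alt),
      label = base$label,
      conservation = base$conservation,
      bvalue = stats::rnorm(n, 0, 1),
      stability = stats::rnorm(n, -0.5, 1),
      d_hydro = deltas["d_hydro", ],
      d_mw = deltas["d_mw", ],
      extra_feature = stats::rnorm(n, 0, 1),
      stringsAsFactors = FALSE
    )
  }
}

#' Generate MAF and predictor-score columns with class-specific missingness
#'
#' MAF is drawn from an exponential truncated to `[0, 0.5]` whose mean
#' matches `maf_mean`, observed with probability `maf_observed_frac`
#' (missing otherwise). SIFT/PolyPhen2/MutPred scores are beta-distributed
#' with the class specification's means; SIFT is oriented lower = more
#' pathogenic,
#' the other two higher = more pathogenic.
#'
#' @param specs List of [class_spec()] objects.
#' @param seed Integer seed.
#' @return data.frame with columns `variant_id`, `label`, `maf`, `sift`,
#'   `polyphen2`, `mutpred` (NA marks missing values).
#' @export
gen_score_columns <- function(specs = default_class_specs("sequence"),
                              seed = 1L) {
  check_specs(specs)
  out <- with_seed(seed, do.call(rbind, lapply(specs, function(sp) {
    n <- sp$n
    observed <- stats::runif(n) < sp$maf_observed_frac
    maf <- ifelse(observed, rtrunc_exp(n, sp$maf_mean, 0.5), NA_real_)
    d <- data.frame(
      variant_id = sprintf("%s_%05d", sp$label, seq_len(n)),
      label = rep(sp$label, n),
      maf = maf,
      stringsAsFactors = FALSE
    )
    for (tool in c("sift", "polyphen2", "mutpred")) {
      p <- sp$score_params[[tool]]
      if (is.null(p)) p <- list(mean = 0.5, precision = 4)
      d[[tool]] <- stats::rbeta(n, p$mean * p$precision,
                                (1 - p$mean) * p$precision)
    }
    d
  })))
  rownames(out) <- NULL
  out
}

# exponential truncated to [0, upper] with target mean m (rate solved
# numerically; for m << upper the truncation is negligible)
rtrunc_exp <- function(n, m, upper = 0.5) {
  if (m <= 0) return(rep(0, n))
  trunc_mean <- function(rate) {
    1 / rate - upper * exp(-rate * upper) / (1 - exp(-rate * upper))
  }
  rate <- stats::uniroot(function(r) trunc_mean(r) - m,
                         lower = 1e-6, upper = 1e4, tol = 1e-10)$root
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-rate * upper))) / rate
}

#' Generate a toy protein structure with known neighbour ground truth
#'
#' Places side-chain centroids so that exactly the requested residue pairs
#' are within 8 angstroms of each other (contact distance 6, all other
#' pairs > 8). Contact components are laid out along well-separated lines,
#' which supports chains of consecutive contacts; if the requested pairs
#' cannot be realized this way a placement error is raised after an
#' explicit all-pairs verification. The last residue is a glycine (its CA
#' is the centroid); the rest are alanines with the CB at the planted
#' centroid.
#'
#' @param n_residues Number of residues (>= 2).
#' @param contact_pairs List of 1-based index pairs that must be
#'   neighbours.
#' @param seed Integer seed (controls a small coordinate jitter).
#' @return List with `model` (a `structure_model`) and `neighbors`
#'   (named list: ground-truth neighbour residue numbers per residue).
#' @export
gen_structure <- function(n_residues, contact_pairs = list(), seed = 1L) {
  if (n_residues < 2) stop("n_residues must be >= 2", call. = FALSE)
  for (p in contact_pairs) {
    if (length(p) != 2 || any(p < 1) || any(p > n_residues) || p[1] == p[2]) {
      stop("invalid contact pair", call. = FALSE)
    }
  }
  adj <- lapply(seq_len(n_residues), function(i) integer(0))
  for (p in contact_pairs) {
    adj[[p[1]]] <- c(adj[[p[1]]], p[2])
    adj[[p[2]]] <- c(adj[[p[2]]], p[1])
  }
  # lay out each contact component along its own line, 6 A between
  # consecutive contacts; components 100 A apart
  centers <- matrix(NA_real_, n_residues, 3)
  comp <- integer(n_residues)
  cid <- 0L
  for (s in seq_len(n_residues)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    offset <- 0
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      centers[v, ] <- c(offset * 6, cid * 100, 0)
      for (u in adj[[v]]) {
        if (!comp[u]) {
          comp[u] <- cid
          offset <- offset + 1
          queue <- c(queue, u)
        }
      }
    }
  }
  centers <- with_seed(seed, centers + matrix(stats::runif(n_residues * 3,
                                                           -0.2, 0.2),
                                              n_residues, 3))
  # verify the requested geometry against an all-pairs distance check
  dmat <- as.matrix(stats::dist(centers))
  want <- matrix(FALSE, n_residues, n_residues)
  for (p in contact_pairs) want[p[1], p[2]] <- want[p[2], p[1]] <- TRUE
  got <- dmat <= 8 & upper.tri(dmat) | dmat <= 8 & lower.tri(dmat)
  diag(got) <- FALSE
  if (!identical(unname(got), unname(want))) {
    stop("placement error: requested contact pairs are geometrically ",
         "infeasible with the line layout", call. = FALSE)
  }
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    gly <- i == n_residues
    res_name <- if (gly) "GLY" else "ALA"
    ctr <- centers[i, ]
    # backbone placed 2-3 A off the centroid; for glycine CA sits on it
    ca <- if (gly) ctr else ctr + c(-1.5, 0.8, 0.4)
    rows <- data.frame(
      res_id = as.character(i), res_seq = i, ins = " ",
      res_name = res_name, aa = if (gly) "G" else "A",
      atom = c("N", "CA", "C", "O", if (!gly) "CB"),
      element = c("N", "C", "C", "O", if (!gly) "C"),
      x = c(ca[1] - 1.3, ca[1], ca[1] + 1.4, ca[1] + 1.9,
            if (!gly) ctr[1]),
      y = c(ca[2] + 0.4, ca[2], ca[2] - 0.6, ca[2] + 0.5,
            if (!gly) ctr[2]),
      z = c(ca[3], ca[3], ca[3], ca[3] - 1.0, if (!gly) ctr[3]),
      occupancy = 1,
      stringsAsFactors = FALSE
    )
    rows
  }))
  rownames(atoms) <- NULL
  model <- structure(list(chain = "A", residues = atoms),
                     class = "structure_model")
  truth <- lapply(seq_len(n_residues), function(i) sort(unique(adj[[i]])))
  names(truth) <- as.character(seq_len(n_residues))
  list(model = model, neighbors = truth)
}

#' Generate a toy multiple protein alignment with planted conserved sites
#'
#' The first record is the gap-free reference. Non-conserved columns
#' mutate independently per species with probability `subst_prob`;
#' conserved columns are invariant.
#'
#' @param n_species Number of sequences (>= 2).
#' @param length Alignment length.
#' @param conserved_sites 1-based positions kept invariant.
#' @param subst_prob Per-site substitution probability for the other
#'   columns (default 0.5).
#' @param seed Integer seed.
#' @return Character matrix as from [read_alignment_fasta()]; write with
#'   [write_alignment_fasta()].
#' @export
gen_alignment <- function(n_species, length, conserved_sites = integer(0),
                          subst_prob = 0.5, seed = 1L) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  if (any(conserved_sites < 1) || any(conserved_sites > length)) {
    stop("conserved_sites out of range", call. = FALSE)
  }
  aas <- names(RESIDUE_MASS)
  with_seed(seed, {
    ref <- sample(aas, length, replace = TRUE)
    m <- matrix(rep(ref, each = n_species), n_species, length)
    free <- setdiff(seq_len(length), conserved_sites)
    for (j in free) {
      mutate <- c(FALSE, stats::runif(n_species - 1) < subst_prob)
      if (any(mutate)) {
        m[mutate, j] <- sample(setdiff(aas, ref[j]), sum(mutate),
                               replace = TRUE)
      }
    }
    rownames(m) <- c("reference", sprintf("species%02d",
                                          seq_len(n_species - 1)))
    m
  })
}

#' Write an alignment matrix as FASTA
#' @param alignment Character matrix (rows = records).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  seqs <- apply(alignment, 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

# run code under a temporary RNG state so generators are deterministic in
# (args, seed) and do not clobber the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
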