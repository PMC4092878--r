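# Amino-acid constant tables --------------------------------------------

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- stats::setNames(names(AA3), AA3)

# average residue (in-chain, water-free) masses in Da
RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

# hydrophobicity scales; Kyte-Doolittle is the default
HYDRO_SCALES <- list(
  kyte_doolittle = c(
    I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
    H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
  ),
  hopp_woods = c(
    R = 3.0, D = 3.0, E = 3.0, K = 3.0, S = 0.3, N = 0.2, Q = 0.2,
    G = 0.0, P = 0.0, T = -0.4, A = -0.5, H = -0.5, C = -1.0, M = -1.3,
    V = -1.5, I = -1.8, L = -1.8, Y = -2.3, F = -2.5, W = -3.4
  )
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# PDB parsing ------------------------------------------------------------

#' Parse a protein chain from PDB-format text
#'
#' Reads fixed-column ATOM records for one chain. HETATM records and
#' hydrogens are excluded; alternate locations are resolved to the highest
#' occupancy (ties broken by file order); insertion codes are kept as part
#' of the residue identity.
#'
#' @param pdb_text Character scalar or vector of PDB lines, or a file path.
#' @param chain Single chain identifier (default `"A"`).
#' @return Object of class `structure_model`: list with `chain` and
#'   `residues`, a data.frame of atoms with columns `res_id` (resSeq plus
#'   insertion code), `res_seq`, `ins`, `res_name`, `aa` (one-letter),
#'   `atom`, `element`, `x`, `y`, `z`, `occupancy`.
#' @export
parse_structure <- function(pdb_text, chain = "A") {
  lines <- pdb_lines(pdb_text)
  lines <- lines[startsWith(lines, "ATOM")]
  lines <- lines[substr(lines, 22, 22) == chain]
  if (!length(lines)) {
    stop("no ATOM records for chain '", chain, "'", call. = FALSE)
  }
  fld <- function(from, to) trimws(substr(lines, from, to))
  coords <- suppressWarnings(cbind(
    x = as.numeric(fld(31, 38)),
    y = as.numeric(fld(39, 46)),
    z = as.numeric(fld(47, 54))
  ))
  if (anyNA(coords)) {
    stop("malformed coordinate field in ATOM record", call. = FALSE)
  }
  occ <- suppressWarnings(as.numeric(fld(55, 60)))
  occ[is.na(occ)] <- 1
  element <- fld(77, 78)
  atom_name <- fld(13, 16)
  # infer element from the atom name when column 77-78 is blank
  guess <- sub("^[0-9]*", "", atom_name)
  element <- ifelse(element == "", substr(guess, 1, 1), element)
  d <- data.frame(
    res_seq = as.integer(fld(23, 26)),
    ins = substr(lines, 27, 27),
    res_name = fld(18, 20),
    atom = atom_name,
    altloc = substr(lines, 17, 17),
    element = toupper(element),
    coords, occupancy = occ,
    stringsAsFactors = FALSE
  )
  d <- d[d$element != "H" & d$element != "D", ]
  d$res_id <- paste0(d$res_seq, trimws(d$ins))
  # altloc resolution: within residue+atom keep highest occupancy, first wins ties
  key <- paste(d$res_id, d$atom, sep = "|")
  ord <- order(match(key, unique(key)), -d$occupancy,
               seq_len(nrow(d)))
  d <- d[ord, ]
  d <- d[!duplicated(paste(d$res_id, d$atom, sep = "|")), ]
  d$aa <- unname(AA1[d$res_name])
  d$aa[is.na(d$aa)] <- "X"
  d <- d[, c("res_id", "res_seq", "ins", "res_name", "aa", "atom",
             "element", "x", "y", "z", "occupancy")]
  rownames(d) <- NULL
  structure(list(chain = chain, residues = d), class = "structure_model")
}

pdb_lines <- function(pdb_text) {
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
      file.exists(pdb_text)) {
    return(readLines(pdb_text))
  }
  unlist(strsplit(pdb_text, "\n", fixed = TRUE))
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: chain %s, %d residues, %d atoms\n",
              x$chain, length(unique(x$residues$res_id)),
              nrow(x$residues)))
  invisible(x)
}

#' Residue identifiers of a structure model, in file order
#' @param model A `structure_model`.
#' @return Character vector of residue ids.
#' @export
residue_ids <- function(model) unique(model$residues$res_id)

#' One-letter sequence of a chain in residue order
#' @param model A `structure_model`.
#' @return Single string (unknown residues as `X`).
#' @export
structure_sequence <- function(model) {
  a <- model$residues
  paste(a$aa[!duplicated(a$res_id)], collapse = "")
}

#' Side-chain centroid of a residue
#'
#' Unweighted mean of the side-chain heavy-atom coordinates (all heavy
#' atoms except backbone N, CA, C, O, OXT). Glycine uses its alpha-carbon.
#' A non-glycine residue with no side-chain heavy atoms (e.g. truncated
#' side chain) falls back to CA with a warning.
#'
#' @param model A `structure_model`.
#' @param res_id Residue identifier (see [residue_ids()]).
#' @return Numeric length-3 coordinate vector (x, y, z).
#' @export
residue_centroid <- function(model, res_id) {
  a <- model$residues[model$residues$res_id == res_id, ]
  if (!nrow(a)) stop("residue '", res_id, "' not in model", call. = FALSE)
  ca <- a[a$atom == "CA", c("x", "y", "z")]
  if (a$res_name[1] == "GLY") {
    if (!nrow(ca)) stop("glycine '", res_id, "' has no CA", call. = FALSE)
    return(as.numeric(ca[1, ]))
  }
  sc <- a[!(a$atom %in% BACKBONE_ATOMS), c("x", "y", "z")]
  if (nrow(sc)) {
    return(unname(colMeans(sc)))
  }
  warning("residue '", res_id,
          "' has no side-chain heavy atoms; falling back to CA",
          call. = FALSE)
  if (!nrow(ca)) {
    stop("residue '", res_id, "' has no CA either", call. = FALSE)
  }
  as.numeric(ca[1, ])
}

#' All side-chain centroids of a model
#' @param model A `structure_model`.
#' @return Matrix with one row per residue (rownames = residue ids).
#' @export
centroid_matrix <- function(model) {
  ids <- residue_ids(model)
  m <- t(vapply(ids, function(r) residue_centroid(model, r), numeric(3)))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Structural neighbours of a residue
#'
#' Residues whose side-chain centroid lies within `radius` angstroms
#' (inclusive) of the target residue's centroid, the target itself
#' excluded. The count of this set is the NNG feature.
#'
#' @param model A `structure_model`.
#' @param target Residue identifier.
#' @param radius Sphere radius in angstroms (default 8).
#' @return Character vector of neighbour residue ids, ordered by residue
#'   number.
#' @export
find_neighbors <- function(model, target, radius = 8.0) {
  ids <- residue_ids(model)
  if (!target %in% ids) {
    stop("target residue '", target, "' not in model", call. = FALSE)
  }
  cm <- centroid_matrix(model)
  d <- sqrt(colSums((t(cm) - cm[target, ])^2))
  ids[d <= radius & ids != target]
}

#' Mean conservation of a residue's structural neighbours
#'
#' Averages the conservation profile over the neighbour positions after
#' mapping structure numbering to profile (canonical sequence) numbering.
#' Neighbours that map to a gap are skipped and counted.
#'
#' @param profile A `conservation_profile`.
#' @param neighbors Integer vector of structure residue numbers.
#' @param mapping Optional `alignment_map` from structure numbering to
#'   profile positions; `NULL` means the frames are identical.
#' @return List with `consng` (mean conservation, `NA` when no neighbour
#'   maps — an undefined-feature marker, not an error), `n_used`,
#'   `n_unmapped`.
#' @export
neighbor_conservation <- function(profile, neighbors, mapping = NULL) {
  if (!length(neighbors)) {
    return(list(consng = NA_real_, n_used = 0L, n_unmapped = 0L))
  }
  pos <- as.integer(neighbors)
  if (!is.null(mapping)) {
    pos <- pos[pos >= 1L & pos <= mapping$len_a]
    pos <- map_position(mapping, pos)
  }
  pos <- pos[!is.na(pos) & pos >= 1L & pos <= length(profile$rates)]
  n_used <- length(pos)
  list(
    consng = if (n_used) mean(profile$rates[pos]) else NA_real_,
    n_used = n_used,
    n_unmapped = length(neighbors) - n_used
  )
}

# DSSP -------------------------------------------------------------------

#' Parse per-residue accessibility and secondary structure from DSSP output
#'
#' Classic DSSP format. The ACC column is returned as the integer
#' water-molecule count; the 8-state secondary structure summary is
#' collapsed to three states: H/G/I -> helix, E/B -> strand, everything
#' else (including blank) -> coil. Chain-break records (`!`) are skipped.
#'
#' @param dssp_text DSSP file content (scalar/vector of lines) or path.
#' @param chain Chain identifier.
#' @return data.frame with columns `res_id`, `res_seq`, `aa`, `acc`, `ss`.
#' @export
parse_dssp <- function(dssp_text, chain = "A") {
  lines <- pdb_lines(dssp_text)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) {
    stop("not a DSSP file: per-residue header not found", call. = FALSE)
  }
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nchar(body) >= 38]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  body <- body[substr(body, 12, 12) == chain]
  if (!length(body)) {
    return(data.frame(res_id = character(), res_seq = integer(),
                      aa = character(), acc = integer(), ss = character()))
  }
  res_seq <- suppressWarnings(as.integer(trimws(substr(body, 6, 10))))
  acc <- suppressWarnings(as.integer(trimws(substr(body, 35, 38))))
  if (anyNA(res_seq) || anyNA(acc)) {
    stop("DSSP column misparse (residue number or ACC)", call. = FALSE)
  }
  ss8 <- substr(body, 17, 17)
  ss <- ifelse(ss8 %in% c("H", "G", "I"), "helix",
               ifelse(ss8 %in% c("E", "B"), "strand", "coil"))
  ins <- trimws(substr(body, 11, 11))
  data.frame(
    res_id = paste0(res_seq, ins),
    res_seq = res_seq,
    aa = substr(body, 14, 14),
    acc = acc,
    ss = ss,
    stringsAsFactors = FALSE
  )
}

# Substitution deltas ----------------------------------------------------

#' Physicochemical change of an amino-acid substitution
#'
#' @param ref,alt One-letter codes of the reference and substituted
#'   residues.
#' @param hydro_scale Name of the hydrophobicity scale
#'   (`"kyte_doolittle"` default, or `"hopp_woods"`).
#' @return List with `d_mw` (alt minus ref average residue mass, Da) and
#'   `d_hydro` (alt minus ref scale value). Both are antisymmetric under
#'   swapping ref and alt.
#' @export
substitution_delta <- function(ref, alt, hydro_scale = "kyte_doolittle") {
  scale <- HYDRO_SCALES[[match.arg(hydro_scale, names(HYDRO_SCALES))]]
  for (r in c(ref, alt)) {
    if (!r %in% names(RESIDUE_MASS)) {
      stop("unknown residue code '", r, "'", call. = FALSE)
    }
  }
  list(
    d_mw = unname(RESIDUE_MASS[alt] - RESIDUE_MASS[ref]),
    d_hydro = unname(scale[alt] - scale[ref])
  )
}

# PDB writing (used by the synthetic generator and the CLI) ---------------

#' Write a structure model as PDB-format ATOM records
#'
#' @param model A `structure_model`.
#' @param path Output file path; `NULL` returns the lines invisibly.
#' @return The PDB lines, invisibly.
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model$residues
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
    a$res_name, model$chain, a$res_seq,
    ifelse(trimws(a$ins) == "", " ", a$ins),
    a$x, a$y, a$z, a$occupancy, 0, a$element
  )
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
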