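pdb_fixture <- function() {
  # 3 residues: ALA1 (one CB), GLY2, SER3 with an altloc pair on OG
  c(
    "HEADER    TOY",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.000   1.000   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       4.000   2.000   1.000  1.00  0.00           C",
    "ATOM      6  N   SER A   3       6.000   0.000   0.000  1.00  0.00           N",
    "ATOM      7  CA  SER A   3       7.000   0.000   0.000  1.00  0.00           C",
    "ATOM      8  OG ASER A   3       8.000   1.000   0.000  0.40  0.00           O",
    "ATOM      9  OG BSER A   3       8.500   1.500   0.000  0.60  0.00           O",
    "HETATM   10  O   HOH A   9       9.000   9.000   9.000  1.00  0.00           O",
    "ATOM     11  H   SER A   3       7.100   0.100   0.000  1.00  0.00           H",
    "END"
  )
}

test_that("PDB parsing excludes HETATM/H and resolves altlocs", {
  m <- parse_structure(pdb_fixture(), "A")
  expect_equal(residue_ids(m), c("1", "2", "3"))
  expect_equal(nrow(m$residues), 8) # 3 + 2 + 3 (one OG kept, no H/HOH)
  og <- m$residues[m$residues$atom == "OG", ]
  expect_equal(nrow(og), 1)
  expect_equal(og$occupancy, 0.6) # highest occupancy wins
  expect_equal(structure_sequence(m), "AGS")
  expect_error(parse_structure(pdb_fixture(), "B"), "no ATOM")
  bad <- sub("1.000   2.000   3.000", "x.xxx   2.000   3.000",
             pdb_fixture(), fixed = TRUE)
  expect_error(parse_structure(bad, "A"), "malformed")
})

test_that("centroids: side-chain mean, glycine CA, fallback with warning", {
  m <- parse_structure(pdb_fixture(), "A")
  expect_equal(residue_centroid(m, "1"), c(1, 2, 3))       # single CB
  expect_equal(residue_centroid(m, "2"), c(4, 2, 1))       # GLY -> CA
  expect_equal(residue_centroid(m, "3"), c(8.5, 1.5, 0))   # kept altloc OG
  # truncated side chain falls back to CA
  trunc <- parse_structure(pdb_fixture()[c(1, 7, 8)], "A")
  expect_warning(ctr <- residue_centroid(trunc, "3"), "falling back")
  expect_equal(ctr, c(7, 0, 0))
  # two side-chain atoms -> midpoint
  two <- make_point_model(matrix(0, 1, 3))
  two$residues <- rbind(two$residues, two$residues)
  two$residues$x <- c(0, 2)
  expect_equal(residue_centroid(two, "1"), c(1, 0, 0))
  expect_error(residue_centroid(m, "99"), "not in model")
})

test_that("neighbour search: inclusive 8 A boundary and symmetry", {
  m <- make_point_model(rbind(c(0, 0, 0), c(7.9, 0, 0), c(16.2, 0, 0)))
  expect_equal(find_neighbors(m, "1"), "2")  # 7.9 inside
  expect_equal(find_neighbors(m, "2"), "1") # 2-3 distance 8.3, outside
  m2 <- make_point_model(rbind(c(0, 0, 0), c(8.1, 0, 0)))
  expect_equal(find_neighbors(m2, "1"), character(0))  # 8.1 outside
  m3 <- make_point_model(rbind(c(0, 0, 0), c(8, 0, 0)))
  expect_equal(find_neighbors(m3, "1"), "2")  # exactly 8 inclusive
  expect_error(find_neighbors(m, "77"), "not in model")
})

test_that("find_neighbors equals the brute-force oracle on 100 random structures", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    m <- make_point_model(matrix(runif(n * 3, 0, 25), n, 3))
    truth <- oracle_neighbors(m)
    for (r in sample(as.character(seq_len(n)), min(n, 5))) {
      got <- find_neighbors(m, r)
      expect_equal(got, truth[[r]], info = paste("structure", i, "res", r))
      # symmetry
      for (nb in got) expect_true(r %in% find_neighbors(m, nb))
    }
  }
})

test_that("neighbour conservation averages over mapped neighbours only", {
  p <- normalize_rates(c(5, 1, 2, 3, 4))
  # direct frame: neighbours 1,2,3 with planted conservation values
  nc <- neighbor_conservation(p, c(2, 3, 4))
  expect_equal(nc$consng, mean(p$rates[c(2, 3, 4)]))
  one <- neighbor_conservation(p, 5)
  expect_equal(one$consng, unname(p$rates[5]))
  # mapping with a gap: structure position 3 unmapped
  map <- align_global("ACDE", "ACE")
  nc2 <- neighbor_conservation(normalize_rates(c(1, 2, 3)), c(2, 3), map)
  expect_equal(nc2$n_unmapped, 1L)
  expect_equal(nc2$consng, unname(normalize_rates(c(1, 2, 3))$rates[2]))
  none <- neighbor_conservation(p, integer(0))
  expect_true(is.na(none$consng))
})

test_that("DSSP parsing: ACC counts, 3-state collapse, chain breaks", {
  txt <- make_dssp_text(
    res_seq = 1:10,
    aa = rep("A", 10),
    ss8 = c("H", "G", "I", "E", "B", "T", "S", " ", "H", " "),
    acc = c(42, 1:9),
    breaks = 6
  )
  d <- parse_dssp(txt, "A")
  expect_equal(nrow(d), 10)  # break row skipped
  expect_equal(d$acc[1], 42)
  expect_equal(d$ss,
               c("helix", "helix", "helix", "strand", "strand",
                 "coil", "coil", "coil", "helix", "coil"))
  expect_error(parse_dssp(c("just a header"), "A"), "not a DSSP")
  # header-only file -> empty result for the chain
  hdr_only <- make_dssp_text(1, "A", "H", 5, chain = "B")
  expect_equal(nrow(parse_dssp(hdr_only, "A")), 0)
})

test_that("substitution deltas are antisymmetric and match reference masses", {
  expect_equal(substitution_delta("A", "A"),
               list(d_mw = 0, d_hydro = 0))
  expect_equal(substitution_delta("A", "G")$d_mw, -14.03, tolerance = 1e-3)
  set.seed(13)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:15) {
    pair <- sample(aas, 2)
    fwd <- substitution_delta(pair[1], pair[2])
    rev <- substitution_delta(pair[2], pair[1])
    expect_equal(fwd$d_mw, -rev$d_mw)
    expect_equal(fwd$d_hydro, -rev$d_hydro)
  }
  expect_error(substitution_delta("A", "Z"), "unknown residue")
})

test_that("write_pdb / parse_structure round-trip preserves coordinates", {
  s <- gen_structure(6, list(c(1, 2), c(2, 3)), seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s$model, path)
  back <- parse_structure(path, "A")
  expect_equal(back$residues$x, s$model$residues$x, tolerance = 1e-3)
  expect_equal(back$residues$atom, s$model$residues$atom)
  expect_equal(structure_sequence(back), structure_sequence(s$model))
})
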