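test_that("feature tables have the canonical shape and determinism", {
  b <- gen_feature_table(schema = "structure", seed = 1)
  expect_equal(ncol(b$feature_table), 14)
  expect_equal(nrow(b$feature_table), 416)
  expect_equal(as.vector(table(b$feature_table$label)[c("disease", "pgx", "neutral")]),
               c(174, 55, 187))
  b2 <- gen_feature_table(schema = "structure", seed = 1)
  expect_identical(b$feature_table, b2$feature_table)
  b3 <- gen_feature_table(schema = "structure", seed = 2)
  expect_false(identical(b$feature_table, b3$feature_table))

  s <- gen_feature_table(schema = "sequence", seed = 1)
  expect_equal(ncol(s$feature_table), 8)
  expect_equal(nrow(s$feature_table), 1265)

  one <- gen_feature_table(list(class_spec("pgx", 1)), "sequence", seed = 3)
  expect_equal(nrow(one$feature_table), 1)
  expect_equal(one$feature_table$label, "pgx")

  expect_error(gen_feature_table(list(class_spec("pgx", 2),
                                      class_spec("pgx", 2)),
                                 "sequence"), "duplicate")
  expect_error(gen_feature_table(schema = "nope"), "arg")
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- rnorm(1)
  set.seed(99)
  invisible(gen_feature_table(schema = "sequence", seed = 5))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("class means recover the calibration targets within 3 SE", {
  # parameter recovery at the default (reported) class sizes, and at the
  # sequence-set sizes for conservation: means within 3 SE of spec value
  b <- gen_feature_table(schema = "structure", seed = 17)
  tab <- b$feature_table
  targets <- list(
    conservation = c(disease = -0.474, pgx = 0.000, neutral = 0.209),
    consng = c(disease = -0.316, pgx = -0.152, neutral = -0.021),
    nng = c(disease = 10.0, pgx = 9.4, neutral = 8.3),
    acc = c(disease = 30.4, pgx = 42.0, neutral = 52.8)
  )
  for (f in names(targets)) {
    for (cl in names(targets[[f]])) {
      v <- tab[[f]][tab$label == cl]
      se <- sd(v) / sqrt(length(v))
      expect_lt(abs(mean(v) - targets[[f]][[cl]]), 3 * se + 1e-12,
                label = sprintf("%s/%s |mean-target|", f, cl))
    }
  }

  s <- gen_feature_table(schema = "sequence", seed = 23)
  seq_target <- c(disease = -0.323, pgx = 0.145, neutral = 0.340)
  for (cl in names(seq_target)) {
    v <- s$feature_table$conservation[s$feature_table$label == cl]
    expect_lt(abs(mean(v) - seq_target[[cl]]), 0.05,
              label = paste("sequence conservation mean", cl))
  }
})

test_that("gen_structure plants exactly the requested contacts", {
  s <- gen_structure(3, list(c(1, 2)), seed = 1)
  expect_equal(s$neighbors, list(`1` = 2L, `2` = 1L, `3` = integer(0)))
  expect_equal(find_neighbors(s$model, "1"), "2")
  expect_equal(find_neighbors(s$model, "3"), character(0))

  chain <- gen_structure(10, lapply(1:9, function(i) c(i, i + 1)),
                         seed = 6)
  for (r in as.character(1:10)) {
    expect_equal(as.integer(find_neighbors(chain$model, r)),
                 chain$neighbors[[r]], info = paste("residue", r))
  }
  # ground truth always equals the brute-force oracle
  oracle <- oracle_neighbors(chain$model)
  for (r in names(oracle)) {
    expect_equal(as.integer(oracle[[r]]), chain$neighbors[[r]])
  }
  # glycine present and determinism
  expect_true("GLY" %in% chain$model$residues$res_name)
  again <- gen_structure(10, lapply(1:9, function(i) c(i, i + 1)),
                         seed = 6)
  expect_identical(chain$model$residues, again$model$residues)
  expect_error(gen_structure(1), ">= 2")
  expect_error(gen_structure(4, list(c(1, 5))), "invalid contact")
  # a 3-cycle cannot be laid out on a line: placement error, not silence
  expect_error(gen_structure(4, list(c(1, 2), c(2, 3), c(1, 3))),
               "placement")
})

test_that("gen_alignment: conserved columns invariant, reference gap-free", {
  a <- gen_alignment(8, 12, conserved_sites = c(2, 7), seed = 5)
  expect_equal(dim(a), c(8, 12))
  expect_false(any(a[1, ] %in% c("-", ".")))
  expect_true(all(apply(a[, c(2, 7)], 2,
                        function(cl) length(unique(cl)) == 1)))
  all_cons <- gen_alignment(5, 5, conserved_sites = 1:5, seed = 2)
  expect_true(all(apply(all_cons, 2,
                        function(cl) length(unique(cl)) == 1)))
  expect_error(gen_alignment(1, 5), ">= 2")
  expect_error(gen_alignment(5, 5, conserved_sites = 9), "out of range")
  expect_identical(gen_alignment(8, 12, seed = 4),
                   gen_alignment(8, 12, seed = 4))
})

test_that("score columns match missingness and monotone gradient specs", {
  specs <- default_class_specs("sequence")
  labels <- vapply(specs, function(s) s$label, character(1))
  big <- lapply(specs, function(s) {
    s$n <- 500L
    s
  })
  sc <- gen_score_columns(big, seed = 31)
  frac <- tapply(!is.na(sc$maf), sc$label, mean)
  expect_lt(abs(frac[["disease"]] - 0.04), 0.05)
  expect_lt(abs(frac[["neutral"]] - 0.57), 0.05)
  expect_lt(abs(frac[["pgx"]] - 0.74), 0.05)
  mm <- tapply(sc$maf, sc$label, mean, na.rm = TRUE)
  expect_lt(abs(mm[["pgx"]] - 0.139), 0.03)
  expect_lt(abs(mm[["neutral"]] - 0.061), 0.02)
  # monotone pathogenicity gradients
  mp <- tapply(sc$mutpred, sc$label, mean)
  expect_gt(mp[["disease"]], mp[["pgx"]])
  expect_gt(mp[["pgx"]], mp[["neutral"]])
  sift <- tapply(sc$sift, sc$label, mean)
  expect_lt(sift[["disease"]], sift[["pgx"]]) # lower = more pathogenic
  expect_true(all(sc$sift >= 0 & sc$sift <= 1))

  # maf_observed_frac = 0 -> entirely missing class
  none <- class_spec("disease", 50, maf_observed_frac = 0, maf_mean = 0.01)
  sc0 <- gen_score_columns(list(none), seed = 2)
  expect_true(all(is.na(sc0$maf)))
})

test_that("class_spec validates its invariants", {
  expect_error(class_spec("disease", 0), ">= 1")
  expect_error(class_spec("disease", 5, maf_observed_frac = 1.2), "0, 1")
  expect_error(class_spec("disease", 5, maf_mean = 0.7), "0, 0.5")
  expect_error(class_spec("other", 5), "neutral")
})
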