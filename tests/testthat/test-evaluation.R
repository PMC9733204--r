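test_that("validity, uniqueness and novelty follow the three nested filters", {
  r <- validity_uniqueness_novelty(c("CCO", "C(", "CCO", "CCN"), c("CCN"))
  expect_equal(r$pct_valid, 75)
  expect_equal(r$pct_valid_unique, 50)
  expect_equal(r$pct_valid_unique_novel, 25)
  allbad <- validity_uniqueness_novelty(c("C(", "1C", ")("))
  expect_equal(allbad$pct_valid, 0)
  expect_equal(allbad$pct_valid_unique, 0)
  expect_equal(allbad$pct_valid_unique_novel, 0)
  dup <- validity_uniqueness_novelty(c("CCO", "CCO"))
  expect_equal(dup$pct_valid, 100)
  expect_equal(dup$pct_valid_unique, 50)
  expect_error(validity_uniqueness_novelty(character(0)), "no generated")
})

test_that("uniqueness is structural: equivalent SMILES spellings collapse", {
  r <- validity_uniqueness_novelty(c("OCC", "CCO"), character(0))
  expect_equal(r$pct_valid_unique, 50)
  raw <- validity_uniqueness_novelty(c("OCC", "CCO"), character(0),
                                     canonical = FALSE)
  expect_equal(raw$pct_valid_unique, 100)
})

test_that("the metric ordering valid >= unique >= novel always holds", {
  pool <- c(toy_corpus_100()$smiles[1:20], "C(", "CC)", "C1CC", "", "CCO", "CCN")
  set.seed(13)
  for (i in 1:30) {
    gen <- sample(pool, sample(3:10, 1), replace = TRUE)
    train <- sample(pool, 3)
    r <- validity_uniqueness_novelty(gen, train)
    expect_gte(r$pct_valid, r$pct_valid_unique)
    expect_gte(r$pct_valid_unique, r$pct_valid_unique_novel)
  }
})

test_that("property windows are inclusive, symmetric and guarded", {
  expect_true(property_within_window(95, 100, 0.10))
  expect_true(property_within_window(100, 100))
  expect_false(property_within_window(89, 100, 0.10))
  expect_identical(property_within_window(110, 100, 0.10),
                   property_within_window(90, 100, 0.10))
  expect_error(property_within_window(1, 0), "non-zero")
  rep <- property_window_report(
    data.frame(mol_weight = c(100, 105, 130), logp = c(1, 2, 3)),
    list(mol_weight = 100, logp = 2), 0.10)
  expect_identical(rep$count[rep$property == "mol_weight"], 2L)
  expect_identical(rep$count[rep$property == "logp"], 1L)
})

test_that("min-max scaling maps to [0,1] with a degenerate-constant rule", {
  expect_equal(minmax_scale(c(0, 5, 10)), c(0, 0.5, 1))
  expect_identical(minmax_scale(c(7, 7, 7)), c(0, 0, 0))
  expect_error(minmax_scale(5), "at least 2")
  set.seed(17)
  for (i in 1:20) {
    out <- minmax_scale(rnorm(10))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("the composite score matches its printed arithmetic", {
  expect_equal(score_molecule(0, 0, 0, 0.5, 0.5, 0.5), 1 / 0.35,
               tolerance = 1e-6)
  base <- score_molecule(0.2, 0.2, 0.2, 0.5, 0.5, 0.5)
  expect_lt(score_molecule(0.4, 0.2, 0.2, 0.5, 0.5, 0.5), base)
  expect_lt(score_molecule(0.2, 0.4, 0.2, 0.5, 0.5, 0.5), base)
  expect_lt(score_molecule(0.2, 0.2, 0.4, 0.5, 0.5, 0.5), base)
  # affinity bundle enters as bindA + 1 - bindD + 1 - RAscore, as printed
  expect_lt(score_molecule(0.2, 0.2, 0.2, 0.7, 0.5, 0.5), base)
  expect_gt(score_molecule(0.2, 0.2, 0.2, 0.5, 0.7, 0.5), base)
  expect_gt(score_molecule(0.2, 0.2, 0.2, 0.5, 0.5, 0.7), base)
  # corrected variant flips the on-target direction
  expect_gt(score_molecule(0.2, 0.2, 0.2, 0.7, 0.5, 0.5, corrected = TRUE), base)
  # denominator guard
  expect_equal(score_molecule(0, 0, 0, 0, 1, 1), 1e9, tolerance = 1e-3)
})

test_that("top-k ranking is descending with deterministic tie-breaks", {
  df <- data.frame(smiles = c("CCO", "CCN", "CCC"), score = c(3, 1, 2),
                   stringsAsFactors = FALSE)
  top <- rank_top_k(df, 2)
  expect_identical(top$score, c(3, 2))
  full <- rank_top_k(df, 3)
  expect_identical(full$score, c(3, 2, 1))
  ties <- data.frame(smiles = c("CCN", "CCO", "CCC"), score = c(1, 1, 1),
                     stringsAsFactors = FALSE)
  t1 <- rank_top_k(ties, 3)
  t2 <- rank_top_k(ties[c(2, 3, 1), ], 3)
  expect_identical(t1$smiles, t2$smiles)
  expect_error(rank_top_k(df, 5), "exceeds")
})

test_that("batch scoring produces bounded components and finite scores", {
  corp <- toy_corpus_100()$smiles[1:12]
  oracles <- make_mock_oracles(1)
  panel <- target_panel(c("RAF1", "BRAF"), c("EGFR"))
  sc <- score_batch(corp, "CCC(=O)Nc1ccccc1", panel, oracles)
  expect_true(all(sc$mw_scaled >= 0 & sc$mw_scaled <= 1))
  expect_true(all(sc$bind_a_scaled >= 0 & sc$bind_a_scaled <= 1))
  expect_true(all(is.finite(sc$score) & sc$score > 0))
  top <- rank_top_k(sc, 5)
  expect_identical(nrow(top), 5L)
  expect_true(all(diff(top$score) <= 0))
})
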