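test_that("vocabulary covers the corpus alphabet with delimiters and pad", {
  v <- build_vocabulary(data.frame(smiles = "CCO"))
  expect_true(all(c("<", ">", "<pad>", "C", "O") %in% v$tokens))
  expect_equal(sum(v$tokens == "<"), 1L)
  expect_equal(sum(v$tokens == ">"), 1L)
  # order invariance via deterministic sorting
  v1 <- build_vocabulary(data.frame(smiles = c("C", "N")))
  v2 <- build_vocabulary(data.frame(smiles = c("N", "C")))
  expect_identical(v1$tokens, v2$tokens)
  expect_error(build_vocabulary(data.frame(smiles = character(0))), "empty")
})

test_that("two-character atoms and bracket atoms are single tokens", {
  v <- build_vocabulary(data.frame(smiles = c("CCl", "CBr", "C[nH]1cccc1")))
  expect_true("Cl" %in% v$tokens)
  expect_true("Br" %in% v$tokens)
  expect_true("[nH]" %in% v$tokens)
  expect_false("l" %in% v$tokens)
  ts <- tokenize("CCl", v)
  expect_identical(ts$tokens, c("<", "C", "Cl", ">"))
})

test_that("tokenize wraps in delimiters and reports unknown characters", {
  v <- build_vocabulary(data.frame(smiles = c("CCO", "C(Br)=O")))
  expect_identical(tokenize("CCO", v)$tokens, c("<", "C", "C", "O", ">"))
  expect_identical(tokenize("C(Br)=O", v)$tokens,
                   c("<", "C", "(", "Br", ")", "=", "O", ">"))
  expect_error(tokenize("", v), "empty")
  expect_error(tokenize("CSC", v), "'S' at position 2")
})

test_that("detokenize inverts tokenize and validates delimiters", {
  v <- build_vocabulary(toy_corpus_100())
  expect_identical(detokenize(c("<", "C", "C", "O", ">")), "CCO")
  expect_identical(detokenize(c("<", ">")), "")
  expect_error(detokenize(c("C", "C")), "start with")
  for (s in toy_corpus_100()$smiles) {
    expect_identical(detokenize(tokenize(s, v)), s)
  }
})

test_that("condition descriptors are deterministic and chemically sane", {
  m <- compute_conditions("C")
  expect_equal(m[["mol_weight"]], 16.04, tolerance = 1e-3)
  expect_identical(m[["tpsa"]], 0)
  expect_identical(compute_conditions("CCO"), compute_conditions("CCO"))
  expect_error(compute_conditions("C("), "invalid")
  b <- compute_conditions_batch(c("CCO", "not_a_smiles", "c1ccccc1"))
  expect_equal(nrow(b), 3L)
  expect_true(is.na(b$mol_weight[2]))
  expect_gt(b$tpsa[1], 0)
})

test_that("SMILES validity combines syntax checking with the parser", {
  expect_true(is_valid_smiles("CCO"))
  expect_true(is_valid_smiles("c1ccccc1"))
  expect_false(is_valid_smiles("C("))     # unbalanced branch
  expect_false(is_valid_smiles("C1CC"))   # unmatched ring bond
  expect_false(is_valid_smiles("CC)"))
  expect_false(is_valid_smiles(""))
  expect_false(is_valid_smiles("C C"))
  expect_identical(is_valid_smiles(c("CCO", "C(")), c(TRUE, FALSE))
})

test_that("corpus filter enforces validity, length and the MW window", {
  recs <- data.frame(
    id = as.character(1:5),
    smiles = c("CCO",                                  # MW 46: below window
               "CCCCCCC",                              # MW 100: below window
               strrep("C", 120),                       # length >= 100
               "CCCCCCCCCCCCCCCCCCCC",                 # MW 283, length 20
               "C1CC"),                                # invalid
    stringsAsFactors = FALSE)
  out <- filter_corpus(recs)
  expect_identical(out$id, "4")
  # subset + idempotence
  expect_identical(filter_corpus(out), out)
  expect_true(all(out$smiles %in% recs$smiles))
})

test_that("toy corpus is reproducible, valid and diverse", {
  expect_identical(generate_toy_corpus(10, seed = 1),
                   generate_toy_corpus(10, seed = 1))
  corp <- cached("corpus500", generate_toy_corpus(500, seed = 7))
  expect_true(all(is_valid_smiles(corp$smiles)))
  expect_gte(length(unique(corp$smiles)), 150L)
})

test_that("SMILES files and vocabularies round-trip through disk", {
  corp <- toy_corpus_100()[1:10, ]
  smi <- tempfile(fileext = ".smi")
  write_smiles(corp, smi)
  expect_identical(read_smiles(smi)$smiles, corp$smiles)
  csv <- tempfile(fileext = ".csv")
  write_smiles(corp, csv)
  back <- read_smiles(csv)
  expect_identical(back$smiles, corp$smiles)
  expect_identical(back$id, corp$id)
  v <- build_vocabulary(corp)
  vj <- tempfile(fileext = ".json")
  write_vocabulary(v, vj)
  expect_identical(read_vocabulary(vj)$tokens, v$tokens)
})

test_that("condition scaling standardizes to zero mean and unit sd", {
  conds <- compute_conditions_batch(toy_corpus_100()$smiles[1:20])
  st <- condition_stats(conds)
  scaled <- t(vapply(seq_len(20), function(i) {
    scale_conditions(stats::setNames(as.numeric(conds[i, ]),
                                     c("mol_weight", "logp", "tpsa")), st)
  }, numeric(3)))
  expect_equal(colMeans(scaled), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(apply(scaled, 2, sd), c(1, 1, 1), tolerance = 1e-10)
})
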