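# Generation metrics, property windows, and the composite molecule score.

#' Validity / uniqueness / novelty of a generated batch
#'
#' A generated string is *valid* when it parses; valid molecules are
#' *unique* when their canonical SMILES are distinct; unique molecules are
#' *novel* when their canonical form is absent from the (canonicalized)
#' training set. All three are reported as percentages of the number
#' generated, so the ordering `valid >= unique >= novel` always holds.
#'
#' @param generated Character vector of generated SMILES.
#' @param training_set Character vector of training SMILES (may be empty).
#' @param canonical Compare structures via canonical SMILES (default); when
#'   `FALSE`, raw strings are compared instead.
#' @return List of class `generation_report`: `n_generated`, `pct_valid`,
#'   `pct_valid_unique`, `pct_valid_unique_novel`, and the corresponding
#'   counts.
#' @export
validity_uniqueness_novelty <- function(generated, training_set = character(0),
                                        canonical = TRUE) {
  if (length(generated) == 0L) stop("no generated molecules to evaluate")
  n <- length(generated)
  valid <- is_valid_smiles(generated)
  keys <- if (canonical) canonical_smiles(generated[valid]) else generated[valid]
  keys <- keys[!is.na(keys)]
  uniq <- unique(keys)
  train_keys <- if (length(training_set)) {
    if (canonical) {
      tk <- canonical_smiles(training_set)
      tk[!is.na(tk)]
    } else training_set
  } else character(0)
  novel <- setdiff(uniq, train_keys)
  structure(list(n_generated = n,
                 n_valid = sum(valid), n_valid_unique = length(uniq),
                 n_valid_unique_novel = length(novel),
                 pct_valid = 100 * sum(valid) / n,
                 pct_valid_unique = 100 * length(uniq) / n,
                 pct_valid_unique_novel = 100 * length(novel) / n),
            class = "generation_report")
}

#' @export
print.generation_report <- function(x, ...) {
  cat(sprintf("generated %d | valid %.1f%% | valid+unique %.1f%% | valid+unique+novel %.1f%%\n",
              x$n_generated, x$pct_valid, x$pct_valid_unique,
              x$pct_valid_unique_novel))
  invisible(x)
}

#' Is a property within a fractional window of a reference value?
#'
#' `|value - reference| <= tol * |reference|`, the "within 10 percent of the
#' reference molecule" membership test (inclusive at the boundary,
#' symmetric in deviation sign).
#'
#' @param value Observed property value(s); vectorized.
#' @param reference Non-zero reference value.
#' @param tol Fractional tolerance, default 0.10.
#' @return Logical vector.
#' @export
property_within_window <- function(value, reference, tol = 0.10) {
  if (reference == 0) stop("reference value must be non-zero")
  abs(value - reference) <= tol * abs(reference)
}

#' Property-window report for a generated batch
#'
#' For each property column shared by `values` and `reference`, counts how
#' many molecules fall within the fractional window of the reference value.
#'
#' @param values Data.frame of per-molecule property values.
#' @param reference Named list/vector of reference values (non-zero).
#' @param tol Fractional tolerance, default 0.10.
#' @return Data.frame with columns `property`, `n`, `count`, `pct`.
#' @export
property_window_report <- function(values, reference, tol = 0.10) {
  props <- intersect(names(values), names(reference))
  if (length(props) == 0L) stop("no shared property columns")
  rows <- lapply(props, function(p) {
    v <- values[[p]]
    v <- v[!is.na(v)]
    inw <- property_within_window(v, reference[[p]], tol)
    data.frame(property = p, n = length(v), count = sum(inw),
               pct = if (length(v)) 100 * sum(inw) / length(v) else 0)
  })
  do.call(rbind, rows)
}

#' Min-max scale a vector to [0, 1]
#'
#' `(v - min) / (max - min)`; a constant vector maps to all zeros.
#'
#' @param values Numeric vector of length >= 2.
#' @return Scaled vector in `[0, 1]`.
#' @export
minmax_scale <- function(values) {
  if (length(values) < 2L) stop("min-max scaling needs at least 2 values")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Composite molecule score
#'
#' `score = 1 / (0.3 * (mw + logp + tpsa) / 3 +
#'               0.7 * (bind_a + 1 - bind_d + 1 - rascore) / 3 + eps)`
#' where `mw`, `logp`, `tpsa` are the 0-1 scaled absolute differences from
#' the reference molecule and `bind_a`, `bind_d` the 0-1 scaled mean
#' affinities. The affinity terms enter exactly as printed above; set
#' `corrected = TRUE` to use `1 - bind_a` instead, which makes high
#' on-target affinity raise the score (see the methods vignette).
#'
#' @param mw,logp,tpsa Scaled absolute descriptor differences in `[0, 1]`.
#' @param bind_a,bind_d Scaled mean on-/off-target affinities in `[0, 1]`.
#' @param rascore Synthesizability score in `[0, 1]`.
#' @param eps Denominator guard, default 1e-9.
#' @param corrected Use the sign-corrected on-target term (default `FALSE`).
#' @param property_weight,affinity_weight Term weights, defaults 0.3 / 0.7.
#' @return The scalar score (capped at `1/eps`).
#' @export
score_molecule <- function(mw, logp, tpsa, bind_a, bind_d, rascore,
                           eps = 1e-9, corrected = FALSE,
                           property_weight = 0.3, affinity_weight = 0.7) {
  stopifnot(all(c(mw, logp, tpsa, bind_a, bind_d, rascore) >= 0),
            all(c(mw, logp, tpsa, bind_a, bind_d, rascore) <= 1))
  a_term <- if (corrected) 1 - bind_a else bind_a
  denom <- property_weight * (mw + logp + tpsa) / 3 +
    affinity_weight * (a_term + 1 - bind_d + 1 - rascore) / 3
  1 / max(denom + eps, eps)
}

#' Score a batch of generated molecules against a reference
#'
#' Computes descriptor differences from the reference molecule, min-max
#' scales them over the batch, scales the oracle affinities the same way,
#' and applies [score_molecule()] to every molecule.
#'
#' @param smiles Character vector of valid generated SMILES (>= 2).
#' @param reference_smiles The reference molecule.
#' @param panel A `target_panel`.
#' @param oracles Oracle list (`affinity`, `synth`).
#' @param corrected Passed to [score_molecule()].
#' @return Data.frame with the raw and scaled components and `score`,
#'   one row per molecule.
#' @export
score_batch <- function(smiles, reference_smiles, panel, oracles,
                        corrected = FALSE) {
  ok <- is_valid_smiles(smiles)
  smiles <- smiles[ok]
  if (length(smiles) < 2L) stop("need at least 2 valid molecules to score")
  ref <- compute_conditions(reference_smiles)
  props <- compute_conditions_batch(smiles)
  aff_a <- vapply(smiles, function(s) mean_affinity(s, panel$group_a, oracles$affinity),
                  numeric(1), USE.NAMES = FALSE)
  aff_d <- if (length(panel$group_d)) {
    vapply(smiles, function(s) mean_affinity(s, panel$group_d, oracles$affinity),
           numeric(1), USE.NAMES = FALSE)
  } else rep(0, length(smiles))
  ra <- vapply(smiles, function(s) as.numeric(oracles$synth(s)),
               numeric(1), USE.NAMES = FALSE)
  d_mw <- minmax_scale(abs(props$mol_weight - ref[["mol_weight"]]))
  d_lp <- minmax_scale(abs(props$logp - ref[["logp"]]))
  d_tp <- minmax_scale(abs(props$tpsa - ref[["tpsa"]]))
  s_a <- minmax_scale(aff_a)
  s_d <- if (length(panel$group_d)) minmax_scale(aff_d) else rep(0, length(smiles))
  score <- mapply(score_molecule, d_mw, d_lp, d_tp, s_a, s_d, ra,
                  MoreArgs = list(corrected = corrected))
  data.frame(smiles = smiles, mol_weight = props$mol_weight,
             logp = props$logp, tpsa = props$tpsa,
             aff_a = aff_a, aff_d = aff_d, rascore = ra,
             mw_scaled = d_mw, logp_scaled = d_lp, tpsa_scaled = d_tp,
             bind_a_scaled = s_a, bind_d_scaled = s_d,
             score = score, stringsAsFactors = FALSE)
}

#' Select the top-k scoring molecules
#'
#' Highest scores first; exact ties are broken lexicographically by
#' canonical SMILES so the selection is deterministic.
#'
#' @param scored Data.frame with columns `smiles` and `score` (e.g. from
#'   [score_batch()]).
#' @param k Number of molecules to keep (default 100).
#' @return The top-k rows, ordered by descending score, with a `rank`
#'   column.
#' @export
rank_top_k <- function(scored, k = 100L) {
  if (k > nrow(scored)) stop("k = ", k, " exceeds the ", nrow(scored),
                             " molecules available")
  key <- canonical_smiles(scored$smiles)
  key[is.na(key)] <- scored$smiles[is.na(key)]
  ord <- order(-scored$score, key, method = "radix")
  out <- scored[ord[seq_len(k)], , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}
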