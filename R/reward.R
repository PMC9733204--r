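# Reward shaping for reinforcement learning: synthesizability (RAscore)
# and on-/off-target predicted binding affinity.

#' Define an on-/off-target protein panel
#'
#' @param group_a Character vector of proteins the molecule should bind
#'   (on-targets); must be non-empty.
#' @param group_d Character vector of proteins the molecule should not bind
#'   (off-targets); disjoint from `group_a`.
#' @return List of class `target_panel`.
#' @export
target_panel <- function(group_a, group_d = character(0)) {
  if (length(group_a) == 0L) stop("group_a must contain at least one protein")
  if (length(intersect(group_a, group_d)) > 0L)
    stop("group_a and group_d must be disjoint")
  structure(list(group_a = group_a, group_d = group_d), class = "target_panel")
}

#' Mean predicted binding affinity over a protein panel
#'
#' @param smiles A SMILES string.
#' @param proteins Non-empty character vector of protein identifiers.
#' @param oracle Affinity oracle: `function(smiles, protein)` returning a
#'   finite numeric score (higher = stronger predicted binding).
#' @return Arithmetic mean of the per-protein scores.
#' @export
mean_affinity <- function(smiles, proteins, oracle) {
  if (length(proteins) == 0L) stop("protein panel is empty")
  mean(vapply(proteins, function(p) as.numeric(oracle(smiles, p)), numeric(1)))
}

#' Synthesizability reward component
#'
#' `reward1 = 1` when `RAscore = 0`, otherwise `5 * RAscore + 1`. A
#' continuous RAscore in `[0, 1]` is accepted, so the component ranges over
#' `[1, 6]`.
#'
#' @param rascore Retrosynthetic accessibility score in `[0, 1]`.
#' @return The reward component.
#' @export
reward_synth <- function(rascore) {
  if (!is.finite(rascore) || rascore < 0 || rascore > 1)
    stop("RAscore must lie in [0, 1]")
  if (rascore == 0) 1 else rascore * 5 + 1
}

#' On-target (group A) affinity reward component
#'
#' `reward2 = (affA - 4)^2 + 1` when the mean on-target affinity exceeds the
#' threshold (strictly), and 1 otherwise.
#'
#' @param aff_a Mean predicted binding affinity to the on-target panel.
#' @param threshold Branch threshold (default 5; the inequality is strict).
#' @return The reward component.
#' @export
reward_on_target <- function(aff_a, threshold = 5) {
  if (!is.finite(aff_a)) stop("affinity must be finite")
  if (aff_a > threshold) (aff_a - 4)^2 + 1 else 1
}

#' Off-target (group D) affinity reward component
#'
#' `reward3 = 6` when the mean off-target affinity is below the threshold
#' (strictly), and 1 otherwise: low predicted off-target binding is
#' rewarded.
#'
#' @param aff_d Mean predicted binding affinity to the off-target panel.
#' @param threshold Branch threshold (default 5.5; `aff_d < threshold`
#'   earns the high reward).
#' @return The reward component (6 or 1).
#' @export
reward_off_target <- function(aff_d, threshold = 5.5) {
  if (!is.finite(aff_d)) stop("affinity must be finite")
  if (aff_d < threshold) 6 else 1
}

#' Total episode reward for a generated molecule
#'
#' Queries the affinity oracle over both panels and the synthesizability
#' oracle, then sums the three components. Invalid SMILES (including the
#' empty string) receive the all-minimum reward (1 + 1 + 1 = 3) without
#' consulting the oracles, which keeps the policy-gradient log terms finite
#' while still penalizing invalidity against any molecule that clears a
#' threshold.
#'
#' @param smiles The generated SMILES string.
#' @param panel A `target_panel`.
#' @param aff_oracle Affinity oracle `function(smiles, protein)`.
#' @param synth_oracle Synthesizability oracle `function(smiles)` returning
#'   an RAscore in `[0, 1]`.
#' @param on_threshold,off_threshold Reward branch thresholds (defaults 5
#'   and 5.5).
#' @return List of class `reward_components`: `aff_a`, `aff_d`, `rascore`,
#'   `reward1`, `reward2`, `reward3`, `total`, `valid`.
#' @export
total_reward <- function(smiles, panel, aff_oracle, synth_oracle,
                         on_threshold = 5, off_threshold = 5.5) {
  if (!is_valid_smiles(smiles)) {
    return(structure(list(aff_a = NA_real_, aff_d = NA_real_,
                          rascore = NA_real_, reward1 = 1, reward2 = 1,
                          reward3 = 1, total = 3, valid = FALSE),
                     class = "reward_components"))
  }
  aff_a <- tryCatch(mean_affinity(smiles, panel$group_a, aff_oracle),
                    error = function(e) stop("affinity oracle failed: ",
                                             conditionMessage(e)))
  aff_d <- if (length(panel$group_d) > 0L) {
    tryCatch(mean_affinity(smiles, panel$group_d, aff_oracle),
             error = function(e) stop("affinity oracle failed: ",
                                      conditionMessage(e)))
  } else -Inf  # no off-targets: the low-affinity branch applies trivially
  ra <- tryCatch(as.numeric(synth_oracle(smiles)),
                 error = function(e) stop("synthesizability oracle failed: ",
                                          conditionMessage(e)))
  r1 <- reward_synth(ra)
  r2 <- reward_on_target(aff_a, on_threshold)
  r3 <- if (is.finite(aff_d)) reward_off_target(aff_d, off_threshold) else 6
  structure(list(aff_a = aff_a, aff_d = if (is.finite(aff_d)) aff_d else NA_real_,
                 rascore = ra, reward1 = r1, reward2 = r2, reward3 = r3,
                 total = r1 + r2 + r3, valid = TRUE),
            class = "reward_components")
}

#' @export
print.reward_components <- function(x, ...) {
  cat(sprintf("reward: %.3f (synth %.3f + on-target %.3f + off-target %.3f)%s\n",
              x$total, x$reward1, x$reward2, x$reward3,
              if (x$valid) "" else " [invalid SMILES]"))
  invisible(x)
}

# heavy atoms and nitrogen counts from the tokenizer (bracket atoms parsed
# for their element symbol)
.atom_counts <- function(smiles) {
  toks <- tryCatch(.tokenize_chars(smiles), error = function(e) character(0))
  plain_atoms <- c("B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
                   "b", "c", "n", "o", "p", "s")
  heavy <- 0L; nitro <- 0L
  for (tk in toks) {
    if (grepl("^\\[", tk)) {
      el <- sub("^\\[[0-9]*([A-Za-z][a-z]?).*", "\\1", tk)
      if (toupper(el) != "H") heavy <- heavy + 1L
      if (toupper(el) == "N") nitro <- nitro + 1L
    } else if (tk %in% plain_atoms) {
      heavy <- heavy + 1L
      if (toupper(tk) == "N") nitro <- nitro + 1L
    }
  }
  c(heavy = heavy, nitrogen = nitro)
}

#' Deterministic mock oracles for offline testing
#'
#' Structure-dependent stand-ins for the external binding-affinity and
#' synthesizability predictors, so the full reinforcement-learning loop can
#' run and be tested without any downloaded model. The affinity oracle
#' returns `3 + 4 * (nitrogen count / heavy-atom count)` plus a small
#' seeded per-protein offset, so it is bounded, reproducible, and increases
#' when nitrogens are added to a fixed scaffold. The synthesizability
#' oracle is a logistic curve in the heavy-atom count (smaller molecules
#' score closer to 1), always in `[0, 1]`.
#'
#' @param seed Integer seed fixing the per-protein offsets.
#' @return List with `affinity` (`function(smiles, protein)`) and `synth`
#'   (`function(smiles)`).
#' @export
make_mock_oracles <- function(seed = 1L) {
  offset_cache <- new.env(parent = emptyenv())
  protein_offset <- function(protein) {
    key <- as.character(protein)
    if (!is.null(offset_cache[[key]])) return(offset_cache[[key]])
    hash <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 10000L
    restore <- .Random.seed_guard(as.integer(seed) * 13L + hash)
    off <- stats::runif(1, -0.5, 0.5)
    restore()
    offset_cache[[key]] <- off
    off
  }
  affinity <- function(smiles, protein) {
    ct <- .atom_counts(smiles)
    if (ct["heavy"] == 0L) return(0)
    3 + 4 * ct[["nitrogen"]] / ct[["heavy"]] + protein_offset(protein)
  }
  synth <- function(smiles) {
    ct <- .atom_counts(smiles)
    1 / (1 + exp((ct[["heavy"]] - 20) / 5))
  }
  list(affinity = affinity, synth = synth)
}

# ---- oracle registry -----------------------------------------------------

.oracle_registry <- new.env(parent = emptyenv())

#' Register a named oracle factory
#'
#' Adapters for real predictors (or test doubles) are registered under a
#' name and looked up from run configurations. The factory is called with a
#' seed and must return `list(affinity = function(smiles, protein),
#' synth = function(smiles))`.
#'
#' @param name Registry key.
#' @param factory Factory function `function(seed)`.
#' @return `name`, invisibly.
#' @export
register_oracle <- function(name, factory) {
  if (!is.function(factory)) stop("factory must be a function(seed)")
  assign(name, factory, envir = .oracle_registry)
  invisible(name)
}

#' Instantiate a registered oracle pair
#'
#' @param name Registry key (the packaged default is `"mock"`).
#' @param seed Seed passed to the factory.
#' @return Oracle list as from [make_mock_oracles()].
#' @export
get_oracles <- function(name = "mock", seed = 1L) {
  if (!exists(name, envir = .oracle_registry))
    stop("no oracle registered under '", name, "'")
  get(name, envir = .oracle_registry)(seed)
}
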