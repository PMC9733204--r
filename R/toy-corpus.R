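# Fragment grammar for the toy corpus. Every fragment is a complete
# chain-extension substring, so any concatenation starting from a seed chain
# is syntactically valid SMILES by construction.
.toy_seeds <- c("CC", "CCC", "CCCC", "CCO", "CCN", "CC(C)C", "CCOC", "CCCN")
.toy_rings <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCNCC1", "c1ccc(C)cc1",
                "C1CCOC1", "c1ccsc1")
.toy_links <- c("C(=O)N", "C(=O)O", "C(=O)", "CC", "OC", "NC", "C(C)", "S")
.toy_subs  <- c("Cl", "Br", "F", "O", "N", "C#N", "OC", "N(C)C", "C(F)(F)F")

#' Generate a toy SMILES corpus
#'
#' Assembles short molecules by seeded random concatenation of a fixed
#' fragment grammar (alkyl chains, aromatic/aliphatic rings, amide and ester
#' linkers, halogen and small polar substituents). Every fragment is a valid
#' chain extension, so the emitted strings are valid SMILES by construction,
#' diverse, and cheap enough to compute descriptors for. Intended as the
#' offline stand-in for a real training corpus in tests and examples.
#'
#' @param n Number of records to generate.
#' @param seed Integer seed; the same `(n, seed)` pair always yields the
#'   identical corpus.
#' @return Data.frame with columns `id`, `smiles`.
#' @export
generate_toy_corpus <- function(n, seed = 1L) {
  if (n <= 0L) stop("n must be positive")
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  smiles <- character(n)
  for (i in seq_len(n)) {
    parts <- sample(.toy_seeds, 1L)
    n_blocks <- sample(1:3, 1L)
    for (b in seq_len(n_blocks)) {
      parts <- c(parts, sample(.toy_links, 1L))
      if (stats::runif(1) < 0.75) parts <- c(parts, sample(.toy_rings, 1L))
    }
    # substituents are univalent caps, so they may only terminate the chain
    if (stats::runif(1) < 0.5) parts <- c(parts, sample(.toy_subs, 1L))
    smiles[i] <- paste(parts, collapse = "")
  }
  data.frame(id = sprintf("toy%d", seq_len(n)), smiles = smiles,
             stringsAsFactors = FALSE)
}

# Save/restore the global RNG state around a seeded computation so seeded
# helpers do not perturb the caller's random stream.
.Random.seed_guard <- function(seed) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
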