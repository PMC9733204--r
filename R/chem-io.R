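PAD_TOKEN <- "<pad>"
START_TOKEN <- "<"
END_TOKEN <- ">"

#' Read a SMILES corpus
#'
#' Reads either a `.smi`/plain-text file with one SMILES per line or a CSV
#' with columns `id,smiles`. Plain-text records are assigned sequential ids.
#'
#' @param path Path to a `.smi`, `.txt`, or `.csv` file.
#' @return A data.frame with character columns `id` and `smiles`.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("id", "smiles") %in% names(df))) {
      stop("CSV corpus must have columns 'id' and 'smiles'")
    }
    df <- df[, c("id", "smiles")]
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    df <- data.frame(id = sprintf("mol%d", seq_along(lines)),
                     smiles = lines, stringsAsFactors = FALSE)
  }
  if (any(grepl("\\s", df$smiles))) stop("SMILES strings must not contain whitespace")
  df
}

#' Write a SMILES corpus
#'
#' @param records Data.frame with columns `id`, `smiles`.
#' @param path Output path; `.csv` writes `id,smiles`, anything else writes
#'   one SMILES per line.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(records, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(records[, c("id", "smiles")], path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(records$smiles, path)
  }
  invisible(path)
}

# Tokenizer: character-level, except two-character halogens (Cl, Br),
# bracket atoms ([nH], [O-], [NH3+], ...) and %nn ring closures, which are
# single tokens.
.tokenize_chars <- function(smiles) {
  if (!nzchar(smiles)) stop("cannot tokenize an empty SMILES string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES at position ", i, ": ", smiles)
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%" && i + 2L <= n &&
               grepl("^[0-9][0-9]$", paste(chars[(i + 1L):(i + 2L)], collapse = ""))) {
      out <- c(out, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      out <- c(out, "Br")
      i <- i + 2L
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      out <- c(out, "Cl")
      i <- i + 2L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Build a token vocabulary from a corpus
#'
#' Tokenizes every corpus SMILES (character-level with two-character halogen
#' tokens `Cl`/`Br`, bracket atoms, and `%nn` ring closures as single tokens)
#' and returns the sorted union plus the start (`<`), end (`>`), and padding
#' tokens. Ordering is deterministic, so corpora that differ only in record
#' order give identical vocabularies.
#'
#' @param records Data.frame with a `smiles` column (or a character vector).
#' @return An object of class `smiles_vocabulary`: list with `tokens`
#'   (character vector) and `index` (named integer vector mapping token to
#'   1-based id).
#' @export
build_vocabulary <- function(records) {
  smiles <- if (is.data.frame(records)) records$smiles else as.character(records)
  if (length(smiles) == 0L) stop("cannot build a vocabulary from an empty corpus")
  toks <- unique(unlist(lapply(smiles, .tokenize_chars)))
  toks <- setdiff(toks, c(START_TOKEN, END_TOKEN, PAD_TOKEN))
  tokens <- c(PAD_TOKEN, START_TOKEN, END_TOKEN, sort(toks, method = "radix"))
  index <- stats::setNames(seq_along(tokens), tokens)
  structure(list(tokens = tokens, index = index), class = "smiles_vocabulary")
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat("SMILES vocabulary:", length(x$tokens), "tokens\n")
  cat(" ", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

#' Tokenize a SMILES string
#'
#' Splits `smiles` into vocabulary tokens and wraps it in the start token
#' `<` and end token `>`.
#'
#' @param smiles A single SMILES string.
#' @param vocab A `smiles_vocabulary`.
#' @return An object of class `token_sequence`: list with `tokens` (including
#'   delimiters) and `length` (interior token count).
#' @export
tokenize <- function(smiles, vocab) {
  if (!nzchar(smiles)) stop("cannot tokenize an empty SMILES string")
  toks <- .tokenize_chars(smiles)
  unknown <- which(!(toks %in% vocab$tokens))
  if (length(unknown) > 0L) {
    stop(sprintf("token '%s' at position %d is not in the vocabulary",
                 toks[unknown[1L]], unknown[1L]))
  }
  structure(list(tokens = c(START_TOKEN, toks, END_TOKEN), length = length(toks)),
            class = "token_sequence")
}

#' Reassemble a SMILES string from a token sequence
#'
#' @param seq A `token_sequence` (or bare character vector delimited by
#'   `<` and `>`).
#' @return The interior SMILES string (possibly empty).
#' @export
detokenize <- function(seq) {
  toks <- if (inherits(seq, "token_sequence")) seq$tokens else as.character(seq)
  n <- length(toks)
  if (n < 2L || toks[1L] != START_TOKEN || toks[n] != END_TOKEN) {
    stop("token sequence must start with '<' and end with '>'")
  }
  if (n == 2L) return("")
  paste(toks[2L:(n - 1L)], collapse = "")
}

.ob_props <- function(smiles) {
  # single-molecule OpenBabel property call; returns NULL on parse failure
  res <- tryCatch(
    ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL)
  if (is.null(res) || nrow(res) == 0L) return(NULL)
  res[1L, ]
}

# Strict syntactic pre-check: OpenBabel silently repairs some malformed
# strings (e.g. an unclosed branch "C(" parses as "C"), so delimiter balance
# and ring-bond pairing are enforced here before the parser is consulted.
.smiles_syntax_ok <- function(smiles) {
  if (!nzchar(smiles) || grepl("\\s", smiles)) return(FALSE)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_bracket <- FALSE
  ring <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_bracket) {
      if (ch == "[") return(FALSE)
      if (ch == "]") in_bracket <- FALSE
    } else if (ch == "[") {
      in_bracket <- TRUE
    } else if (ch == "]") {
      return(FALSE)
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste(chars[(i + 1L):(i + 2L)], collapse = "")))
        return(FALSE)
      d <- as.integer(paste(chars[(i + 1L):(i + 2L)], collapse = ""))
      ring <- if (d %in% ring) setdiff(ring, d) else c(ring, d)
      i <- i + 2L
    } else if (grepl("[0-9]", ch)) {
      d <- as.integer(ch)
      ring <- if (d %in% ring) setdiff(ring, d) else c(ring, d)
    }
    i <- i + 1L
  }
  !in_bracket && depth == 0L && length(ring) == 0L
}

#' Test whether strings are chemically valid SMILES
#'
#' A string is valid when it passes a strict syntactic check (balanced
#' branches and bracket atoms, paired ring-bond digits) and the OpenBabel
#' parser builds a molecule from it. Vectorized; never throws.
#'
#' @param smiles Character vector.
#' @return Logical vector of the same length.
#' @export
is_valid_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (!.smiles_syntax_ok(s)) return(FALSE)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    nzchar(trimws(out))
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Returns the OpenBabel canonical SMILES, or `NA` for strings that fail
#' [is_valid_smiles()].
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES (with `NA` for invalid input).
#' @export
canonical_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (!.smiles_syntax_ok(s)) return(NA_character_)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    out <- trimws(out)
    if (nzchar(out)) out else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Compute the condition descriptor triple for a molecule
#'
#' Molecular weight (Da), LogP (Crippen-type octanol/water partition
#' estimate), and TPSA (topological polar surface area, A^2), as computed by
#' the OpenBabel descriptor implementations. These three numbers form the
#' condition vector the generative model is conditioned on.
#'
#' @param smiles A single valid SMILES string.
#' @return Named numeric vector `c(mol_weight=, logp=, tpsa=)`.
#' @export
compute_conditions <- function(smiles) {
  if (length(smiles) != 1L) stop("compute_conditions takes a single SMILES string")
  if (!is_valid_smiles(smiles)) stop("cannot compute descriptors: invalid SMILES '", smiles, "'")
  p <- .ob_props(smiles)
  if (is.null(p)) stop("descriptor computation failed for '", smiles, "'")
  c(mol_weight = as.numeric(p$MW), logp = as.numeric(p$logP), tpsa = as.numeric(p$TPSA))
}

#' Compute condition triples for many molecules
#'
#' @param smiles Character vector of valid SMILES.
#' @return Data.frame with columns `mol_weight`, `logp`, `tpsa` (one row per
#'   input; `NA` rows for invalid strings).
#' @export
compute_conditions_batch <- function(smiles) {
  rows <- lapply(as.character(smiles), function(s) {
    if (!.smiles_syntax_ok(s)) return(c(NA_real_, NA_real_, NA_real_))
    p <- .ob_props(s)
    if (is.null(p)) return(c(NA_real_, NA_real_, NA_real_))
    c(as.numeric(p$MW), as.numeric(p$logP), as.numeric(p$TPSA))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("mol_weight", "logp", "tpsa")
  out
}

#' Filter a SMILES corpus for training
#'
#' Keeps records whose SMILES are valid, shorter than `max_length`
#' characters (strict), and whose molecular weight lies within
#' `[mw_min, mw_max]` (inclusive). Input order is preserved and the
#' operation is idempotent.
#'
#' @param records Data.frame with columns `id`, `smiles`.
#' @param max_length Maximum SMILES string length, exclusive. Default 100.
#' @param mw_min,mw_max Inclusive molecular-weight window in Da.
#'   Defaults 150 and 500.
#' @return The filtered data.frame (subset of the input rows).
#' @export
filter_corpus <- function(records, max_length = 100, mw_min = 150, mw_max = 500) {
  if (nrow(records) == 0L) return(records)
  keep_len <- nchar(records$smiles) < max_length
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    if (!keep_len[i]) next
    s <- records$smiles[i]
    if (!.smiles_syntax_ok(s)) next
    p <- .ob_props(s)
    if (is.null(p)) next
    mw <- as.numeric(p$MW)
    keep[i] <- mw >= mw_min && mw <= mw_max
  }
  records[keep, , drop = FALSE]
}

#' Condition-scaling statistics
#'
#' Per-descriptor mean and standard deviation over a corpus, used to z-score
#' condition vectors before they enter the model. Stored alongside model
#' weights so generation can scale a reference molecule's descriptors the
#' same way.
#'
#' @param conditions Data.frame from [compute_conditions_batch()].
#' @return List with numeric vectors `mean` and `sd` (names
#'   `mol_weight`, `logp`, `tpsa`). Zero standard deviations are replaced
#'   by 1 so constant descriptors scale to 0.
#' @export
condition_stats <- function(conditions) {
  cc <- conditions[stats::complete.cases(conditions), , drop = FALSE]
  if (nrow(cc) == 0L) stop("no complete condition rows")
  m <- vapply(cc, mean, numeric(1))
  s <- vapply(cc, stats::sd, numeric(1))
  s[!is.finite(s) | s == 0] <- 1
  list(mean = m, sd = s)
}

#' Z-score a condition vector
#'
#' @param cond Named numeric vector from [compute_conditions()].
#' @param stats List from [condition_stats()].
#' @return Numeric 3-vector of standardized descriptors.
#' @export
scale_conditions <- function(cond, stats) {
  as.numeric((cond[c("mol_weight", "logp", "tpsa")] -
                stats$mean[c("mol_weight", "logp", "tpsa")]) /
               stats$sd[c("mol_weight", "logp", "tpsa")])
}

#' Save a vocabulary as JSON
#' @param vocab A `smiles_vocabulary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(vocab$tokens, path)
  invisible(path)
}

#' Load a vocabulary from JSON
#' @param path Path written by [write_vocabulary()].
#' @return A `smiles_vocabulary`.
#' @export
read_vocabulary <- function(path) {
  tokens <- as.character(jsonlite::read_json(path, simplifyVector = TRUE))
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "smiles_vocabulary")
}
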