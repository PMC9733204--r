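# Run configuration: JSON or YAML files with every model/RL field,
# validated and filled with package defaults.

.config_defaults <- function() {
  list(
    corpus = NULL, checkpoint = NULL, output_dir = ".",
    reference_smiles = NULL,
    oracle = "mock",
    group_a = c("RAF1"), group_d = character(0),
    hidden_size = 512L, layers = 3L, stack_width = 50L, stack_depth = 10L,
    latent_dim = 128L, embedding_dim = 128L, max_len = 100L,
    use_stack = TRUE, learning_rate = 1e-3, batch_size = 64L, kl_weight = 1,
    pretrain_epochs = 10L,
    gamma = 0.1, rl_epochs = 500L, episodes_per_epoch = 32L,
    rl_learning_rate = 1e-3,
    window_tol = 0.10, on_threshold = 5, off_threshold = 5.5,
    property_weight = 0.3, affinity_weight = 0.7,
    n_generate = 1000L, top_k = 100L,
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a JSON (`.json`) or YAML (`.yml`/`.yaml`) file, fills every
#' missing field with the package default (3-layer model with 512 hidden
#' nodes, stack 50x10, discount rate 0.1, 500 RL epochs, 10 percent
#' property window, reward thresholds 5 and 5.5, score weights 0.3/0.7),
#' and validates the result, reporting every violated field at once.
#'
#' @param path Path to the config file; an empty file yields all defaults.
#' @return A list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  defaults <- .config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  cfg <- defaults
  for (nm in intersect(names(raw), names(defaults))) cfg[[nm]] <- raw[[nm]]
  for (nm in c("hidden_size", "layers", "stack_width", "stack_depth",
               "latent_dim", "embedding_dim", "max_len", "batch_size",
               "pretrain_epochs", "rl_epochs", "episodes_per_epoch",
               "n_generate", "top_k", "seed")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  for (nm in c("learning_rate", "kl_weight", "gamma", "rl_learning_rate",
               "window_tol", "on_threshold", "off_threshold",
               "property_weight", "affinity_weight")) {
    cfg[[nm]] <- as.numeric(cfg[[nm]])
  }
  for (nm in c("group_a", "group_d")) cfg[[nm]] <- as.character(unlist(cfg[[nm]]))
  problems <- character(0)
  if (length(unknown)) problems <- c(problems,
                                     paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  pos_fields <- c("hidden_size", "layers", "stack_width", "stack_depth",
                  "latent_dim", "embedding_dim", "max_len", "batch_size",
                  "episodes_per_epoch", "n_generate", "top_k")
  for (nm in pos_fields) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      problems <- c(problems, paste0(nm, " must be a positive integer"))
  }
  if (!is.numeric(cfg$gamma) || cfg$gamma <= 0 || cfg$gamma > 1)
    problems <- c(problems, "gamma must lie in (0, 1]")
  if (!is.numeric(cfg$window_tol) || cfg$window_tol <= 0)
    problems <- c(problems, "window_tol must be positive")
  if (!is.numeric(cfg$learning_rate) || cfg$learning_rate <= 0)
    problems <- c(problems, "learning_rate must be positive")
  if (!is.numeric(cfg$rl_learning_rate) || cfg$rl_learning_rate <= 0)
    problems <- c(problems, "rl_learning_rate must be positive")
  if (cfg$pretrain_epochs < 0L || cfg$rl_epochs < 0L)
    problems <- c(problems, "epoch counts must be non-negative")
  if (length(cfg$group_a) == 0L)
    problems <- c(problems, "group_a must name at least one on-target protein")
  if (length(problems)) stop("invalid configuration:\n  - ",
                             paste(problems, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' @param config A `run_config` (or plain list).
#' @param path Output path (`.json` or `.yml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

.model_config_from_run <- function(cfg) {
  model_config(hidden_size = cfg$hidden_size, layers = cfg$layers,
               stack_width = cfg$stack_width, stack_depth = cfg$stack_depth,
               latent_dim = cfg$latent_dim, embedding_dim = cfg$embedding_dim,
               max_len = cfg$max_len, use_stack = cfg$use_stack,
               learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
               kl_weight = cfg$kl_weight, seed = cfg$seed)
}

.rl_config_from_run <- function(cfg) {
  rl_config(gamma = cfg$gamma, epochs = cfg$rl_epochs,
            episodes_per_epoch = cfg$episodes_per_epoch,
            learning_rate = cfg$rl_learning_rate, max_len = cfg$max_len,
            seed = cfg$seed)
}
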