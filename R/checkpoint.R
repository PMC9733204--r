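# Model checkpoints: a directory holding the weights (RDS) plus a JSON
# manifest with the vocabulary, configuration, condition-scaling statistics
# and a format version, so a checkpoint is self-describing.

CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' @param model A `stack_cvae` model.
#' @param dir Directory to create/overwrite.
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # weights and scaling statistics go in the RDS payload so they round-trip
  # bit-for-bit; the manifest is the human/machine-readable description
  saveRDS(list(params = .get_params(model), cond_stats = model$cond_stats),
          file.path(dir, "weights.rds"))
  manifest <- list(format_version = CHECKPOINT_VERSION,
                   package_version = as.character(utils::packageVersion("stackcvae")),
                   vocabulary = model$vocab$tokens,
                   config = unclass(model$config),
                   cond_stats = lapply(model$cond_stats, as.list))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir Directory written by [save_checkpoint()].
#' @return The restored `stack_cvae` model.
#' @export
load_checkpoint <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  wpath <- file.path(dir, "weights.rds")
  if (!file.exists(mpath) || !file.exists(wpath))
    stop("not a checkpoint directory: ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (manifest$format_version > CHECKPOINT_VERSION)
    stop("checkpoint format version ", manifest$format_version,
         " is newer than this package supports")
  tokens <- as.character(manifest$vocabulary)
  vocab <- structure(list(tokens = tokens,
                          index = stats::setNames(seq_along(tokens), tokens)),
                     class = "smiles_vocabulary")
  cfg <- do.call(model_config, manifest$config[setdiff(names(manifest$config), NULL)])
  payload <- readRDS(wpath)
  model <- build_model(vocab, cfg, payload$cond_stats, seed = cfg$seed,
                       zero_init = TRUE)
  .set_params(model, payload$params)
}
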