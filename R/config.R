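## Run configuration: one YAML file drives generation, training, and
## provider selection. Unknown keys are rejected so that typos never pass
## silently, and the fully resolved configuration is itself valid input,
## which is what makes logged runs reproducible.

config_schema <- function() {
  list(
    seed = "scalar",
    generator = names(formals(generator_config)),
    split = c("n_train", "n_test"),
    train = names(formals(train_config)),
    provider = c("kind", "dim", "seed")
  )
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "))
  }
}

#' Read and resolve a run configuration file
#'
#' @param path YAML file with optional sections `seed`, `generator`, `split`,
#'   `train`, `provider`. Unknown keys anywhere are rejected. A top-level
#'   `seed` is inherited by sections that do not set their own.
#' @return A `run_config` list with fully resolved `generator`
#'   ([generator_config()]), `train` ([train_config()]), `split`, and
#'   `provider` entries.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  resolve_run_config(raw, where = path)
}

resolve_run_config <- function(raw, where = "config") {
  schema <- config_schema()
  check_keys(raw, names(schema), where)
  seed <- as.integer(raw$seed %||na% 1L)
  gen_args <- raw$generator %||na% list()
  check_keys(gen_args, setdiff(schema$generator, c("lexicons", "templates")), "generator")
  if (!is.null(gen_args$length_range)) gen_args$length_range <- unlist(gen_args$length_range)
  if (is.null(gen_args$seed)) gen_args$seed <- seed
  train_args <- raw$train %||na% list()
  check_keys(train_args, schema$train, "train")
  if (is.null(train_args$seed)) train_args$seed <- seed
  split <- raw$split %||na% list(n_train = 200L, n_test = 50L)
  check_keys(split, schema$split, "split")
  provider <- raw$provider %||na% list(kind = "trainable_lookup")
  check_keys(provider, schema$provider, "provider")
  structure(list(seed = seed,
                 generator = do.call(generator_config, gen_args),
                 train = do.call(train_config, train_args),
                 split = lapply(split, as.integer),
                 provider = provider),
            class = "run_config")
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Write the resolved configuration back to YAML
#'
#' The written file is a valid [read_run_config()] input reproducing the run.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  gen <- unclass(cfg$generator)
  gen$lexicons <- NULL; gen$templates <- NULL  # shipped defaults, not config
  yaml::write_yaml(list(seed = cfg$seed,
                        generator = gen,
                        split = cfg$split,
                        train = unclass(cfg$train),
                        provider = cfg$provider),
                   path)
  invisible(path)
}
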