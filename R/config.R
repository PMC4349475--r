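# Simulation configuration: defaults, validation, YAML/JSON loading.

#' Default simulation configuration (the baseline study profile)
#'
#' Baseline study conditions: founder networks of 22 core loci plus 3
#' environment loci; populations of 40 reduced to 10 survivors per selection
#' round; 1000 adaptation generations; hybridization of 80 hybrids every 20
#' generations with parent means over 40 individuals each; Poisson mutation
#' load of 0.3 events per genome per generation with equal operator weights;
#' Metropolis-Hastings selection at temperature 0.01.
#'
#' @param ... named overrides of any top-level field, of `gen` ([gen_params()]
#'   fields) or of `mutation` ([mutation_rates()] fields).
#' @return a validated configuration list (class `grn_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    gen = gen_params(),
    mutation = mutation_rates(),
    population_size = 40L,
    n_survivors = 10L,
    selection_temperature = 0.01,
    mh_steps = NULL,            # defaults to population_size
    n_adapt_generations = 1000L,
    hybridization_interval = 20L,
    n_hybrids = 80L,
    n_parent_sample = 40L,
    n_environments = 3L,
    n_mech_sample = 8L,
    collapse_delta = 0.2,
    collapse_k = 2L,
    master_seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% c("gen", "mutation")) next
    if (!nm %in% names(cfg)) stop("unknown configuration key: ", nm)
    cfg[[nm]] <- dots[[nm]]
  }
  if (!is.null(dots$gen)) cfg$gen <- do.call(gen_params, dots$gen)
  if (!is.null(dots$mutation)) cfg$mutation <- do.call(mutation_rates, dots$mutation)
  validate_config(cfg)
}

#' Validate a configuration list
#' @param cfg configuration list.
#' @return the validated configuration (class `grn_config`), with defaults in
#'   place for derived fields.
#' @export
validate_config <- function(cfg) {
  counts <- c("population_size", "n_survivors", "n_adapt_generations",
              "hybridization_interval", "n_hybrids", "n_parent_sample",
              "n_environments", "n_mech_sample", "collapse_k")
  zero_ok <- c("n_adapt_generations", "n_mech_sample")
  for (f in counts) {
    v <- cfg[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < (if (f %in% zero_ok) 0 else 1)) {
      stop("configuration field '", f, "' must be a positive count")
    }
    cfg[[f]] <- as.integer(v)
  }
  if (cfg$n_survivors > cfg$population_size) {
    stop("n_survivors (", cfg$n_survivors, ") must not exceed population_size (",
         cfg$population_size, ")")
  }
  if (!is.numeric(cfg$selection_temperature) || cfg$selection_temperature <= 0) {
    stop("selection_temperature must be positive")
  }
  if (!is.numeric(cfg$collapse_delta) || cfg$collapse_delta < 0) {
    stop("collapse_delta must be non-negative")
  }
  if (is.null(cfg$mh_steps)) cfg$mh_steps <- cfg$population_size
  if (!inherits(cfg$gen, "grn_genparams")) cfg$gen <- do.call(gen_params, cfg$gen)
  if (!inherits(cfg$mutation, "grn_mutation_rates")) {
    cfg$mutation <- do.call(mutation_rates, cfg$mutation)
  }
  cfg$master_seed <- as.integer(cfg$master_seed)
  class(cfg) <- "grn_config"
  cfg
}

#' Load a configuration file (YAML or JSON)
#'
#' Missing keys take their defaults from [default_config()]; unknown keys are
#' an error naming the key; invariants are validated. An empty file yields the
#' full default configuration.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`; YAML is a JSON superset, so
#'   JSON content parses regardless of extension).
#' @return a validated `grn_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known <- c("gen", "mutation", "population_size", "n_survivors",
             "selection_temperature", "mh_steps", "n_adapt_generations",
             "hybridization_interval", "n_hybrids", "n_parent_sample",
             "n_environments", "n_mech_sample", "collapse_delta", "collapse_k",
             "master_seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$gen)) raw$gen <- do.call(gen_params, as.list(raw$gen))
  if (!is.null(raw$mutation)) {
    m <- as.list(raw$mutation)
    if (!is.null(m$weights)) m$weights <- unlist(m$weights)
    raw$mutation <- do.call(mutation_rates, m)
  }
  cfg <- unclass(default_config())
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  validate_config(cfg)
}

#' Save a configuration as YAML
#' @param cfg a `grn_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$gen <- unclass(out$gen)
  out$gen$gate_probs <- as.list(out$gen$gate_probs)
  out$mutation <- list(lambda_per_genome = out$mutation$lambda,
                       weights = as.list(out$mutation$weights))
  yaml::write_yaml(out, path)
  invisible(path)
}
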