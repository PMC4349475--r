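# Fitness: attractor response scored against the ideal phenotype per
# environment, averaged over environments.

#' Construct an environment
#'
#' An environment is a specific combination of clamped states of the
#' environment nodes plus the module that must switch ON under it (all other
#' modules must switch OFF).
#'
#' @param env_id identifier.
#' @param clamp named logical vector over the genome's environment loci.
#' @param target_module module id (name in the `grn_modules` list).
#' @return object of class `grn_environment`.
#' @export
environment_spec <- function(env_id, clamp, target_module) {
  if (is.null(names(clamp)) || anyNA(clamp)) stop("clamp must be a named logical vector")
  structure(list(env_id = env_id, clamp = clamp, target_module = target_module),
            class = "grn_environment")
}

#' Default environment set: one-hot clamp vectors
#'
#' Environment k clamps the k-th environment node ON and the others OFF, and
#' targets module k. One-hot combinations maximize distinguishability between
#' the conditions the three modules must discriminate.
#'
#' @param env_loci character vector of environment locus ids.
#' @param module_ids character vector of module ids (same length).
#' @return list of `grn_environment` objects.
#' @export
default_environments <- function(env_loci, module_ids) {
  if (length(env_loci) != length(module_ids)) {
    stop("need one module per environment")
  }
  lapply(seq_along(env_loci), function(k) {
    clamp <- stats::setNames(seq_along(env_loci) == k, env_loci)
    environment_spec(paste0("E", k), clamp, module_ids[[k]])
  })
}

# Per-locus activity: a heterozygous locus contributes the mean of its two
# allele-node activities; loci lost from the genome contribute 0 (the module
# keeps its nominal size in the denominator).
locus_activity <- function(activity, net, locus) {
  ids <- net$locus_nodes[[locus]]
  if (is.null(ids)) return(0)
  mean(activity[ids])
}

#' Fitness of an attractor response in one environment
#'
#' Each module is summarized by the mean activity of its loci; the fitness is
#' the target module's value minus the mean value of the non-target modules,
#' giving a number between 1 (perfect response) and -1 (exactly the wrong
#' response). Modules emptied by gene loss score 0 with a warning.
#'
#' @param activity named activity vector from [attractor_activity()].
#' @param env a `grn_environment`.
#' @param modules a `grn_modules` object.
#' @param net the `grn_network` the activity was computed on (locus -> node map).
#' @return numeric fitness in [-1, 1].
#' @export
environment_fitness <- function(activity, env, modules, net) {
  vals <- vapply(names(modules), function(mid) {
    loci <- modules[[mid]]
    if (length(loci) == 0L) { warning("module ", mid, " is empty; value 0"); return(0) }
    mean(vapply(loci, function(L) locus_activity(activity, net, L), numeric(1)))
  }, numeric(1))
  others <- setdiff(names(modules), env$target_module)
  penalty <- if (length(others) > 0L) mean(vals[others]) else 0
  unname(vals[[env$target_module]] - penalty)
}

#' Overall fitness of a genome
#'
#' Builds the phenotype network once; for every environment, clamps the
#' environment nodes, finds the attractor from the standard all-OFF initial
#' state, averages node states over the attractor cycle, and scores the
#' response with [environment_fitness()]. The overall fitness is the
#' arithmetic mean over environments.
#'
#' @param genome a `grn_genome`.
#' @param envs list of `grn_environment` objects.
#' @param modules a `grn_modules` object.
#' @param net optional pre-built `grn_network` for `genome`.
#' @return object of class `grn_fitness`: `per_env` (named numeric) and
#'   `overall` (their mean), both in [-1, 1].
#' @export
overall_fitness <- function(genome, envs, modules, net = NULL) {
  if (length(envs) < 1L) stop("at least one environment is required")
  if (is.null(net)) {
    # fused fast path: bytecode emitted straight from the alleles
    per_env <- compiled_fitness(compile_genome(genome), envs, modules)
  } else {
    attr(net, "bytecode") <- compile_network(net)  # compile once, reuse per clamp
    per_env <- vapply(envs, function(env) {
      attr <- find_attractor(net, clamp = env$clamp)
      environment_fitness(attractor_activity(attr), env, modules, net)
    }, numeric(1))
    names(per_env) <- vapply(envs, function(e) as.character(e$env_id), character(1))
  }
  structure(list(per_env = per_env, overall = mean(per_env)),
            class = "grn_fitness")
}

#' @export
print.grn_fitness <- function(x, ...) {
  cat("Fitness:", format(x$overall, digits = 4), "\n")
  cat("  per environment:",
      paste(names(x$per_env), format(x$per_env, digits = 3), collapse = "  "), "\n")
  invisible(x)
}

# Scalar convenience used throughout evolution and mechanism scoring.
fitness_of <- function(genome, envs, modules) {
  mean(compiled_fitness(compile_genome(genome), envs, modules))
}
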