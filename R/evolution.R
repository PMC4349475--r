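# Population-level evolutionary algorithm: mutation, gamete formation, mating,
# Metropolis-Hastings selection, and the adaptation / divergence /
# hybrid-intercross experiments.

#' Mutation rate specification
#'
#' @param lambda_per_genome mean number of mutation events per genome per
#'   generation (Poisson); default 0.3.
#' @param weights named non-negative relative probabilities for the six
#'   mutation operators `edge_add`, `edge_delete`, `logic_rewrite`,
#'   `negate_input`, `duplicate_locus`, `delete_allele`; default equal.
#' @return object of class `grn_mutation_rates`.
#' @export
mutation_rates <- function(lambda_per_genome = 0.3,
                           weights = c(edge_add = 1, edge_delete = 1,
                                       logic_rewrite = 1, negate_input = 1,
                                       duplicate_locus = 1, delete_allele = 1)) {
  ops <- c("edge_add", "edge_delete", "logic_rewrite", "negate_input",
           "duplicate_locus", "delete_allele")
  if (lambda_per_genome < 0) stop("lambda_per_genome must be >= 0")
  w <- stats::setNames(rep(0, length(ops)), ops)
  w[names(weights)] <- weights
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative, not all zero")
  structure(list(lambda = lambda_per_genome, weights = w),
            class = "grn_mutation_rates")
}

# mutable slots: (locus, haplotype) pairs carrying an allele, env loci excluded
mutable_slots <- function(genome) {
  core <- genome_loci(genome, core = TRUE)
  out <- list()
  for (L in core) {
    for (h in c("m", "p")) {
      if (!is.null(genome$loci[[L]][[h]])) out[[length(out) + 1L]] <- c(L, h)
    }
  }
  out
}

# fresh locus id for a duplication, unique within the genome
new_locus_id <- function(genome) {
  repeat {
    id <- sprintf("d%06d", sample.int(999999L, 1L))
    if (!id %in% names(genome$loci)) return(id)
  }
}

apply_mutation_op <- function(genome, op, params) {
  slots <- mutable_slots(genome)
  if (length(slots) == 0L) return(NULL)
  pick <- slots[[sample.int(length(slots), 1L)]]
  L <- pick[[1]]; h <- pick[[2]]
  a <- genome$loci[[L]][[h]]
  if (op == "edge_add") {
    cand <- setdiff(names(genome$loci), a$inputs)
    if (length(cand) == 0L) return(NULL)
    v <- cand[[sample.int(length(cand), 1L)]]
    lit <- logic_var(v)
    if (stats::runif(1) < params$p_negate) lit <- logic_not(lit)
    gate <- sample(c("and", "or"), 1L,
                   prob = params$gate_probs[c("and", "or")])
    a$logic <- if (a$logic$type == "const") lit
               else if (gate == "and") logic_and(a$logic, lit)
               else logic_or(a$logic, lit)
    a$inputs <- sort(unique(c(a$inputs, v)))
  } else if (op == "edge_delete") {
    if (length(a$inputs) == 0L) return(NULL)
    v <- a$inputs[[sample.int(length(a$inputs), 1L)]]
    res <- logic_remove_var(a$logic, v)
    a$logic <- res %||% logic_const(stats::runif(1) < 0.5)
    a$inputs <- logic_vars(a$logic)
  } else if (op == "logic_rewrite") {
    k <- sample.int(logic_size(a$logic), 1L)
    sub <- logic_subtree(a$logic, k)
    vars <- logic_vars(sub)
    if (length(vars) == 0L && length(a$inputs) > 0L) {
      vars <- a$inputs[[sample.int(length(a$inputs), 1L)]]
    }
    a$logic <- logic_replace_subtree(a$logic, k,
                                     random_logic(vars, params$gate_probs, params$p_negate))
    a$inputs <- logic_vars(a$logic)
  } else if (op == "negate_input") {
    nv <- logic_count_vars(a$logic)
    if (nv == 0L) return(NULL)
    a$logic <- logic_toggle_not(a$logic, sample.int(nv, 1L))
  } else if (op == "duplicate_locus") {
    id <- new_locus_id(genome)
    dup <- a
    dup$locus <- id
    dup$lineage <- new_lineage_tag()
    slot <- list(m = NULL, p = NULL)
    slot[[h]] <- dup
    genome$loci[[id]] <- slot
    genome$loci <- genome$loci[order(names(genome$loci))]
    return(genome)
  } else if (op == "delete_allele") {
    genome$loci[[L]][[h]] <- NULL
    if (is.null(genome$loci[[L]]$m) && is.null(genome$loci[[L]]$p)) {
      genome$loci[[L]] <- NULL
    }
    return(genome)
  }
  # rebuild through the constructor: fresh lineage tag (content changed) and
  # re-derived canonical string / bytecode
  genome$loci[[L]][[h]] <- allele(L, a$logic, inputs = a$inputs,
                                  outputs = a$outputs, origin = a$origin)
  genome
}

#' Mutate a genome
#'
#' Draws the number of mutation events from Poisson(`lambda_per_genome`); each
#' event picks an operator by the configured weights and a uniformly random
#' target allele (environment loci excluded). Operators: gain a regulatory
#' input (wired into the logic via a random gate, possibly negated), lose an
#' input (structural removal from the logic), rewrite a random logic subtree,
#' toggle a NOT on one input occurrence, duplicate one allele into a fresh
#' hemizygous locus on the same haplotype, or delete one allele (the locus
#' disappears entirely when both haplotypes are empty). An operator that does
#' not apply to the drawn target is resampled (bounded retries). A mutated
#' allele receives a fresh lineage tag.
#'
#' @param genome a `grn_genome`.
#' @param rates a [mutation_rates()] object.
#' @param params a [gen_params()] object (gate templates for new logic).
#' @param refresh if `TRUE`, recompute the derived output lists afterwards.
#'   The evolutionary loop defers this (outputs are bookkeeping read only by
#'   exports, which refresh on demand).
#' @return the mutated `grn_genome`.
#' @export
mutate_genome <- function(genome, rates = mutation_rates(), params = gen_params(),
                          refresh = TRUE) {
  n_events <- stats::rpois(1L, rates$lambda)
  if (n_events == 0L) return(genome)
  ops <- names(rates$weights)
  changed <- FALSE
  for (ev in seq_len(n_events)) {
    for (try in 1:20) {
      op <- sample(ops, 1L, prob = rates$weights)
      res <- apply_mutation_op(genome, op, params)
      if (!is.null(res)) { genome <- res; changed <- TRUE; break }
    }
  }
  if (changed && refresh) genome <- refresh_outputs(genome)
  genome
}

#' Form a gamete by independent reassortment
#'
#' For each locus independently, the maternal or the paternal entry (allele or
#' absence) is inherited with probability 1/2.
#'
#' @param genome a `grn_genome`.
#' @return object of class `grn_gamete`: a named list of alleles (or `NULL`
#'   for absent) plus the environment locus ids.
#' @export
form_gamete <- function(genome) {
  loci <- names(genome$loci)
  take_m <- stats::runif(length(loci)) < 0.5
  alleles <- stats::setNames(vector("list", length(loci)), loci)
  for (i in seq_along(loci)) {
    slot <- genome$loci[[loci[[i]]]]
    chosen <- if (take_m[[i]]) slot$m else slot$p
    # assigning NULL would delete the element; absent entries stay NULL
    if (!is.null(chosen)) alleles[[i]] <- chosen
  }
  structure(list(alleles = alleles, env_loci = genome$env_loci),
            class = "grn_gamete")
}

#' Combine two gametes into a diploid genome
#'
#' The locus set is the union of the gametes' loci; the first gamete fills the
#' maternal slots, the second the paternal slots. A locus missing from one
#' gamete is hemizygous; a locus empty in both gametes is dropped.
#'
#' @param g1,g2 `grn_gamete` objects.
#' @return a `grn_genome`.
#' @export
mate_gametes <- function(g1, g2) {
  n1 <- names(g1$alleles)
  if (identical(n1, names(g2$alleles))) {
    loci <- n1  # common case: same locus set, already sorted
    a1 <- g1$alleles; a2 <- g2$alleles
  } else {
    loci <- sort(union(n1, names(g2$alleles)))
    a1 <- g1$alleles[loci]; a2 <- g2$alleles[loci]
    names(a1) <- names(a2) <- loci
  }
  out <- vector("list", length(loci))
  names(out) <- loci
  keep <- logical(length(loci))
  for (i in seq_along(loci)) {
    m <- a1[[i]]
    p <- a2[[i]]
    if (is.null(m) && is.null(p)) next  # locus lost from both gametes
    keep[[i]] <- TRUE
    out[[i]] <- list(m = m, p = p)
  }
  # gametes come from validated genomes, so the constructor checks are skipped
  structure(list(loci = out[keep], env_loci = sort(union(g1$env_loci, g2$env_loci))),
            class = "grn_genome")
}

#' Construct a population
#' @param individuals list of `grn_genome` objects.
#' @param generation generation index (default 0).
#' @return object of class `grn_population`.
#' @export
population <- function(individuals, generation = 0L) {
  structure(list(individuals = individuals, generation = as.integer(generation)),
            class = "grn_population")
}

#' Found a population from a single genome
#' @param founder a `grn_genome`.
#' @param size population size (default 40).
#' @return a `grn_population` of `size` identical individuals.
#' @export
founder_population <- function(founder, size = 40L) {
  population(rep(list(founder), size), generation = 0L)
}

#' @export
print.grn_population <- function(x, ...) {
  cat("Population of", length(x$individuals), "individuals, generation",
      x$generation, "\n")
  invisible(x)
}

#' Metropolis-Hastings survivor selection
#'
#' For each survivor slot an incumbent is drawn uniformly; `mh_steps` uniform
#' challengers are then proposed in turn, each accepted outright when at least
#' as fit, and otherwise with probability `exp((F_challenger - F_incumbent) /
#' temperature)`. The settled incumbent becomes the survivor. Low-fitness
#' individuals can therefore survive, with much lower probability; at equal
#' fitness selection is uniform.
#'
#' @param pop a `grn_population`.
#' @param fitnesses numeric vector of overall fitness per individual.
#' @param n_survivors number of survivors (default 10).
#' @param temperature positive selection temperature (default 0.01).
#' @param mh_steps proposals per survivor slot; defaults to the population size.
#' @return list of surviving `grn_genome`s, with the chosen indices in
#'   attribute `"indices"`.
#' @export
select_survivors <- function(pop, fitnesses, n_survivors = 10L,
                             temperature = 0.01, mh_steps = NULL) {
  n <- length(pop$individuals)
  if (length(fitnesses) != n) stop("one fitness per individual required")
  if (n_survivors > n) stop("n_survivors must not exceed the population size")
  if (!is.numeric(temperature) || temperature <= 0) stop("temperature must be positive")
  if (is.null(mh_steps)) mh_steps <- n
  idx <- integer(n_survivors)
  for (s in seq_len(n_survivors)) {
    i <- sample.int(n, 1L)
    for (step in seq_len(mh_steps)) {
      j <- sample.int(n, 1L)
      if (fitnesses[[j]] >= fitnesses[[i]] ||
          stats::runif(1) < exp((fitnesses[[j]] - fitnesses[[i]]) / temperature)) {
        i <- j
      }
    }
    idx[[s]] <- i
  }
  structure(pop$individuals[idx], indices = idx)
}

#' Advance a population by one generation
#'
#' Evaluates every individual's fitness, selects survivors by
#' [select_survivors()], and refills the population to its configured size:
#' each offspring mates one gamete from each of two distinct survivors
#' (uniform with replacement across offspring) and is then mutated.
#'
#' @param pop a `grn_population`.
#' @param study a `grn_study` (environments, modules, configuration).
#' @param fitnesses optional pre-computed fitness vector for `pop`.
#' @return list with `population` (the successor `grn_population`),
#'   `fitnesses` (of the input population) and `survivor_indices`.
#' @export
next_generation <- function(pop, study, fitnesses = NULL) {
  cfg <- study$config
  if (is.null(fitnesses)) {
    fitnesses <- vapply(pop$individuals, fitness_of, numeric(1),
                        envs = study$envs, modules = study$modules)
  }
  surv <- select_survivors(pop, fitnesses, n_survivors = cfg$n_survivors,
                           temperature = cfg$selection_temperature,
                           mh_steps = cfg$mh_steps)
  n_surv <- length(surv)
  rates <- cfg$mutation
  params <- cfg$gen
  offspring <- vector("list", cfg$population_size)
  for (k in seq_len(cfg$population_size)) {
    pair <- if (n_surv >= 2L) sample.int(n_surv, 2L) else c(1L, 1L)
    child <- mate_gametes(form_gamete(surv[[pair[[1]]]]),
                          form_gamete(surv[[pair[[2]]]]))
    offspring[[k]] <- mutate_genome(child, rates, params, refresh = FALSE)
  }
  list(population = population(offspring, pop$generation + 1L),
       fitnesses = fitnesses,
       survivor_indices = attr(surv, "indices"))
}

#' Evolve a population for a number of generations
#'
#' Iterates [next_generation()], recording mean/max/min population fitness per
#' generation (measured on the population entering each generation).
#'
#' @param pop a `grn_population`.
#' @param study a `grn_study`.
#' @param n_generations number of generations (>= 0).
#' @return list with `population` (final) and `record` (class
#'   `grn_run_record`, a data.frame with one row per generation:
#'   `generation`, `mean_fitness`, `max_fitness`, `min_fitness`).
#' @export
adapt <- function(pop, study, n_generations) {
  if (n_generations < 0) stop("n_generations must be >= 0")
  rec <- data.frame(generation = integer(0), mean_fitness = numeric(0),
                    max_fitness = numeric(0), min_fitness = numeric(0))
  for (g in seq_len(n_generations)) {
    step <- next_generation(pop, study)
    rec[nrow(rec) + 1L, ] <- list(pop$generation, mean(step$fitnesses),
                                  max(step$fitnesses), min(step$fitnesses))
    pop <- step$population
  }
  class(rec) <- c("grn_run_record", "data.frame")
  list(population = pop, record = rec)
}

#' @export
plot.grn_run_record <- function(x, ...) {
  graphics::plot(x$generation, x$mean_fitness, type = "l",
                 xlab = "generation", ylab = "mean population fitness",
                 ylim = c(-1, 1), ...)
  graphics::lines(x$generation, x$max_fitness, lty = 3)
  graphics::lines(x$generation, x$min_fitness, lty = 3)
  invisible(x)
}
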