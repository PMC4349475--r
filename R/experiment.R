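# Study setup, named RNG streams, and the headline experiments: adaptation,
# divergence with periodic hybridization, and hybrid intercrossing.

# Named RNG streams derived from one master seed. Each stream owns a saved
# .Random.seed; with_stream() swaps it in, runs code, and swaps it back out,
# so sampling on one stream (e.g. hybridization) cannot perturb another
# (e.g. a parent population's trajectory).
make_streams <- function(master_seed,
                         names = c("netgen", "adapt", "popA", "popB",
                                   "hybrid", "f2", "mech")) {
  env <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    set.seed((as.integer(master_seed) %% 1000000L) * 101L + i * 7919L)
    assign(names[[i]], get(".Random.seed", envir = globalenv()), envir = env)
  }
  env
}

with_stream <- function(streams, name, expr) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  outer <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
    assign(".Random.seed", outer, envir = globalenv())
  })
  expr
}

#' Set up a study: founder network, modules, environments
#'
#' Generates the founder scaffold, strips environment-node inputs, assigns
#' random logic (homozygous founder genome), detects the fitness modules, and
#' binds the default one-hot environments to them.
#'
#' @param config a [default_config()]-style configuration list.
#' @param seed optional seed overriding `config$master_seed` for network
#'   generation.
#' @return object of class `grn_study`: `config`, `scaffold`, `founder`
#'   (genome), `modules`, `envs`.
#' @export
grn_study <- function(config = default_config(), seed = NULL) {
  config <- validate_config(config)
  seed <- seed %||% config$master_seed
  if (!is.na(seed)) set.seed(seed)  # seed = NA: use the current RNG state
  # redraw scaffolds that do not split into enough communities (rare);
  # the RNG advances across attempts, so the draw is still seed-deterministic
  modules <- NULL
  for (attempt in 1:25) {
    scaffold <- generate_scaffold(config$gen)
    modules <- tryCatch(detect_modules(scaffold, k = config$n_environments),
                        error = function(e) NULL)
    if (!is.null(modules)) break
  }
  if (is.null(modules)) {
    stop("could not generate a scaffold with ", config$n_environments,
         " detectable modules in 25 attempts")
  }
  founder <- assign_logic(scaffold, config$gen)
  envs <- default_environments(scaffold$env, names(modules))
  structure(list(config = config, scaffold = scaffold, founder = founder,
                 modules = modules, envs = envs),
            class = "grn_study")
}

#' @export
print.grn_study <- function(x, ...) {
  cat("GRN evolution study\n")
  print(x$scaffold)
  print(x$modules)
  cat("  population", x$config$population_size, "->", x$config$n_survivors,
      "survivors; lambda =", x$config$mutation$lambda, "\n")
  invisible(x)
}

# Mean per-class mechanism sums over a sample of hybrids (see mechanisms.R).
hybrid_mechanism_means <- function(hybrids, study, n_sample) {
  n_sample <- min(n_sample, length(hybrids))
  if (n_sample == 0L) return(NULL)
  take <- sample.int(length(hybrids), n_sample)
  fit_fn <- function(g) fitness_of(g, study$envs, study$modules)
  sums <- lapply(hybrids[take], function(h) summarize_mechanisms(h, fit_fn)$sums)
  Reduce(`+`, sums) / n_sample
}

#' Divergence and hybridization experiment
#'
#' Starting from an adapted population, two initially identical copies evolve
#' independently with no interbreeding; every `hybridization_interval`
#' generations, `n_hybrids` hybrids are formed by mating one gamete from a
#' random individual of each population, their fitness (and optionally their
#' mechanism decomposition, on a subsample) is recorded, and the hybrids are
#' discarded — they never re-enter the parent populations. The two parent
#' trajectories and the hybrid sampling run on separate RNG streams, so the
#' parents evolve identically whether or not hybridization is measured.
#'
#' @param adapted a `grn_population` (typically the result of [adapt()]).
#' @param study a `grn_study`.
#' @param n_generations number of post-split generations.
#' @param streams internal: RNG stream environment.
#' @param mechanisms if `TRUE`, decompose a subsample of
#'   `config$n_mech_sample` hybrids per event into heterosis mechanisms.
#' @param keep_hybrids if `TRUE`, retain the hybrid genomes of every event.
#' @return object of class `grn_divergence`: `events` (data.frame: event
#'   index, generation, parent means over `n_parent_sample` individuals each,
#'   hybrid mean over `n_hybrids`, and mechanism class sums when requested),
#'   `hybrid_fitness` (list of raw per-event fitness vectors), `hybrids`
#'   (list of per-event genome lists, when kept), and the final parent
#'   populations `pop_a`, `pop_b`.
#' @export
run_divergence_experiment <- function(adapted, study, n_generations,
                                      streams = NULL, mechanisms = TRUE,
                                      keep_hybrids = FALSE) {
  cfg <- study$config
  streams <- streams %||% make_streams(cfg$master_seed)
  pop_a <- adapted
  pop_b <- adapted
  interval <- cfg$hybridization_interval
  events <- list()
  hybrid_fitness <- list()
  hybrid_store <- list()
  fit_fn <- function(g) fitness_of(g, study$envs, study$modules)
  for (g in seq_len(n_generations)) {
    pop_a <- with_stream(streams, "popA", next_generation(pop_a, study)$population)
    pop_b <- with_stream(streams, "popB", next_generation(pop_b, study)$population)
    if (g %% interval == 0L) {
      ev <- with_stream(streams, "hybrid", {
        na <- min(cfg$n_parent_sample, length(pop_a$individuals))
        nb <- min(cfg$n_parent_sample, length(pop_b$individuals))
        ia <- sample.int(length(pop_a$individuals), na)
        ib <- sample.int(length(pop_b$individuals), nb)
        fa <- vapply(pop_a$individuals[ia], fit_fn, numeric(1))
        fb <- vapply(pop_b$individuals[ib], fit_fn, numeric(1))
        hybrids <- lapply(seq_len(cfg$n_hybrids), function(k) {
          pa <- pop_a$individuals[[sample.int(length(pop_a$individuals), 1L)]]
          pb <- pop_b$individuals[[sample.int(length(pop_b$individuals), 1L)]]
          mate_gametes(form_gamete(pa), form_gamete(pb))
        })
        fh <- vapply(hybrids, fit_fn, numeric(1))
        list(fa = fa, fb = fb, fh = fh, hybrids = hybrids)
      })
      mech <- if (mechanisms) {
        with_stream(streams, "mech",
                    hybrid_mechanism_means(ev$hybrids, study, cfg$n_mech_sample))
      } else NULL
      row <- data.frame(event = length(events) + 1L, generation = g,
                        parent_a_mean = mean(ev$fa), parent_b_mean = mean(ev$fb),
                        hybrid_mean = mean(ev$fh))
      if (!is.null(mech)) row <- cbind(row, as.data.frame(as.list(mech)))
      events[[length(events) + 1L]] <- row
      hybrid_fitness[[length(hybrid_fitness) + 1L]] <- ev$fh
      if (keep_hybrids) hybrid_store[[length(hybrid_store) + 1L]] <- ev$hybrids
    }
  }
  events_df <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(event = integer(0), generation = integer(0),
               parent_a_mean = numeric(0), parent_b_mean = numeric(0),
               hybrid_mean = numeric(0))
  structure(list(events = events_df, hybrid_fitness = hybrid_fitness,
                 hybrids = if (keep_hybrids) hybrid_store else NULL,
                 pop_a = pop_a, pop_b = pop_b),
            class = "grn_divergence")
}

#' @export
print.grn_divergence <- function(x, ...) {
  cat("Divergence experiment:", nrow(x$events), "hybridization events\n")
  if (nrow(x$events) > 0L) print(utils::head(x$events, 10))
  invisible(x)
}

#' @export
plot.grn_divergence <- function(x, ...) {
  ev <- x$events
  graphics::plot(ev$generation, ev$hybrid_mean, type = "b", col = "darkgreen",
                 ylim = range(c(-1, 1)), xlab = "generations since split",
                 ylab = "mean fitness", ...)
  graphics::lines(ev$generation, ev$parent_a_mean, col = "red")
  graphics::lines(ev$generation, ev$parent_b_mean, col = "black")
  graphics::legend("bottomleft", c("hybrids", "parent A", "parent B"),
                   col = c("darkgreen", "red", "black"), lty = 1, bty = "n")
  invisible(x)
}

#' Intercross a hybrid population
#'
#' Starting from a set of hybrid genomes, evolves the closed hybrid population
#' (gamete formation, mating, mutation, selection among hybrid descendants
#' only) and records mean fitness per generation. The first entry of the
#' series is the founding hybrids' mean fitness.
#'
#' @param hybrids non-empty list of `grn_genome` objects.
#' @param study a `grn_study`.
#' @param n_follow number of intercross generations to follow.
#' @return data.frame (`grn_run_record`): `generation` (0 = founding hybrids),
#'   `mean_fitness`, `max_fitness`, `min_fitness`.
#' @export
cross_hybrid_generation <- function(hybrids, study, n_follow) {
  if (length(hybrids) == 0L) stop("hybrid list must be non-empty")
  study$config$population_size <- length(hybrids)
  study$config$n_survivors <- min(study$config$n_survivors, length(hybrids))
  pop <- population(hybrids, generation = 0L)
  f0 <- vapply(hybrids, fitness_of, numeric(1),
               envs = study$envs, modules = study$modules)
  rec <- data.frame(generation = 0L, mean_fitness = mean(f0),
                    max_fitness = max(f0), min_fitness = min(f0))
  if (n_follow > 0L) {
    res <- adapt(pop, study, n_follow)
    r <- res$record
    # adapt() records fitness of the population entering each generation;
    # its first row duplicates the founding measurement, so drop it and add
    # a final measurement of the last population.
    if (nrow(r) > 1L) {
      r2 <- r[-1L, , drop = FALSE]
      r2$generation <- seq_len(nrow(r2))
      rec <- rbind(rec, r2)
    }
    ff <- vapply(res$population$individuals, fitness_of, numeric(1),
                 envs = study$envs, modules = study$modules)
    rec <- rbind(rec, data.frame(generation = n_follow, mean_fitness = mean(ff),
                                 max_fitness = max(ff), min_fitness = min(ff)))
  }
  class(rec) <- c("grn_run_record", "data.frame")
  rec
}

#' One-call adaptation + divergence run
#'
#' Convenience wrapper reproducing the full experimental protocol: found a
#' homozygous population from the study's founder genome, adapt it for
#' `config$n_adapt_generations`, duplicate it, and run the divergence /
#' hybridization phase for `n_divergence_generations`.
#'
#' @param config configuration list (see [default_config()]).
#' @param n_divergence_generations post-split generations (default
#'   `config$n_adapt_generations`).
#' @param ... passed to [run_divergence_experiment()].
#' @return list with `study`, `adaptation` (record), and `divergence`
#'   (`grn_divergence`).
#' @export
run_full_experiment <- function(config = default_config(),
                                n_divergence_generations = NULL, ...) {
  config <- validate_config(config)
  streams <- make_streams(config$master_seed)
  study <- with_stream(streams, "netgen", grn_study(config, seed = NA))
  adapted <- with_stream(streams, "adapt", {
    pop <- founder_population(study$founder, config$population_size)
    adapt(pop, study, config$n_adapt_generations)
  })
  n_div <- n_divergence_generations %||% config$n_adapt_generations
  div <- run_divergence_experiment(adapted$population, study, n_div,
                                   streams = streams, ...)
  list(study = study, adaptation = adapted$record, divergence = div)
}
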