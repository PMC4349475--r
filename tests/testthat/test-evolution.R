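# Mutation, gamete formation, mating, selection, generation cycle.

# five-locus genome in which every allele has at least one input
chain_genome <- function() {
  mk_genome(list(g1 = "(g5 OR g2)", g2 = "(g1 AND g3)", g3 = "(NOT g2)",
                 g4 = "(g3 OR (NOT g1))", g5 = "g4"),
            env_loci = "e1")
}

test_that("a zero mutation load returns the genome unchanged", {
  genome <- chain_genome()
  expect_identical(mutate_genome(genome, mutation_rates(0)), genome)
})

test_that("mutation operators preserve genome integrity", {
  params <- gen_params()
  set.seed(15)
  ops <- c("edge_add", "edge_delete", "logic_rewrite", "negate_input",
           "duplicate_locus", "delete_allele")
  genome <- random_genome(n_core = 8, n_env = 2)
  for (i in 1:300) {
    op <- sample(ops, 1)
    res <- heterosim:::apply_mutation_op(genome, op, params)
    if (is.null(res)) next
    for (L in names(res$loci)) {
      slot <- res$loci[[L]]
      expect_false(is.null(slot$m) && is.null(slot$p))
      for (h in c("m", "p")) {
        a <- slot[[h]]
        if (is.null(a)) next
        expect_true(all(logic_vars(a$logic) %in% a$inputs))
        expect_identical(a$canon, logic_to_string(a$logic))
      }
    }
    expect_true(all(res$env_loci %in% names(res$loci)))
    genome <- res
  }
})

test_that("duplication adds exactly one hemizygous locus", {
  genome <- chain_genome()
  set.seed(8)
  res <- heterosim:::apply_mutation_op(genome, "duplicate_locus", gen_params())
  expect_identical(length(res$loci), length(genome$loci) + 1L)
  new_locus <- setdiff(names(res$loci), names(genome$loci))
  expect_length(new_locus, 1)
  slot <- res$loci[[new_locus]]
  expect_true(xor(is.null(slot$m), is.null(slot$p)))
  dup <- slot$m %||% slot$p
  expect_identical(dup$locus, new_locus)
})

test_that("allele deletion empties a haplotype and removes doubly absent loci", {
  genome <- chain_genome()
  set.seed(3)
  res <- heterosim:::apply_mutation_op(genome, "delete_allele", gen_params())
  hemi <- Filter(function(L) is.null(res$loci[[L]]$m) || is.null(res$loci[[L]]$p),
                 names(res$loci))
  expect_length(hemi, 1)
  # delete the remaining allele at the same locus: the locus disappears
  h_left <- if (is.null(res$loci[[hemi]]$m)) "p" else "m"
  res2 <- remove_allele(res, hemi, h_left)
  expect_false(hemi %in% names(res2$loci))
})

test_that("mutation event counts follow the configured Poisson load", {
  genome <- chain_genome()
  # negation always applies here (every allele has inputs), so the genome is
  # unchanged exactly when zero events are drawn: P(unchanged) = exp(-lambda)
  rates <- mutation_rates(0.3, weights = c(negate_input = 1))
  set.seed(1234)
  n <- 3000
  unchanged <- 0L
  for (i in seq_len(n)) {
    # zero events returns the input unmodified; any negation changes a canon
    if (identical(mutate_genome(genome, rates), genome)) unchanged <- unchanged + 1L
  }
  p <- exp(-0.3)
  se <- sqrt(n * p * (1 - p))
  expect_lt(abs(unchanged - n * p), 3 * se)
})

test_that("gametes reassort independently and uniformly", {
  genome <- mk_genome(list(), env_loci = "e1",
                      het = list(x = c("TRUE", "FALSE"),
                                 y = c("TRUE", "FALSE"),
                                 z = c("TRUE", "FALSE")))
  key <- function(gam) paste(vapply(c("x", "y", "z"), function(L) {
    gam$alleles[[L]]$canon
  }, character(1)), collapse = "")
  set.seed(55)
  draws <- character(8000)
  for (i in seq_along(draws)) draws[[i]] <- key(form_gamete(genome))
  counts <- table(draws)
  expect_length(counts, 8)
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 0.001)
})

test_that("a hemizygous locus transmits its allele half the time", {
  loci <- list(x = list(m = mk_allele("x", "TRUE"), p = NULL),
               y = list(m = mk_allele("y", "FALSE"), p = mk_allele("y", "FALSE")))
  genome <- diploid_genome(loci)
  set.seed(66)
  n <- 10000
  carried <- 0L
  for (i in seq_len(n)) {
    if (!is.null(form_gamete(genome)$alleles[["x"]])) carried <- carried + 1L
  }
  se <- sqrt(n * 0.25)
  expect_lt(abs(carried - n / 2), 3 * se)
})

test_that("selfing a gamete yields a fully homozygous genome with the haploid dynamics", {
  set.seed(19)
  genome <- random_genome(n_core = 8, n_env = 2, churn = 8)
  gam <- form_gamete(genome)
  selfed <- mate_gametes(gam, gam)
  expect_length(heterozygous_loci(selfed), 0)
  net <- build_phenotype_network(selfed)
  expect_length(net$nodes, length(selfed$loci))
})

test_that("mating unions loci across gametes with hemizygosity where unmatched", {
  g1 <- structure(list(alleles = list(a = mk_allele("a", "TRUE"),
                                      d1 = mk_allele("d1", "FALSE")),
                       env_loci = character(0)), class = "grn_gamete")
  g2 <- structure(list(alleles = list(a = mk_allele("a", "TRUE"),
                                      d2 = mk_allele("d2", "TRUE")),
                       env_loci = character(0)), class = "grn_gamete")
  child <- mate_gametes(g1, g2)
  expect_setequal(names(child$loci), c("a", "d1", "d2"))
  expect_true(is.null(child$loci$d1$p))
  expect_true(is.null(child$loci$d2$m))
  # a locus empty in both gametes is dropped
  g3 <- structure(list(alleles = list(a = mk_allele("a", "TRUE"), q = NULL),
                       env_loci = character(0)), class = "grn_gamete")
  g4 <- structure(list(alleles = list(a = mk_allele("a", "TRUE"), q = NULL),
                       env_loci = character(0)), class = "grn_gamete")
  expect_identical(names(mate_gametes(g3, g4)$loci), "a")
})

test_that("selection is uniform at equal fitness", {
  pop <- population(as.list(1:20))
  set.seed(31)
  counts <- integer(20)
  for (trial in 1:1000) {
    surv <- select_survivors(pop, rep(0.5, 20), n_survivors = 10,
                             temperature = 0.1, mh_steps = 5)
    idx <- attr(surv, "indices")
    counts[idx] <- counts[idx] + 1L
  }
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 0.001)
})

test_that("at low temperature the fittest individual is almost always kept", {
  pop <- population(as.list(1:25))
  fitnesses <- c(1, rep(-1, 24))
  set.seed(40)
  hits <- 0L
  for (trial in 1:300) {
    surv <- select_survivors(pop, fitnesses, n_survivors = 10,
                             temperature = 1e-6)
    if (1L %in% attr(surv, "indices")) hits <- hits + 1L
  }
  expect_gte(hits / 300, 0.99)
})

test_that("survivor counts and temperature validation follow the contract", {
  pop <- population(as.list(1:40))
  surv <- select_survivors(pop, stats::runif(40), n_survivors = 10)
  expect_length(surv, 10)
  expect_error(select_survivors(pop, stats::runif(40), n_survivors = 50),
               "exceed")
  expect_error(select_survivors(pop, stats::runif(40), temperature = 0),
               "positive")
  expect_error(select_survivors(pop, stats::runif(10), n_survivors = 5),
               "one fitness per individual")
})

test_that("a generation restores the configured population size", {
  cfg <- default_config(n_adapt_generations = 5L)
  set.seed(77)
  study <- grn_study(cfg, seed = 13)
  pop <- founder_population(study$founder, cfg$population_size)
  step <- next_generation(pop, study)
  expect_length(step$population$individuals, 40)
  expect_identical(step$population$generation, 1L)
  expect_length(step$fitnesses, 40)
})

test_that("generations are bit-reproducible under a fixed seed", {
  cfg <- default_config()
  study <- grn_study(cfg, seed = 14)
  pop <- founder_population(study$founder, 20)
  study$config$population_size <- 20L
  snap <- function() {
    set.seed(555)
    p <- pop
    for (i in 1:3) p <- next_generation(p, study)$population
    lapply(p$individuals, function(g) vapply(g$loci, function(s) {
      paste(s$m$canon %||% "-", s$p$canon %||% "-")
    }, character(1)))
  }
  expect_identical(snap(), snap())
})

test_that("without variation a generation leaves mean fitness unchanged", {
  study <- grn_study(default_config(), seed = 15)
  study$config$mutation <- mutation_rates(0)
  pop <- founder_population(study$founder, 40)
  set.seed(3)
  step1 <- next_generation(pop, study)
  step2 <- next_generation(step1$population, study)
  expect_equal(mean(step1$fitnesses), mean(step2$fitnesses))
})

test_that("adapt honors degenerate and contractual cases", {
  study <- grn_study(default_config(), seed = 16)
  pop <- founder_population(study$founder, 10)
  study$config$population_size <- 10L
  study$config$n_survivors <- 4L
  set.seed(1)
  res0 <- adapt(pop, study, 0)
  expect_identical(res0$population, pop)
  expect_identical(nrow(res0$record), 0L)
  res5 <- adapt(pop, study, 5)
  expect_identical(nrow(res5$record), 5L)
  expect_identical(res5$record$generation, 0:4)
})

test_that("mutation preserves origin tags and evolution cannot mix lineages", {
  study <- grn_study(default_config(), seed = 18)
  study$config$population_size <- 12L
  study$config$n_survivors <- 4L
  popA <- tag_origin(founder_population(study$founder, 12), "A")
  set.seed(10)
  for (i in 1:3) popA <- next_generation(popA, study)$population
  tags <- unique(unlist(lapply(popA$individuals, origin_tags)))
  expect_identical(tags, "A")
  # a hybrid of differently tagged parents carries both origins
  popB <- tag_origin(founder_population(study$founder, 12), "B")
  hyb <- mate_gametes(form_gamete(popA$individuals[[1]]),
                      form_gamete(popB$individuals[[1]]))
  expect_setequal(origin_tags(hyb), c("A", "B"))
})

test_that("divergence records events on schedule and parents ignore hybrid sampling", {
  cfg <- default_config(population_size = 16L, n_survivors = 5L,
                        hybridization_interval = 10L, n_hybrids = 8L,
                        n_parent_sample = 8L, n_mech_sample = 2L,
                        master_seed = 42L)
  study <- grn_study(cfg, seed = 20)
  pop <- founder_population(study$founder, 16)
  fingerprint <- function(p) lapply(p$individuals, function(g) {
    vapply(g$loci, function(s) paste(s$m$canon %||% "-", s$p$canon %||% "-"),
           character(1))
  })
  run <- function(mech) {
    streams <- heterosim:::make_streams(42L)
    run_divergence_experiment(pop, study, 30, streams = streams,
                              mechanisms = mech)
  }
  d1 <- run(FALSE)
  expect_identical(d1$events$generation, c(10L, 20L, 30L))
  expect_true(all(lengths(d1$hybrid_fitness) == 8L))
  # hybrid mechanism scoring must not perturb the parent trajectories
  d2 <- run(TRUE)
  expect_identical(fingerprint(d1$pop_a), fingerprint(d2$pop_a))
  expect_identical(fingerprint(d1$pop_b), fingerprint(d2$pop_b))
  expect_identical(d1$events$hybrid_mean, d2$events$hybrid_mean)
  # and the whole experiment is reproducible from the seed
  d3 <- run(FALSE)
  expect_identical(d1$events, d3$events)
})

test_that("hybrids of identical populations match the parent mean", {
  cfg <- default_config(population_size = 12L, n_survivors = 4L,
                        hybridization_interval = 40L)
  study <- grn_study(cfg, seed = 21)
  pop <- founder_population(study$founder, 12)
  set.seed(5)
  for (i in 1:10) pop <- next_generation(pop, study)$population
  fit <- vapply(pop$individuals, heterosim:::fitness_of, numeric(1),
                envs = study$envs, modules = study$modules)
  hyb <- replicate(60, {
    pa <- pop$individuals[[sample.int(12, 1)]]
    pb <- pop$individuals[[sample.int(12, 1)]]
    heterosim:::fitness_of(mate_gametes(form_gamete(pa), form_gamete(pb)),
                           study$envs, study$modules)
  })
  expect_lt(abs(mean(hyb) - mean(fit)), 0.15)
})

test_that("hybrid intercross series start at the founding mean and stay flat without variation", {
  study <- grn_study(default_config(), seed = 22)
  study$config$mutation <- mutation_rates(0)
  study$config$n_survivors <- 4L
  gam <- form_gamete(study$founder)
  hybrids <- rep(list(mate_gametes(gam, gam)), 10)
  set.seed(2)
  s0 <- cross_hybrid_generation(hybrids, study, 0)
  expect_identical(nrow(s0), 1L)
  expect_identical(s0$generation, 0L)
  s3 <- cross_hybrid_generation(hybrids, study, 3)
  expect_true(all(abs(s3$mean_fitness - s3$mean_fitness[[1]]) < 1e-12))
  expect_error(cross_hybrid_generation(list(), study, 3), "non-empty")
})
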