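# Fixtures and independent oracles built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Allele from a canonical logic string.
mk_allele <- function(locus, logic_str, inputs = NULL) {
  expr <- logic_from_string(logic_str)
  if (is.null(inputs)) allele(locus, expr) else allele(locus, expr, inputs = inputs)
}

# Homozygous genome from named logic strings; env loci get constant markers.
mk_genome <- function(logic_strs, env_loci = character(0), het = list()) {
  loci <- list()
  for (L in names(logic_strs)) {
    a <- mk_allele(L, logic_strs[[L]])
    loci[[L]] <- list(m = a, p = a)
  }
  for (e in env_loci) {
    a <- mk_allele(e, "FALSE")
    loci[[e]] <- list(m = a, p = a)
  }
  # het: named list locus -> c(maternal logic, paternal logic)
  for (L in names(het)) {
    loci[[L]] <- list(m = mk_allele(L, het[[L]][[1]]),
                      p = mk_allele(L, het[[L]][[2]]))
  }
  diploid_genome(loci, env_loci = env_loci)
}

# Bare phenotype network from logic strings (bypasses genomes) for dynamics
# unit tests.
mk_net <- function(logic_strs, clamped = character(0)) {
  nodes <- names(logic_strs)
  structure(list(
    nodes = nodes,
    logic = lapply(logic_strs, logic_from_string),
    clamped = nodes %in% clamped,
    env_loci = clamped,
    locus_nodes = stats::setNames(as.list(nodes), nodes)
  ), class = "grn_network")
}

named_state <- function(net, ...) {
  vals <- c(...)
  stats::setNames(as.logical(vals), net$nodes)
}

# Independent brute-force oracle: full state-transition-graph analysis.
# Evaluates each node's logic directly with eval_logic (no reliance on
# find_attractor or the compiled engine) over the complete state space of the
# non-clamped nodes, then follows the trajectory from `initial`.
brute_force_attractor <- function(net, initial) {
  nodes <- net$nodes
  free <- nodes[!net$clamped]
  step_fun <- function(state) {
    out <- state
    for (v in free) out[[v]] <- eval_logic(net$logic[[v]], state)
    out
  }
  n_free <- length(free)
  key <- function(s) paste0(as.integer(s[nodes]), collapse = "")
  # full transition map over all 2^n_free states (clamped part fixed by initial)
  trans <- new.env(parent = emptyenv())
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n_free))
  for (r in seq_len(nrow(grid))) {
    s <- initial
    s[free] <- unlist(grid[r, ])
    assign(key(s), step_fun(s), envir = trans)
  }
  # follow trajectory from initial through the precomputed map
  seen <- new.env(parent = emptyenv())
  s <- initial
  hist <- list()
  i <- 0L
  repeat {
    k <- key(s)
    first <- get0(k, envir = seen, ifnotfound = NULL)
    if (!is.null(first)) {
      cyc <- hist[(first + 1L):i]
      states <- do.call(rbind, lapply(cyc, function(x) x[nodes]))
      colnames(states) <- nodes
      return(list(states = states, period = i - first, transient = first))
    }
    assign(k, i, envir = seen)
    hist[[i + 1L]] <- s
    s <- get(key(s), envir = trans)
    i <- i + 1L
  }
}

# Random small genome: founder from a random scaffold, optionally churned by
# mutation to introduce heterozygosity, duplications and losses.
random_genome <- function(n_core = 8, n_env = 2, churn = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- gen_params(n_core = n_core, n_env = n_env, m = 2, p_triad = 0.4)
  g <- assign_logic(generate_scaffold(params), params)
  if (churn > 0) {
    for (i in seq_len(churn)) g <- mutate_genome(g, mutation_rates(1.5), params)
  }
  g
}

# Cycle states of an attractor as a canonical set of strings (rotation- and
# label-independent comparison).
cycle_set <- function(att) {
  sort(apply(att$states[, sort(colnames(att$states)), drop = FALSE], 1,
             function(r) paste0(as.integer(r), collapse = "")))
}
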