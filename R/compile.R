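# Fused genome -> bytecode compilation for the fitness hot path.
#
# Produces the same dynamics as build_phenotype_network() + compile_network():
# one node per allele after homozygote collapsing, heterozygous references
# expanded to (L::m OR L::p) at emission time, absent-locus references emitted
# as constant OFF. Agreement with the structural path is covered by tests.

compile_genome <- function(genome) {
  slots <- genome$loci
  loci <- names(slots)
  n_loci <- length(loci)
  het <- logical(n_loci)
  first_node <- integer(n_loci)   # node index of locus i (first of two if het)
  node_alleles <- vector("list", 2L * n_loci)
  node <- 0L
  for (i in seq_len(n_loci)) {
    slot <- slots[[i]]
    m <- slot$m; p <- slot$p
    first_node[[i]] <- node + 1L
    if (!is.null(m) && !is.null(p) &&
        !identical(m$lineage, p$lineage) &&
        !(m$canon == p$canon && identical(m$inputs, p$inputs))) {
      het[[i]] <- TRUE
      node_alleles[[node + 1L]] <- m
      node_alleles[[node + 2L]] <- p
      node <- node + 2L
    } else {
      node <- node + 1L
      node_alleles[[node]] <- if (is.null(m)) p else m
    }
  }
  n_nodes <- node
  node_alleles <- node_alleles[seq_len(n_nodes)]
  node_ids <- character(n_nodes)
  node_ids[first_node] <- loci
  if (any(het)) {
    hi <- first_node[het]
    node_ids[hi] <- paste0(loci[het], "::m")
    node_ids[hi + 1L] <- paste0(loci[het], "::p")
  }
  clamped <- logical(n_nodes)
  env_idx <- match(genome$env_loci, loci)
  env_node <- stats::setNames(first_node[env_idx], genome$env_loci)
  clamped[env_node] <- TRUE

  codes <- lapply(node_alleles, function(a) a$code)
  # one global match over all input lists, split back per node
  inputs_list <- lapply(node_alleles, function(a) a$inputs)
  lens <- lengths(inputs_list)
  flat <- match(unlist(inputs_list, use.names = FALSE), loci, nomatch = 0L)
  ends <- cumsum(lens)
  imaps <- vector("list", n_nodes)
  for (k in seq_len(n_nodes)) {
    imaps[[k]] <- if (lens[[k]] == 0L) integer(0)
                  else flat[(ends[[k]] - lens[[k]] + 1L):ends[[k]]]
  }
  bc <- assemble_genome_cpp(codes, imaps, first_node, het, clamped)

  locus_nodes <- stats::setNames(vector("list", n_loci), loci)
  for (i in seq_len(n_loci)) {
    locus_nodes[[i]] <- if (het[[i]]) c(first_node[[i]], first_node[[i]] + 1L)
                        else first_node[[i]]
  }
  list(nodes = node_ids, op = bc$op, arg = bc$arg,
       off = bc$off, len = bc$len, clamped = clamped, env_node = env_node,
       locus_nodes = locus_nodes)
}

# Per-environment fitness from a compiled genome; identical scoring to
# overall_fitness() through the structural path.
compiled_fitness <- function(cg, envs, modules) {
  n <- length(cg$nodes)
  # module aggregation: locus value = mean of its node activities, absent = 0
  mod_idx <- lapply(modules, function(mloci) {
    idx <- integer(0); w <- numeric(0)
    for (L in mloci) {
      nd <- cg$locus_nodes[[L]]
      if (is.null(nd)) next
      idx <- c(idx, nd); w <- c(w, rep(1 / length(nd), length(nd)))
    }
    list(idx = idx, w = w / length(mloci))
  })
  mod_names <- names(modules)
  inits <- matrix(FALSE, nrow = length(envs), ncol = n)
  for (e in seq_along(envs)) {
    inits[e, cg$env_node[names(envs[[e]]$clamp)]] <- envs[[e]]$clamp
  }
  act <- attractor_activity_cpp(cg$op, cg$arg, cg$off, cg$len, cg$clamped, inits)
  per_env <- numeric(length(envs))
  for (e in seq_along(envs)) {
    activity <- act[e, ]
    vals <- vapply(mod_idx, function(mi) sum(activity[mi$idx] * mi$w), numeric(1))
    ti <- match(envs[[e]]$target_module, mod_names)
    target <- vals[[ti]]
    others <- vals[-ti]
    per_env[[e]] <- target - (if (length(others)) sum(others) / length(others) else 0)
  }
  names(per_env) <- vapply(envs, function(e) as.character(e$env_id), character(1))
  per_env
}
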