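# Founder network generation: directed preferential attachment with triad
# formation, environment-node stripping, random logic assignment, and module
# detection.

#' Network generation parameters
#'
#' @param n_core number of regular (gene) loci; default 22.
#' @param n_env number of environment loci (outgoing connections only); default 3.
#' @param m out-edges added per new node; default 2.
#' @param p_triad probability that an edge is placed by directed triad
#'   formation (targeting an out-neighbor of the previous target) rather than
#'   by preferential attachment; in [0,1], default 0.6.
#' @param gate_probs probabilities of the AND/OR gate templates used when
#'   random logic is assigned.
#' @param p_negate probability that an input enters a random logic function
#'   negated.
#' @return object of class `grn_genparams`.
#' @export
gen_params <- function(n_core = 22L, n_env = 3L, m = 2L, p_triad = 0.6,
                       gate_probs = c(and = 0.5, or = 0.5), p_negate = 0.25) {
  n_core <- as.integer(n_core); n_env <- as.integer(n_env); m <- as.integer(m)
  gate_probs <- unlist(gate_probs)
  if (!all(c("and", "or") %in% names(gate_probs))) stop("gate_probs needs 'and' and 'or'")
  if (is.na(n_core) || n_core < 1L) stop("n_core must be >= 1")
  if (is.na(n_env) || n_env < 0L) stop("n_env must be >= 0")
  if (is.na(m) || m < 1L) stop("m must be >= 1")
  if (!is.numeric(p_triad) || p_triad < 0 || p_triad > 1) stop("p_triad must be in [0,1]")
  if (!is.numeric(p_negate) || p_negate < 0 || p_negate > 1) stop("p_negate must be in [0,1]")
  structure(list(n_core = n_core, n_env = n_env, m = m, p_triad = p_triad,
                 gate_probs = gate_probs, p_negate = p_negate),
            class = "grn_genparams")
}

new_scaffold <- function(nodes, edges, env) {
  structure(list(nodes = nodes,
                 edges = data.frame(from = as.character(edges$from),
                                    to = as.character(edges$to),
                                    stringsAsFactors = FALSE),
                 env = env),
            class = "grn_scaffold")
}

#' Generate a founder network scaffold
#'
#' Directed adaptation of growth by preferential attachment with triad
#' formation. Nodes are added one at a time; each new node places `m`
#' out-edges. The first edge targets an existing node with probability
#' proportional to in-degree + 1; each subsequent edge, with probability
#' `p_triad`, instead targets a random out-neighbor of the previous target
#' (closing a directed triad), falling back to preferential attachment when no
#' such neighbor is available. The last `n_env` nodes added are designated
#' environment nodes; because edges always point from the newest node to older
#' ones, environment nodes end with out-going connections only.
#'
#' @param params a [gen_params()] object.
#' @param seed optional integer seed; when supplied the generation is
#'   reproducible.
#' @return object of class `grn_scaffold`: node ids (`g1`, `g2`, ... for core
#'   loci, `e1`, ... for environment loci), a directed edge list
#'   (regulator -> target), and the environment-node id set.
#' @export
generate_scaffold <- function(params = gen_params(), seed = NULL) {
  stopifnot(inherits(params, "grn_genparams"))
  if (!is.null(seed)) set.seed(seed)
  n_total <- params$n_core + params$n_env
  core_ids <- paste0("g", seq_len(params$n_core))
  env_ids <- if (params$n_env > 0L) paste0("e", seq_len(params$n_env)) else character(0)
  # environment nodes are the last nodes added
  nodes <- c(core_ids, env_ids)
  m <- params$m
  n_seed <- min(m, n_total)
  from <- character(0); to <- character(0)
  if (n_total > n_seed) {
    indeg <- stats::setNames(integer(n_total), nodes)
    out_nb <- stats::setNames(vector("list", n_total), nodes)
    for (i in (n_seed + 1L):n_total) {
      new <- nodes[[i]]
      existing <- nodes[seq_len(i - 1L)]
      n_edges <- min(m, length(existing))
      chosen <- character(0)
      prev <- NULL
      for (e in seq_len(n_edges)) {
        target <- NULL
        if (e > 1L && !is.null(prev) && stats::runif(1) < params$p_triad) {
          cand <- setdiff(out_nb[[prev]], c(chosen, new))
          if (length(cand) > 0L) target <- cand[[sample.int(length(cand), 1L)]]
        }
        if (is.null(target)) {
          cand <- setdiff(existing, chosen)
          w <- indeg[cand] + 1
          target <- cand[[sample.int(length(cand), 1L, prob = w)]]
        }
        chosen <- c(chosen, target)
        from <- c(from, new); to <- c(to, target)
        indeg[[target]] <- indeg[[target]] + 1L
        out_nb[[new]] <- c(out_nb[[new]], target)
        prev <- target
      }
    }
  }
  sc <- new_scaffold(nodes, data.frame(from = from, to = to, stringsAsFactors = FALSE),
                     env_ids)
  strip_environment_inputs(sc)
}

#' Erase incoming connections of environment nodes
#'
#' Environment nodes represent externally clamped factors; any in-edges they
#' acquired during network creation are erased while their out-going
#' connections are retained. Idempotent; scaffolds without environment nodes
#' are returned unchanged.
#'
#' @param scaffold a `grn_scaffold`.
#' @return the stripped `grn_scaffold`.
#' @export
strip_environment_inputs <- function(scaffold) {
  stopifnot(inherits(scaffold, "grn_scaffold"))
  keep <- !(scaffold$edges$to %in% scaffold$env)
  scaffold$edges <- scaffold$edges[keep, , drop = FALSE]
  rownames(scaffold$edges) <- NULL
  scaffold
}

scaffold_in_neighbors <- function(scaffold, node) {
  sort(unique(scaffold$edges$from[scaffold$edges$to == node]))
}

scaffold_out_neighbors <- function(scaffold, node) {
  sort(unique(scaffold$edges$to[scaffold$edges$from == node]))
}

#' Convert a scaffold to an igraph object
#' @param scaffold a `grn_scaffold`.
#' @return a directed `igraph` graph with a logical `env` vertex attribute.
#' @export
scaffold_to_igraph <- function(scaffold) {
  g <- igraph::graph_from_data_frame(scaffold$edges, directed = TRUE,
                                     vertices = data.frame(name = scaffold$nodes))
  igraph::V(g)$env <- scaffold$nodes %in% scaffold$env
  g
}

#' Assign random logic, producing the homozygous founder genome
#'
#' Every non-environment locus receives an allele whose input list is its
#' in-neighbor set in the scaffold, whose output list is its out-neighbor set,
#' and whose logic is a random AND/OR/NOT expression referencing exactly its
#' inputs ([random_logic()]). Input-free core loci receive a constant function
#' whose value is drawn at creation. Environment loci receive input-free
#' marker alleles (their state is clamped, never computed). Both haplotypes
#' carry identical alleles: the founder is fully homozygous.
#'
#' @param scaffold a stripped `grn_scaffold`.
#' @param params a [gen_params()] object (gate template probabilities).
#' @param seed optional integer seed.
#' @return a homozygous `grn_genome`.
#' @export
assign_logic <- function(scaffold, params = gen_params(), seed = NULL) {
  stopifnot(inherits(scaffold, "grn_scaffold"))
  if (!is.null(seed)) set.seed(seed)
  loci <- list()
  for (v in scaffold$nodes) {
    if (v %in% scaffold$env) {
      a <- allele(v, logic_const(FALSE), inputs = character(0),
                  outputs = scaffold_out_neighbors(scaffold, v))
    } else {
      ins <- scaffold_in_neighbors(scaffold, v)
      a <- allele(v, random_logic(ins, params$gate_probs, params$p_negate),
                  inputs = ins, outputs = scaffold_out_neighbors(scaffold, v))
    }
    loci[[v]] <- list(m = a, p = a)
  }
  diploid_genome(loci, env_loci = scaffold$env)
}

#' Detect fitness modules in a scaffold
#'
#' Modules are highly interconnected subsets of non-environment loci; each one
#' is later tied to an environment in which it must switch ON. Detection is
#' greedy modularity maximization (igraph `cluster_fast_greedy`) on the
#' undirected simplified projection of the core subgraph. The `k` largest
#' communities become the modules, ties broken by smallest member id; loci
#' outside those communities belong to no module.
#'
#' @param scaffold a `grn_scaffold`.
#' @param k number of modules; default 3.
#' @return object of class `grn_modules`: a named list (`M1` ... `Mk`) of
#'   disjoint, non-empty character vectors of locus ids.
#' @export
detect_modules <- function(scaffold, k = 3L) {
  stopifnot(inherits(scaffold, "grn_scaffold"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  core <- setdiff(scaffold$nodes, scaffold$env)
  if (length(core) < k) stop("scaffold has fewer than k non-environment loci")
  g <- scaffold_to_igraph(scaffold)
  g <- igraph::induced_subgraph(g, core)
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g)
  comm <- igraph::cluster_fast_greedy(g)
  memb <- igraph::membership(comm)
  groups <- split(names(memb), memb)
  if (length(groups) < k) {
    stop("only ", length(groups), " communities found; ", k, " modules requested")
  }
  sizes <- vapply(groups, length, integer(1))
  min_id <- vapply(groups, function(x) min(x), character(1))
  ord <- order(-sizes, min_id)
  mods <- groups[ord[seq_len(k)]]
  mods <- lapply(mods, function(x) sort(x))
  names(mods) <- paste0("M", seq_len(k))
  structure(mods, class = "grn_modules")
}

#' @export
print.grn_scaffold <- function(x, ...) {
  cat("GRN scaffold:", length(x$nodes), "nodes (", length(x$env),
      "environment ),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' @export
print.grn_modules <- function(x, ...) {
  cat("Fitness modules:\n")
  for (nm in names(x)) cat(" ", nm, ":", paste(x[[nm]], collapse = " "), "\n")
  invisible(x)
}

#' Export a scaffold as GraphML or TSV edge list
#'
#' GraphML records environment status (and, if given, module membership) as
#' node attributes; the TSV format is a two-column `from<TAB>to` edge list.
#'
#' @param scaffold a `grn_scaffold`.
#' @param path output file path.
#' @param format `"graphml"` or `"tsv"`.
#' @param modules optional `grn_modules` recorded as a node attribute.
#' @return `path`, invisibly.
#' @export
export_scaffold <- function(scaffold, path, format = c("graphml", "tsv"),
                            modules = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(scaffold$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = c("from", "to"))
  } else {
    g <- scaffold_to_igraph(scaffold)
    mod <- rep(NA_character_, length(scaffold$nodes))
    if (!is.null(modules)) {
      for (nm in names(modules)) mod[scaffold$nodes %in% modules[[nm]]] <- nm
    }
    igraph::V(g)$module <- mod
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a scaffold from a GraphML file written by [export_scaffold()]
#' @param path GraphML file path.
#' @return a `grn_scaffold`.
#' @export
import_scaffold <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(g)$name
  env <- nodes[as.logical(igraph::V(g)$env)]
  el <- igraph::as_edgelist(g)
  new_scaffold(nodes, data.frame(from = el[, 1], to = el[, 2]), env)
}
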