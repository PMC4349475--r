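# Phenotype networks and synchronous Boolean dynamics.

#' Build the executable phenotype network of a diploid genome
#'
#' Homozygous (and hemizygous) loci are represented by a single node,
#' heterozygous loci by two nodes (`<locus>::m`, `<locus>::p`); two identical
#' alleles have the same effect on the dynamics as one, so collapsing them
#' changes nothing. Every logic reference to a heterozygous locus `L` is
#' rewritten as `(L::m OR L::p)` — a node receiving input from a heterozygous
#' regulator receives input from both its alleles through an OR-gate.
#' References to loci absent from the genome evaluate as constant OFF.
#' Environment loci become clamped nodes with no effective update rule.
#'
#' @param genome a `grn_genome`.
#' @return object of class `grn_network`: node ids, per-node rewritten logic,
#'   the clamped (environment) node set, and a locus -> node map.
#' @export
build_phenotype_network <- function(genome) {
  stopifnot(inherits(genome, "grn_genome"))
  loci <- names(genome$loci)
  zyg <- vapply(loci, function(L) locus_zygosity(genome, L), character(1))
  # reference substitution map: locus id -> expression over node ids
  subs <- list()
  node_ids <- character(0)
  node_allele <- list()
  locus_nodes <- list()
  for (L in loci) {
    slot <- genome$loci[[L]]
    if (zyg[[L]] == "het") {
      ids <- paste0(L, c("::m", "::p"))
      subs[[L]] <- logic_or(logic_var(ids[[1]]), logic_var(ids[[2]]))
      node_ids <- c(node_ids, ids)
      node_allele[[ids[[1]]]] <- slot$m
      node_allele[[ids[[2]]]] <- slot$p
      locus_nodes[[L]] <- ids
    } else {
      subs[[L]] <- logic_var(L)
      node_ids <- c(node_ids, L)
      node_allele[[L]] <- slot$m %||% slot$p
      locus_nodes[[L]] <- L
    }
  }
  logic <- vector("list", length(node_ids))
  names(logic) <- node_ids
  for (nid in node_ids) {
    a <- node_allele[[nid]]
    logic[[nid]] <- logic_substitute_total(a$logic, subs)
  }
  structure(list(nodes = node_ids, logic = logic,
                 clamped = node_ids %in% genome$env_loci,
                 env_loci = genome$env_loci, locus_nodes = locus_nodes),
            class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat("Phenotype network:", length(x$nodes), "nodes (",
      sum(x$clamped), "clamped )\n")
  invisible(x)
}

#' One synchronous update of a network state
#'
#' All non-clamped nodes are assigned their logic evaluated on the previous
#' state simultaneously; clamped (environment) nodes keep their state. Pure-R
#' reference semantics for the compiled engine used by [find_attractor()].
#'
#' @param net a `grn_network`.
#' @param state named logical vector over `net$nodes`.
#' @return the successor state (named logical vector).
#' @export
synchronous_step <- function(net, state) {
  stopifnot(inherits(net, "grn_network"))
  if (!all(net$nodes %in% names(state))) stop("state must cover every node")
  new <- state
  for (i in seq_along(net$nodes)) {
    if (net$clamped[[i]]) next
    nid <- net$nodes[[i]]
    new[[nid]] <- eval_logic(net$logic[[nid]], state)
  }
  new
}

#' Default initial state for attractor search
#'
#' All non-clamped nodes OFF; environment nodes at their clamp values. With
#' deterministic synchronous updating this convention makes the phenotype a
#' pure function of genome and environment.
#'
#' @param net a `grn_network`.
#' @param clamp named logical vector over the environment loci.
#' @return named logical vector over `net$nodes`.
#' @export
initial_state <- function(net, clamp = NULL) {
  s <- stats::setNames(rep(FALSE, length(net$nodes)), net$nodes)
  if (!is.null(clamp)) s[names(clamp)] <- clamp
  s
}

# Compile a network's logic to postfix bytecode for the C++ stack machine.
# Opcodes: 1 LOAD(arg = node index), 2 CONST(arg = 0/1), 3 NOT, 4 AND, 5 OR.
compile_network <- function(net) {
  if (!is.null(attr(net, "bytecode"))) return(attr(net, "bytecode"))
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  op <- integer(0); arg <- integer(0)
  emit <- function(expr) {
    switch(expr$type,
      var = { op[[length(op) + 1L]] <<- 1L; arg[[length(arg) + 1L]] <<- idx[[expr$name]] },
      const = { op[[length(op) + 1L]] <<- 2L; arg[[length(arg) + 1L]] <<- as.integer(expr$value) },
      not = { emit(expr$a); op[[length(op) + 1L]] <<- 3L; arg[[length(arg) + 1L]] <<- 0L },
      and = { emit(expr$a); emit(expr$b); op[[length(op) + 1L]] <<- 4L; arg[[length(arg) + 1L]] <<- 0L },
      or = { emit(expr$a); emit(expr$b); op[[length(op) + 1L]] <<- 5L; arg[[length(arg) + 1L]] <<- 0L }
    )
  }
  off <- integer(length(net$nodes)); len <- integer(length(net$nodes))
  for (i in seq_along(net$nodes)) {
    off[[i]] <- length(op)
    if (net$clamped[[i]]) { len[[i]] <- 0L; next }
    emit(net$logic[[net$nodes[[i]]]])
    len[[i]] <- length(op) - off[[i]]
  }
  list(op = op, arg = arg, off = off, len = len)
}

#' Find the attractor reached from an initial state
#'
#' Iterates synchronous updates until a previously visited state recurs; the
#' deterministic map on a finite state space guarantees termination. Uses a
#' compiled stack-machine engine (C++) with hash-based cycle detection;
#' `engine = "r"` runs the pure-R [synchronous_step()] instead.
#'
#' @param net a `grn_network`.
#' @param initial named logical vector over `net$nodes`; defaults to
#'   [initial_state()] (all OFF) with `clamp` applied.
#' @param clamp named logical vector over environment loci giving their fixed
#'   states.
#' @param engine `"compiled"` (default) or `"r"`.
#' @return object of class `grn_attractor`: `states` (logical matrix, one row
#'   per cycle state, columns named by node), `period`, `transient`.
#' @export
find_attractor <- function(net, initial = NULL, clamp = NULL,
                           engine = "compiled") {
  if (!engine %in% c("compiled", "r")) stop("engine must be 'compiled' or 'r'")
  if (is.null(initial)) initial <- initial_state(net, clamp)
  if (!is.null(clamp)) initial[names(clamp)] <- clamp
  initial <- initial[net$nodes]
  if (anyNA(initial)) stop("initial state must cover every node")
  if (engine == "compiled") {
    bc <- compile_network(net)
    res <- attractor_run_cpp(bc$op, bc$arg, bc$off, bc$len,
                             net$clamped, unname(initial))
    states <- res$states
    colnames(states) <- net$nodes
    attr_obj <- list(states = states, period = nrow(states),
                     transient = res$transient)
  } else {
    seen <- new.env(parent = emptyenv())
    history <- list()
    s <- initial
    step <- 0L
    repeat {
      key <- paste0(as.integer(s[net$nodes]), collapse = "")
      prev <- get0(key, envir = seen, ifnotfound = NULL)
      if (!is.null(prev)) {
        cyc <- history[(prev + 1L):step]
        states <- do.call(rbind, lapply(cyc, function(x) x[net$nodes]))
        colnames(states) <- net$nodes
        attr_obj <- list(states = states, period = step - prev, transient = prev)
        break
      }
      assign(key, step, envir = seen)
      history[[step + 1L]] <- s
      s <- synchronous_step(net, s)
      step <- step + 1L
    }
  }
  structure(attr_obj, class = "grn_attractor")
}

#' Per-node activity of an attractor
#'
#' Mean state of each node over the attractor's cycle states (transient
#' excluded): 0/1 for fixed points, fractional for cyclic attractors.
#'
#' @param attractor a `grn_attractor`.
#' @return named numeric vector in [0,1].
#' @export
attractor_activity <- function(attractor) {
  colMeans(attractor$states)
}

#' @export
print.grn_attractor <- function(x, ...) {
  cat("Attractor: period", x$period, ", transient", x$transient, "\n")
  invisible(x)
}

#' Export a phenotype network as GraphML
#'
#' Edges are realized from each node's rewritten logic (regulator -> target);
#' canonical logic strings are stored as node attributes.
#'
#' @param net a `grn_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_network_graphml <- function(net, path) {
  from <- character(0); to <- character(0)
  for (nid in net$nodes) {
    if (net$clamped[[match(nid, net$nodes)]]) next
    for (v in logic_vars(net$logic[[nid]])) { from <- c(from, v); to <- c(to, nid) }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = net$nodes))
  igraph::V(g)$clamped <- net$clamped
  igraph::V(g)$logic <- vapply(net$nodes, function(nid) {
    if (net$clamped[[match(nid, net$nodes)]]) "" else logic_to_string(net$logic[[nid]])
  }, character(1))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
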