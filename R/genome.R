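# Alleles and diploid genomes.

#' Construct an allele
#'
#' An allele is the heritable description of one locus: the loci it can
#' receive inputs from, the loci it can output to (derived bookkeeping), and
#' the Boolean logic expression assigning the node's state. Two alleles are
#' the "same allele" when their canonical logic strings and input sets match
#' (a shared lineage tag short-circuits the comparison).
#'
#' @param locus locus id (character scalar).
#' @param logic logic expression tree; its variables must be a subset of `inputs`.
#' @param inputs character vector of regulator locus ids. Defaults to the
#'   variable set of `logic`.
#' @param outputs character vector of target locus ids (derived bookkeeping).
#' @param lineage unique tag identifying this allele's creation event.
#' @param origin optional population tag (used to audit gene flow).
#' @return object of class `grn_allele`.
#' @export
allele <- function(locus, logic, inputs = logic_vars(logic), outputs = character(0),
                   lineage = NULL, origin = NA_character_) {
  vars <- logic_vars(logic)
  if (!all(vars %in% inputs)) {
    stop("allele at locus '", locus, "': logic references non-input loci: ",
         paste(setdiff(vars, inputs), collapse = ", "))
  }
  inputs <- sort(unique(inputs))
  structure(
    list(locus = locus, inputs = inputs, outputs = sort(unique(outputs)),
         logic = logic, canon = logic_to_string(logic),
         code = compile_logic(logic, inputs),
         lineage = lineage %||% new_lineage_tag(), origin = origin),
    class = "grn_allele"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fresh lineage tag drawn from the current RNG stream (deterministic under seed).
new_lineage_tag <- function() {
  sprintf("a%08d", sample.int(99999999L, 1L))
}

#' Test whether two alleles are the same allele
#'
#' Equal lineage tags imply equality; otherwise equality is structural:
#' identical canonical logic strings and identical input sets. Output lists are
#' derived within a genome and do not enter the comparison.
#'
#' @param a,b `grn_allele` objects (or `NULL` for an absent allele).
#' @return logical scalar.
#' @export
allele_equal <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  if (!is.null(a$lineage) && identical(a$lineage, b$lineage)) return(TRUE)
  ca <- a$canon %||% logic_to_string(a$logic)
  cb <- b$canon %||% logic_to_string(b$logic)
  identical(ca, cb) && identical(a$inputs, b$inputs)
}

#' Construct a diploid genome
#'
#' @param loci named list; each element is `list(m = <allele or NULL>,
#'   p = <allele or NULL>)` with at least one allele present.
#' @param env_loci character vector of environment locus ids; these loci must
#'   carry input-free alleles on both haplotypes and are clamped during
#'   dynamics.
#' @return object of class `grn_genome`.
#' @export
diploid_genome <- function(loci, env_loci = character(0)) {
  for (L in names(loci)) {
    slot <- loci[[L]]
    if (is.null(slot$m) && is.null(slot$p)) {
      stop("locus '", L, "' has no allele on either haplotype")
    }
    for (h in c("m", "p")) {
      a <- slot[[h]]
      if (!is.null(a) && L %in% env_loci && length(a$inputs) > 0L) {
        stop("environment locus '", L, "' must carry input-free alleles")
      }
    }
  }
  if (!all(env_loci %in% names(loci))) stop("env_loci must be listed in loci")
  structure(list(loci = loci[order(names(loci))], env_loci = sort(env_loci)),
            class = "grn_genome")
}

#' Locus ids of a genome
#' @param genome a `grn_genome`.
#' @param core if `TRUE`, exclude environment loci.
#' @return character vector.
#' @export
genome_loci <- function(genome, core = FALSE) {
  ids <- names(genome$loci)
  if (core) setdiff(ids, genome$env_loci) else ids
}

# Zygosity of one locus: "hom" (two equal alleles), "het" (two distinct),
# "hemi" (one allele), used when building the phenotype network.
locus_zygosity <- function(genome, locus) {
  slot <- genome$loci[[locus]]
  if (is.null(slot)) stop("no such locus: ", locus)
  if (is.null(slot$m) || is.null(slot$p)) return("hemi")
  if (allele_equal(slot$m, slot$p)) "hom" else "het"
}

#' Heterozygous loci of a genome
#'
#' A locus is heterozygous when both haplotypes carry an allele and the two
#' alleles differ (by [allele_equal()]). Hemizygous loci (one allele absent)
#' are not counted.
#'
#' @param genome a `grn_genome`.
#' @return character vector of locus ids.
#' @export
heterozygous_loci <- function(genome) {
  ids <- genome_loci(genome, core = TRUE)
  ids[vapply(ids, function(L) locus_zygosity(genome, L) == "het", logical(1))]
}

# Recompute every allele's output list from the input lists across the genome:
# allele at locus L outputs to all loci that list L among their inputs (on
# either haplotype). Output lists are bookkeeping only; dynamics are governed
# by input lists and logic.
refresh_outputs <- function(genome) {
  loci <- names(genome$loci)
  srcs <- vector("list", 2L * length(loci))
  tgts <- vector("list", 2L * length(loci))
  k <- 0L
  for (L in loci) {
    for (h in c("m", "p")) {
      a <- genome$loci[[L]][[h]]
      if (is.null(a) || length(a$inputs) == 0L) next
      k <- k + 1L
      srcs[[k]] <- a$inputs
      tgts[[k]] <- rep(L, length(a$inputs))
    }
  }
  outs <- split(unlist(tgts[seq_len(k)]), unlist(srcs[seq_len(k)]))
  for (L in loci) {
    out <- if (is.null(outs[[L]])) character(0) else sort(unique(outs[[L]]))
    for (h in c("m", "p")) {
      if (!is.null(genome$loci[[L]][[h]])) genome$loci[[L]][[h]]$outputs <- out
    }
  }
  genome
}

#' Remove one allele, producing the corresponding homozygote
#'
#' Deleting the maternal (paternal) allele at a heterozygous locus yields the
#' network homozygous for the paternal (maternal) allele; used by the
#' dominance/epistasis decomposition. If the other haplotype is absent the
#' locus disappears from the genome.
#'
#' @param genome a `grn_genome`.
#' @param locus locus id.
#' @param haplotype `"m"` or `"p"`.
#' @return a new `grn_genome`; the input is untouched.
#' @export
remove_allele <- function(genome, locus, haplotype = c("m", "p")) {
  haplotype <- match.arg(haplotype)
  slot <- genome$loci[[locus]]
  if (is.null(slot)) stop("no such locus: ", locus)
  if (is.null(slot[[haplotype]])) {
    stop("allele already absent at locus '", locus, "' haplotype '", haplotype, "'")
  }
  other <- setdiff(c("m", "p"), haplotype)
  remaining <- slot[[other]]
  if (is.null(remaining)) {
    genome$loci[[locus]] <- NULL
    genome$env_loci <- setdiff(genome$env_loci, locus)
  } else {
    genome$loci[[locus]] <- list(m = remaining, p = remaining)
  }
  genome
}

#' Tag every allele of a population or genome with an origin label
#'
#' Lineage audit aid: after tagging each parent population, hybrid genomes can
#' be checked for which population each allele came from, and the
#' no-gene-flow invariant of the divergence experiment can be verified.
#'
#' @param x a `grn_genome` or `grn_population`.
#' @param tag character scalar.
#' @return object of the same class with `origin` set on every allele.
#' @export
tag_origin <- function(x, tag) {
  if (inherits(x, "grn_population")) {
    x$individuals <- lapply(x$individuals, tag_origin, tag = tag)
    return(x)
  }
  for (L in names(x$loci)) {
    for (h in c("m", "p")) {
      if (!is.null(x$loci[[L]][[h]])) x$loci[[L]][[h]]$origin <- tag
    }
  }
  x
}

#' Origin tags present in a genome
#' @param genome a `grn_genome`.
#' @return character vector of distinct non-missing origin tags.
#' @export
origin_tags <- function(genome) {
  tags <- unlist(lapply(genome$loci, function(slot) {
    c(if (!is.null(slot$m)) slot$m$origin, if (!is.null(slot$p)) slot$p$origin)
  }))
  sort(unique(tags[!is.na(tags)]))
}

#' @export
print.grn_genome <- function(x, ...) {
  core <- genome_loci(x, core = TRUE)
  het <- heterozygous_loci(x)
  cat("Diploid Boolean GRN genome\n")
  cat("  loci:", length(core), "core +", length(x$env_loci), "environment\n")
  cat("  heterozygous loci:", length(het), "\n")
  invisible(x)
}
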