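# Snapshot / restore: genomes and populations as JSON (logic in the canonical
# string grammar), run manifests, CSV logs.

GENOME_SCHEMA_VERSION <- 1L

allele_to_list <- function(a) {
  if (is.null(a)) return(NULL)
  list(locus = a$locus, inputs = as.list(a$inputs), outputs = as.list(a$outputs),
       logic = logic_to_string(a$logic), lineage = a$lineage,
       origin = if (is.na(a$origin)) NULL else a$origin)
}

allele_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  allele(locus = x$locus, logic = logic_from_string(x$logic),
         inputs = unlist(x$inputs) %||% character(0),
         outputs = unlist(x$outputs) %||% character(0),
         lineage = x$lineage, origin = x$origin %||% NA_character_)
}

genome_to_list <- function(genome) {
  list(schema_version = GENOME_SCHEMA_VERSION,
       env_loci = as.list(genome$env_loci),
       loci = lapply(genome$loci, function(slot) {
         list(m = allele_to_list(slot$m), p = allele_to_list(slot$p))
       }))
}

genome_from_list <- function(x) {
  if (is.null(x$schema_version) || x$schema_version != GENOME_SCHEMA_VERSION) {
    stop("genome schema version mismatch: expected ", GENOME_SCHEMA_VERSION,
         ", found ", x$schema_version %||% "none")
  }
  loci <- lapply(x$loci, function(slot) {
    list(m = allele_from_list(slot$m), p = allele_from_list(slot$p))
  })
  diploid_genome(loci, env_loci = unlist(x$env_loci) %||% character(0))
}

#' Write / read a genome as JSON
#'
#' Logic expressions are serialized in the canonical parenthesized grammar of
#' [logic_to_string()]; a restored genome reproduces identical fitness values.
#' A schema-version mismatch or truncated file raises an error without
#' producing a partial object.
#'
#' @param genome a `grn_genome`.
#' @param path file path.
#' @return `path` invisibly (write); a `grn_genome` (read).
#' @export
write_genome_json <- function(genome, path) {
  genome <- refresh_outputs(genome)  # bring derived output lists up to date
  jsonlite::write_json(genome_to_list(genome), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_genome_json
#' @export
read_genome_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  genome_from_list(x)
}

#' Write / read a population as JSON
#' @param pop a `grn_population`.
#' @param path file path.
#' @return `path` invisibly (write); a `grn_population` (read).
#' @export
write_population_json <- function(pop, path) {
  jsonlite::write_json(
    list(schema_version = GENOME_SCHEMA_VERSION, generation = pop$generation,
         individuals = lapply(pop$individuals,
                              function(g) genome_to_list(refresh_outputs(g)))),
    path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_population_json
#' @export
read_population_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$schema_version) || x$schema_version != GENOME_SCHEMA_VERSION) {
    stop("population schema version mismatch")
  }
  population(lapply(x$individuals, genome_from_list),
             generation = x$generation %||% 0L)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, package version, master seed, and an
#' inventory (with MD5 checksums) of the run's output files — enough to
#' re-execute the run bit-identically.
#'
#' @param cfg a `grn_config`.
#' @param files character vector of output file paths.
#' @param path manifest output path (JSON).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, files, path) {
  cfg_plain <- unclass(cfg)
  cfg_plain$gen <- unclass(cfg_plain$gen)
  cfg_plain$gen$gate_probs <- as.list(cfg_plain$gen$gate_probs)
  cfg_plain$mutation <- list(lambda_per_genome = cfg$mutation$lambda,
                             weights = as.list(cfg$mutation$weights))
  manifest <- list(
    package = "heterosim",
    version = as.character(utils::packageVersion("heterosim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg_plain,
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
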