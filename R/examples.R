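# Hand-wired demonstration study: the smallest genome whose attractor response
# is exactly right (or exactly wrong) in every environment.

#' Minimal responder study: a genome with a known perfect (or inverted) response
#'
#' Builds a small homozygous genome with three environment loci, three two-gene
#' modules, and one-hot environments. In the `"perfect"` variant every gene of
#' module k copies the state of environment node k, so under environment k the
#' attractor switches the whole target module ON and every other module OFF:
#' fitness is exactly 1 in each environment. In the `"inverted"` variant each
#' gene negates its environment node, producing exactly the wrong response and
#' fitness -1.
#'
#' @param response `"perfect"` or `"inverted"`.
#' @return list with `genome`, `modules`, `envs` — ready for
#'   [overall_fitness()].
#' @export
responder_study <- function(response = c("perfect", "inverted")) {
  response <- match.arg(response)
  env_loci <- paste0("e", 1:3)
  genes <- list(M1 = c("a1", "a2"), M2 = c("b1", "b2"), M3 = c("c1", "c2"))
  loci <- list()
  for (k in 1:3) {
    for (g in genes[[k]]) {
      expr <- logic_var(env_loci[[k]])
      if (response == "inverted") expr <- logic_not(expr)
      a <- allele(g, expr)
      loci[[g]] <- list(m = a, p = a)
    }
  }
  for (e in env_loci) {
    a <- allele(e, logic_const(FALSE))
    loci[[e]] <- list(m = a, p = a)
  }
  genome <- diploid_genome(loci, env_loci = env_loci)
  modules <- structure(genes, class = "grn_modules")
  envs <- default_environments(env_loci, names(modules))
  list(genome = genome, modules = modules, envs = envs)
}
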