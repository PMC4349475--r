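# Heterosis mechanism decomposition: local heterozygosity effects, pairwise
# epistasis, collapse detection and run pooling.

# Genome with two heterozygous loci whose allele identities are detectable by
# canonical logic, embedded in a small responsive network.
two_het_genome <- function() {
  mk_genome(list(t = "(x AND y)", u = "x"), env_loci = "e1",
            het = list(x = c("e1", "FALSE"),          # maternal functional
                       y = c("FALSE", "e1")))         # paternal functional
}

# Stub fitness keyed by which focal alleles were removed from the genome.
# `table` maps removal signatures to fitness values; the signature lists the
# focal (locus, haplotype-of-remaining-hom) states.
stub_fitness <- function(genome0, table) {
  force(genome0)
  function(g) {
    removed <- character(0)
    for (L in names(genome0$loci)) {
      if (heterosim:::locus_zygosity(genome0, L) != "het") next
      slot0 <- genome0$loci[[L]]
      slot <- g$loci[[L]]
      if (is.null(slot)) { removed <- c(removed, paste0(L, ":both")); next }
      if (heterosim:::locus_zygosity(g, L) == "het") next
      left <- slot$m
      if (allele_equal(left, slot0$m)) removed <- c(removed, paste0(L, ":p"))
      else removed <- c(removed, paste0(L, ":m"))
    }
    key <- paste(sort(removed), collapse = ",")
    val <- table[[if (key == "") "complete" else key]]
    if (is.null(val)) stop("no stub fitness for removal set '", key, "'")
    val
  }
}

test_that("removing an allele produces the homozygote for the other allele", {
  genome <- two_het_genome()
  hom <- remove_allele(genome, "x", "m")
  expect_identical(heterosim:::locus_zygosity(hom, "x"), "hom")
  expect_identical(hom$loci$x$m$canon, "FALSE")
  expect_length(build_phenotype_network(hom)$nodes,
                length(build_phenotype_network(genome)$nodes) - 1L)
  # the original genome is untouched
  expect_identical(heterosim:::locus_zygosity(genome, "x"), "het")
  expect_error(remove_allele(hom, "q", "m"), "no such locus")
  hemi <- diploid_genome(list(x = list(m = mk_allele("x", "TRUE"), p = NULL)))
  expect_error(remove_allele(hemi, "x", "p"), "already absent")
  # removing the last allele drops the locus
  gone <- remove_allele(hemi, "x", "m")
  expect_length(gone$loci, 0)
})

test_that("removing an allele nobody references leaves fitness unchanged", {
  genome <- mk_genome(list(t = "e1"), env_loci = "e1",
                      het = list(iso = c("TRUE", "FALSE")))  # unreferenced
  modules <- structure(list(M1 = "t"), class = "grn_modules")
  env <- environment_spec("E1", c(e1 = TRUE), "M1")
  f0 <- overall_fitness(genome, list(env), modules)$overall
  f1 <- overall_fitness(remove_allele(genome, "iso", "m"), list(env), modules)$overall
  f2 <- overall_fitness(remove_allele(genome, "iso", "p"), list(env), modules)$overall
  expect_identical(f0, f1)
  expect_identical(f0, f2)
  # attractors over the shared nodes are identical too
  net0 <- build_phenotype_network(genome)
  net1 <- build_phenotype_network(remove_allele(genome, "iso", "m"))
  a0 <- attractor_activity(find_attractor(net0, clamp = c(e1 = TRUE)))
  a1 <- attractor_activity(find_attractor(net1, clamp = c(e1 = TRUE)))
  expect_identical(a0[net1$nodes[net1$nodes %in% names(a0)]],
                   a1[net1$nodes[net1$nodes %in% names(a0)]])
})

test_that("local heterozygosity classification follows the stated rules", {
  genome <- two_het_genome()
  case <- function(fc, fm, fp) {
    # signatures name the removed haplotype: the maternal homozygote is the
    # genome with the paternal allele removed
    fn <- stub_fitness(genome, list(complete = fc, "x:p" = fm, "x:m" = fp,
                                    "y:m" = fc, "y:p" = fc))
    classify_locus(genome, "x", fn)
  }
  r1 <- case(1.0, 0.5, 0.5)
  expect_identical(r1$class, "over_dominance")
  expect_equal(r1$effect, 0.5)
  r2 <- case(1.0, 1.0, 0.0)
  expect_identical(r2$class, "dominance")
  expect_equal(r2$effect, 0.5)
  r3 <- case(0.2, 0.6, 0.8)
  expect_identical(r3$class, "under_dominance")
  expect_equal(r3$effect, -0.5)
  # effects within 0.5% of the complete fitness are noise
  r4 <- case(1.0, 0.998, 0.998)
  expect_identical(r4$class, "none")
  r5 <- case(1.0, 0.99, 0.99)
  expect_identical(r5$class, "over_dominance")
  expect_error(classify_locus(genome, "t", function(g) 1), "not heterozygous")
})

test_that("classification is symmetric in the haplotype labels", {
  genome <- two_het_genome()
  swapped <- genome
  swapped$loci$x <- list(m = genome$loci$x$p, p = genome$loci$x$m)
  fn <- stub_fitness(genome, list(complete = 0.9, "x:m" = 0.7, "x:p" = 0.2,
                                  "y:m" = 0.9, "y:p" = 0.9))
  fn_sw <- stub_fitness(swapped, list(complete = 0.9, "x:m" = 0.2, "x:p" = 0.7,
                                      "y:m" = 0.9, "y:p" = 0.9))
  a <- classify_locus(genome, "x", fn)
  b <- classify_locus(swapped, "x", fn_sw)
  expect_identical(a$class, b$class)
  expect_equal(a$effect, b$effect)
})

test_that("pairwise epistasis follows the multiplicative prediction", {
  genome <- two_het_genome()
  tab <- function(fc, f1, f2, f12) {
    # signatures name the REMOVED haplotype: a1 = (x, m), a2 = (y, p)
    list(complete = fc, "x:m" = f1, "y:p" = f2, "x:m,y:p" = f12)
  }
  ep_of <- function(...) {
    epistasis_pair(genome, c("x", "m"), c("y", "p"),
                   stub_fitness(genome, tab(...)))
  }
  r1 <- ep_of(0.9, 0.6, 0.6, 0.8)
  expect_equal(r1$ep, 0.9 - 0.45)
  expect_identical(r1$class, "positive")
  r2 <- ep_of(0.2, 0.6, 0.6, 0.5)
  expect_equal(r2$ep, 0.2 - 0.72)
  expect_identical(r2$class, "incompatibility")
  # exact multiplicative independence: ep = 0, class none
  r3 <- ep_of(0.48, 0.6, 0.4, 0.5)
  expect_equal(r3$ep, 0)
  expect_identical(r3$class, "none")
  # ep below -threshold without both removals fitter: negative epistasis
  r4 <- ep_of(0.2, 0.6, 0.15, 0.3)  # ep = 0.2 - 0.3 = -0.1, F_wo2 < F_complete
  expect_identical(r4$class, "negative")
  # degenerate double-removal fitness: additive fallback, flagged
  r5 <- ep_of(0.5, 0.3, 0.1, 0)
  expect_true(r5$degenerate)
  expect_equal(r5$ep, 0.5 - (0.3 + 0.1 - 0))
  expect_error(epistasis_pair(genome, c("x", "m"), c("x", "p"), function(g) 1),
               "allelomorphic")
  expect_error(epistasis_pair(genome, c("x", "m"), c("y", "m"), function(g) 1),
               "same parent")
})

test_that("cross-parental alleles with disjoint influence cones show zero epistasis", {
  # x and y live in disconnected halves; neither allele difference can reach
  # the other's targets, and the removals leave the module response intact
  genome <- mk_genome(list(t1 = "(e1 OR x)", t2 = "(e1 OR y)"), env_loci = "e1",
                      het = list(x = c("x", "(NOT x)"),
                                 y = c("y", "(NOT y)")))
  modules <- structure(list(M1 = c("t1", "t2")), class = "grn_modules")
  env <- environment_spec("E1", c(e1 = TRUE), "M1")
  fn <- function(g) overall_fitness(g, list(env), modules)$overall
  for (orient in list(list(c("x", "m"), c("y", "p")),
                      list(c("x", "p"), c("y", "m")))) {
    r <- epistasis_pair(genome, orient[[1]], orient[[2]], fn)
    expect_lt(abs(r$ep), 1e-9)
    expect_identical(r$class, "none")
  }
  # brute-force cross-check of the four deletion fitnesses via the R engine
  nets <- list(genome,
               remove_allele(genome, "x", "m"),
               remove_allele(genome, "y", "p"),
               remove_allele(remove_allele(genome, "x", "m"), "y", "p"))
  fits <- vapply(nets, function(g) {
    net <- build_phenotype_network(g)
    att <- brute_force_attractor(net, initial_state(net, c(e1 = TRUE)))
    vals <- colMeans(att$states)
    mean(vapply(modules$M1, function(L) {
      mean(vals[unlist(net$locus_nodes[[L]])])
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(fits[[1]] - fits[[2]] * fits[[3]] / fits[[4]]), 1e-9)
})

test_that("mechanism summaries cover loci and cross-parental pairs exclusively", {
  # fully homozygous: empty report
  hom <- mk_genome(list(a = "TRUE", b = "FALSE"))
  rep0 <- summarize_mechanisms(hom, function(g) 1)
  expect_identical(nrow(rep0$loci), 0L)
  expect_identical(nrow(rep0$pairs), 0L)
  expect_true(all(rep0$sums == 0))
  # one heterozygous locus: one locus row, no pairs
  one <- mk_genome(list(a = "TRUE"), het = list(x = c("TRUE", "FALSE")))
  fn1 <- stub_fitness(one, list(complete = 1, "x:m" = 0.5, "x:p" = 0.5))
  rep1 <- summarize_mechanisms(one, fn1)
  expect_identical(nrow(rep1$loci), 1L)
  expect_identical(nrow(rep1$pairs), 0L)
  expect_equal(rep1$sums[["over_dominance"]], 0.5)
  # each heterozygous locus receives exactly one class
  expect_identical(anyDuplicated(rep1$loci$locus), 0L)
})

test_that("a shared interaction spanning parents is counted once per pair", {
  # z needs x (maternal allele), y (paternal allele) and w (maternal allele):
  # one three-allele interaction, scored in two cross-parental pairs
  genome <- mk_genome(list(z = "((x AND y) AND w)"), env_loci = "e1",
                      het = list(x = c("e1", "FALSE"),
                                 y = c("FALSE", "e1"),
                                 w = c("e1", "FALSE")))
  modules <- structure(list(M1 = "z", M2 = "x"), class = "grn_modules")
  env <- environment_spec("E1", c(e1 = TRUE), "M1")
  fn <- function(g) overall_fitness(g, list(env), modules)$overall
  rep <- summarize_mechanisms(genome, fn)
  pos <- rep$pairs[rep$pairs$class == "positive", ]
  key <- paste(pos$locus_1, pos$hap_1, pos$locus_2, pos$hap_2)
  expect_true(all(c("x m y p", "w m y p") %in% key))
  # the pair-class sum double counts the single underlying interaction
  expect_equal(rep$sums[["positive"]],
               sum(pos$ep))
  expect_gte(nrow(pos), 2)
  # sums equal the totals of their detail rows across all classes
  for (cls in c("dominance", "over_dominance", "under_dominance")) {
    expect_equal(rep$sums[[cls]], sum(rep$loci$effect[rep$loci$class == cls]))
  }
  for (cls in c("positive", "negative", "incompatibility")) {
    expect_equal(rep$sums[[cls]], sum(rep$pairs$ep[rep$pairs$class == cls]))
  }
})

test_that("summarize_mechanisms agrees with the single-shot operations", {
  set.seed(12)
  genome <- two_het_genome()
  modules <- structure(list(M1 = c("t", "u")), class = "grn_modules")
  env <- environment_spec("E1", c(e1 = TRUE), "M1")
  fn <- function(g) overall_fitness(g, list(env), modules)$overall
  rep <- summarize_mechanisms(genome, fn)
  for (r in seq_len(nrow(rep$loci))) {
    solo <- classify_locus(genome, rep$loci$locus[[r]], fn)
    expect_equal(solo$effect, rep$loci$effect[[r]])
    expect_identical(solo$class, rep$loci$class[[r]])
  }
  for (r in seq_len(nrow(rep$pairs))) {
    solo <- epistasis_pair(genome,
                           c(rep$pairs$locus_1[[r]], rep$pairs$hap_1[[r]]),
                           c(rep$pairs$locus_2[[r]], rep$pairs$hap_2[[r]]), fn)
    expect_equal(solo$ep, rep$pairs$ep[[r]])
    expect_identical(solo$class, rep$pairs$class[[r]])
  }
})

test_that("collapse detection requires depth and persistence", {
  parents <- rep(0.8, 12)
  expect_identical(detect_collapse(rep(0.9, 12), parents), NA_integer_)
  stepper <- c(rep(0.85, 6), rep(-0.2, 6))
  expect_identical(detect_collapse(stepper, parents), 7L)
  dip <- c(rep(0.85, 5), 0.1, rep(0.85, 6))
  expect_identical(detect_collapse(dip, parents), NA_integer_)
  expect_identical(detect_collapse(0.1, 0.8), NA_integer_)  # shorter than k
  # two-column parent input uses the weaker parent
  pm <- cbind(rep(0.9, 4), c(0.9, 0.4, 0.4, 0.4))
  expect_identical(detect_collapse(c(0.85, 0.1, -0.1, -0.1), pm), 2L)
})

test_that("pooling aligns runs on their collapse event", {
  mk_events <- function(collapse_at, n = 12) {
    hy <- rep(0.8, n); hy[collapse_at:n] <- -0.3
    data.frame(event = seq_len(n), generation = 20 * seq_len(n),
               parent_a_mean = 0.8, parent_b_mean = 0.75, hybrid_mean = hy,
               over_dominance = 0.5, under_dominance = 0)
  }
  single <- pool_runs(list(mk_events(5)), anchor = 5)
  expect_identical(single$position, 1:12)  # collapse already at the anchor
  expect_identical(single$position[single$hybrid_mean < 0][1], 5L)
  shifted <- pool_runs(list(mk_events(9)), anchor = 5)
  # collapse at event 9 shifted left by 4
  expect_identical(min(shifted$position), 1L - 4L)
  expect_identical(shifted$position[shifted$hybrid_mean < 0][1], 5L)
  both <- pool_runs(list(mk_events(5), mk_events(9)), anchor = 5)
  expect_identical(max(both$n_runs), 2L)
  expect_true(all(both$hybrid_mean[both$position >= 5 & both$n_runs == 2] < 0))
  no_col <- mk_events(5); no_col$hybrid_mean <- 0.8
  expect_warning(pooled <- pool_runs(list(mk_events(5), no_col)), "no detected collapse")
  expect_identical(max(pooled$n_runs), 1L)
  expect_error(suppressWarnings(pool_runs(list(no_col))), "no run has")
  expect_error(pool_runs(list()), "no runs")
})
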