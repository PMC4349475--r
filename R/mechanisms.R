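# Decomposition of hybrid fitness into local heterozygosity effects
# (dominance, over-dominance, under-dominance) and pairwise epistasis classes
# (positive, negative, incompatibility), plus collapse detection and pooling
# of runs aligned on the collapse.

# Numerical-noise guard: effects of at most 0.5% of the whole-network fitness
# are not counted.
effect_threshold <- function(f_complete, frac = 0.005) frac * abs(f_complete)

#' Classify the local heterozygosity effect at one locus
#'
#' Compares the fitness of the complete (heterozygous) network with the two
#' homozygotes obtained by removing either allele. The effect is
#' `F_complete - (F_hom_m + F_hom_p) / 2`. Effects within 0.5% of the whole
#' network fitness are classed `none`; otherwise, if both homozygotes are less
#' fit than the complete network the locus shows over-dominance; a positive
#' effect not meeting that condition is dominance; a negative effect is
#' under-dominance.
#'
#' @param genome a `grn_genome` heterozygous at `locus`.
#' @param locus locus id.
#' @param fitness_fn function mapping a `grn_genome` to its overall fitness.
#' @return a one-row data.frame: `locus`, `F_complete`, `F_hom_m` (homozygote
#'   for the maternal allele), `F_hom_p`, `effect`, `class`.
#' @export
classify_locus <- function(genome, locus, fitness_fn) {
  if (locus_zygosity(genome, locus) != "het") {
    stop("locus '", locus, "' is not heterozygous")
  }
  f_complete <- fitness_fn(genome)
  f_hom_m <- fitness_fn(remove_allele(genome, locus, "p"))
  f_hom_p <- fitness_fn(remove_allele(genome, locus, "m"))
  effect <- f_complete - (f_hom_m + f_hom_p) / 2
  cls <- if (abs(effect) <= effect_threshold(f_complete)) "none"
  else if (f_hom_m < f_complete && f_hom_p < f_complete) "over_dominance"
  else if (effect > 0) "dominance"
  else "under_dominance"
  data.frame(locus = locus, F_complete = f_complete, F_hom_m = f_hom_m,
             F_hom_p = f_hom_p, effect = effect, class = cls,
             stringsAsFactors = FALSE)
}

#' Epistasis between two cross-parental alleles
#'
#' For alleles at different loci inherited from different parents, the
#' expected fitness under independence is multiplicative:
#' `F_wo1 * F_wo2 / F_wo12`, where `F_wo1`/`F_wo2` are the fitnesses after
#' removing either allele and `F_wo12` after removing both. The epistasis
#' value is `ep = F_complete - F_wo1 * F_wo2 / F_wo12`. When `|F_wo12|` is
#' within `eps` of zero the multiplicative expectation is undefined and the
#' additive prediction `F_wo1 + F_wo2 - F_wo12` is used instead (the row is
#' flagged `degenerate`). Classification (threshold 0.5% of `|F_complete|`):
#' `positive` for ep above the threshold; `incompatibility` for ep below minus
#' the threshold with both single removals fitter than the complete network;
#' `negative` for other below-threshold values; else `none`.
#'
#' @param genome a `grn_genome`.
#' @param a1,a2 length-2 character vectors `c(locus, haplotype)`; the loci must
#'   differ and the haplotypes must differ (same-parent or allelomorphic pairs
#'   fall under local effects, not epistasis).
#' @param fitness_fn function mapping a `grn_genome` to its overall fitness.
#' @param eps degeneracy guard on `|F_wo12|` (default 1e-6).
#' @return one-row data.frame: the pair, the four fitness values, `ep`,
#'   `class`, `degenerate`.
#' @export
epistasis_pair <- function(genome, a1, a2, fitness_fn, eps = 1e-6) {
  if (identical(a1[[1]], a2[[1]])) {
    stop("alleles are an allelomorphic pair; their interaction falls under ",
         "dominance/over-dominance/under-dominance")
  }
  if (identical(a1[[2]], a2[[2]])) {
    stop("alleles inherited from the same parent; such epistasis is present ",
         "in the parent too and is irrelevant for heterosis")
  }
  f_complete <- fitness_fn(genome)
  f_wo1 <- fitness_fn(remove_allele(genome, a1[[1]], a1[[2]]))
  f_wo2 <- fitness_fn(remove_allele(genome, a2[[1]], a2[[2]]))
  f_wo12 <- fitness_fn(remove_allele(remove_allele(genome, a1[[1]], a1[[2]]),
                                     a2[[1]], a2[[2]]))
  degenerate <- abs(f_wo12) <= eps
  ep <- if (degenerate) f_complete - (f_wo1 + f_wo2 - f_wo12)
        else f_complete - (f_wo1 * f_wo2) / f_wo12
  theta <- effect_threshold(f_complete)
  cls <- if (ep > theta) "positive"
  else if (ep < -theta && f_wo1 > f_complete && f_wo2 > f_complete) "incompatibility"
  else if (ep < -theta) "negative"
  else "none"
  data.frame(locus_1 = a1[[1]], hap_1 = a1[[2]], locus_2 = a2[[1]],
             hap_2 = a2[[2]], F_complete = f_complete, F_wo1 = f_wo1,
             F_wo2 = f_wo2, F_wo12 = f_wo12, ep = ep, class = cls,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

mechanism_sum_names <- c("dominance", "over_dominance", "under_dominance",
                         "positive", "negative", "incompatibility")

#' Full mechanism decomposition of a genome
#'
#' Applies [classify_locus()] to every heterozygous locus and
#' [epistasis_pair()] to every cross-parental pair of heterozygous loci (both
#' orientations: maternal of one locus against paternal of the other, and vice
#' versa). Deletion-network fitnesses are cached across pairs. Per-class sums
#' are the totals of the detail rows; because only pairs are scored, one
#' multi-locus interaction can be counted in several pairs, so epistasis sums
#' overestimate the absolute epistatic contribution and are comparable only
#' among themselves.
#'
#' @param genome a `grn_genome`.
#' @param fitness_fn function mapping a `grn_genome` to its overall fitness.
#' @return object of class `grn_mechanisms`: `loci` and `pairs` detail
#'   data.frames plus `sums`, a named numeric vector over the six classes.
#' @export
summarize_mechanisms <- function(genome, fitness_fn) {
  cache <- new.env(parent = emptyenv())
  cached_fitness <- function(removals) {
    key <- if (length(removals) == 0L) "<complete>"
           else paste(vapply(removals, paste, character(1), collapse = ":"),
                      collapse = "|")
    hit <- get0(key, envir = cache, ifnotfound = NULL)
    if (!is.null(hit)) return(hit)
    g <- genome
    for (r in removals) g <- remove_allele(g, r[[1]], r[[2]])
    val <- fitness_fn(g)
    assign(key, val, envir = cache)
    val
  }
  het <- heterozygous_loci(genome)
  loci_rows <- list()
  for (L in het) {
    f_complete <- cached_fitness(list())
    f_hom_m <- cached_fitness(list(c(L, "p")))
    f_hom_p <- cached_fitness(list(c(L, "m")))
    effect <- f_complete - (f_hom_m + f_hom_p) / 2
    cls <- if (abs(effect) <= effect_threshold(f_complete)) "none"
    else if (f_hom_m < f_complete && f_hom_p < f_complete) "over_dominance"
    else if (effect > 0) "dominance"
    else "under_dominance"
    loci_rows[[L]] <- data.frame(locus = L, F_complete = f_complete,
                                 F_hom_m = f_hom_m, F_hom_p = f_hom_p,
                                 effect = effect, class = cls,
                                 stringsAsFactors = FALSE)
  }
  pair_rows <- list()
  if (length(het) >= 2L) {
    theta0 <- NULL
    combos <- utils::combn(het, 2L, simplify = FALSE)
    for (cp in combos) {
      for (orient in list(c("m", "p"), c("p", "m"))) {
        a1 <- c(cp[[1]], orient[[1]])
        a2 <- c(cp[[2]], orient[[2]])
        f_complete <- cached_fitness(list())
        f_wo1 <- cached_fitness(list(a1))
        f_wo2 <- cached_fitness(list(a2))
        f_wo12 <- cached_fitness(list(a1, a2))
        degenerate <- abs(f_wo12) <= 1e-6
        ep <- if (degenerate) f_complete - (f_wo1 + f_wo2 - f_wo12)
              else f_complete - (f_wo1 * f_wo2) / f_wo12
        theta <- effect_threshold(f_complete)
        cls <- if (ep > theta) "positive"
        else if (ep < -theta && f_wo1 > f_complete && f_wo2 > f_complete) "incompatibility"
        else if (ep < -theta) "negative"
        else "none"
        pair_rows[[length(pair_rows) + 1L]] <-
          data.frame(locus_1 = a1[[1]], hap_1 = a1[[2]], locus_2 = a2[[1]],
                     hap_2 = a2[[2]], F_complete = f_complete, F_wo1 = f_wo1,
                     F_wo2 = f_wo2, F_wo12 = f_wo12, ep = ep, class = cls,
                     degenerate = degenerate, stringsAsFactors = FALSE)
      }
    }
  }
  loci_df <- if (length(loci_rows)) do.call(rbind, loci_rows) else
    data.frame(locus = character(0), F_complete = numeric(0),
               F_hom_m = numeric(0), F_hom_p = numeric(0),
               effect = numeric(0), class = character(0))
  rownames(loci_df) <- NULL
  pairs_df <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(locus_1 = character(0), hap_1 = character(0),
               locus_2 = character(0), hap_2 = character(0),
               F_complete = numeric(0), F_wo1 = numeric(0), F_wo2 = numeric(0),
               F_wo12 = numeric(0), ep = numeric(0), class = character(0),
               degenerate = logical(0))
  sums <- stats::setNames(numeric(length(mechanism_sum_names)), mechanism_sum_names)
  for (cls in c("dominance", "over_dominance", "under_dominance")) {
    sums[[cls]] <- sum(loci_df$effect[loci_df$class == cls])
  }
  for (cls in c("positive", "negative", "incompatibility")) {
    sums[[cls]] <- sum(pairs_df$ep[pairs_df$class == cls])
  }
  structure(list(loci = loci_df, pairs = pairs_df, sums = sums),
            class = "grn_mechanisms")
}

#' @export
print.grn_mechanisms <- function(x, ...) {
  cat("Heterosis mechanism decomposition\n")
  cat("  heterozygous loci:", nrow(x$loci), " cross-parental pairs:",
      nrow(x$pairs), "\n")
  print(round(x$sums, 4))
  invisible(x)
}

#' Detect the hybrid fitness collapse in a divergence record
#'
#' The collapse is the first hybridization event at which the hybrid mean
#' fitness falls more than `delta` below the weaker parent mean and stays
#' there for `k` consecutive events.
#'
#' @param hybrid_series numeric vector of hybrid mean fitness per event.
#' @param parent_series numeric vector (same length) of the minimum of the two
#'   parent means per event, or a 2-column matrix/data.frame of both parents.
#' @param delta collapse depth (default 0.2 fitness units).
#' @param k persistence requirement in events (default 2).
#' @return integer event index of the collapse, or `NA_integer_` when the
#'   series never collapses (or is shorter than `k`).
#' @export
detect_collapse <- function(hybrid_series, parent_series, delta = 0.2, k = 2L) {
  if (is.matrix(parent_series) || is.data.frame(parent_series)) {
    parent_series <- do.call(pmin, as.data.frame(parent_series))
  }
  n <- length(hybrid_series)
  if (length(parent_series) != n) stop("series must be aligned by event")
  if (n < k) return(NA_integer_)
  below <- hybrid_series < parent_series - delta
  for (i in seq_len(n - k + 1L)) {
    if (all(below[i:(i + k - 1L)])) return(i)
  }
  NA_integer_
}

#' Pool divergence runs aligned on the fitness collapse
#'
#' Shifts each run's per-event series so its collapse (per
#' [detect_collapse()]) lands at position `anchor`, then averages every
#' numeric column position-wise across runs. Runs without a detected collapse
#' are excluded with a warning.
#'
#' @param records list of `grn_divergence` objects (or of their `events`
#'   data.frames).
#' @param anchor aligned collapse position (default 5, i.e. the collapse
#'   coincides after the 5th hybridization).
#' @param delta,k collapse detector parameters, passed to [detect_collapse()].
#' @return data.frame with `position` (event index on the aligned axis; the
#'   collapse sits at `anchor`), `n_runs` contributing per position, and the
#'   pooled mean of every numeric event column.
#' @export
pool_runs <- function(records, anchor = 5L, delta = 0.2, k = 2L) {
  if (length(records) == 0L) stop("no runs supplied")
  anchor <- as.integer(anchor)
  evs <- lapply(records, function(r) if (inherits(r, "grn_divergence")) r$events else r)
  shifted <- list()
  for (i in seq_along(evs)) {
    ev <- evs[[i]]
    col <- detect_collapse(ev$hybrid_mean,
                           cbind(ev$parent_a_mean, ev$parent_b_mean),
                           delta = delta, k = k)
    if (is.na(col)) {
      warning("run ", i, " has no detected collapse; excluded from pooling")
      next
    }
    ev$position <- ev$event - col + anchor
    shifted[[length(shifted) + 1L]] <- ev
  }
  if (length(shifted) == 0L) stop("no run has a detected collapse")
  all_ev <- do.call(rbind, shifted)
  num_cols <- setdiff(names(all_ev)[vapply(all_ev, is.numeric, logical(1))],
                      c("position", "event"))
  positions <- sort(unique(all_ev$position))
  out <- data.frame(position = positions,
                    n_runs = vapply(positions, function(p) sum(all_ev$position == p),
                                    integer(1)))
  for (cn in num_cols) {
    out[[cn]] <- vapply(positions, function(p) mean(all_ev[[cn]][all_ev$position == p]),
                        numeric(1))
  }
  out
}
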