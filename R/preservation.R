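#' Poisson fossil-preservation model
#'
#' Preservation rates are expected fossil occurrences per lineage per Ma,
#' the intensity of a Poisson sampling process. Three flavours:
#' a single `"uniform"` rate; `"strata"` rates per (time-bin x continent),
#' capturing temporal and spatial sampling bias (e.g. a well-sampled recent
#' North America); or `"species"` rates per species. The effective rate is
#' always `f x base rate` for a global multiplier `f >= 0`.
#'
#' @param rates A single number (uniform), a matrix of `n_bins x n_areas`
#'   (strata), or a named numeric vector (per species).
#' @param bin_edges For strata rates: ascending ages in Ma (length
#'   `n_bins + 1`; last edge may be `Inf`), bin 1 being the youngest.
#' @param areas Area codes for strata columns.
#' @return Object of class `preservation_model`.
#' @export
preservation_model <- function(rates, bin_edges = NULL,
                               areas = continent_areas()) {
  if (is.matrix(rates)) {
    if (is.null(bin_edges)) stop("strata rates need bin_edges")
    stopifnot(length(bin_edges) == nrow(rates) + 1,
              !is.unsorted(bin_edges, strictly = TRUE),
              ncol(rates) == length(areas), all(rates >= 0))
    colnames(rates) <- areas
    structure(list(type = "strata", rates = rates, bin_edges = bin_edges,
                   areas = areas), class = "preservation_model")
  } else if (!is.null(names(rates))) {
    stopifnot(all(rates >= 0))
    structure(list(type = "species", rates = rates),
              class = "preservation_model")
  } else if (length(rates) == 1) {
    stopifnot(rates >= 0)
    structure(list(type = "uniform", rates = rates),
              class = "preservation_model")
  } else {
    stop("rates must be a scalar, a strata matrix, or a named species vector")
  }
}

# Per-species lifespan segments in age coordinates (age0 < age1), with the
# occupied range per segment. Uses simulator trajectories when present,
# otherwise the terminal branch with the (constant) tip range.
species_segments <- function(tree, species = NULL) {
  if (is.null(species)) species <- tree$phy$tip.label
  if (!is.null(tree$trajectories) && !is.null(tree$sim_time)) {
    tr <- tree$trajectories[tree$trajectories$species %in% species, ]
    out <- data.frame(species = tr$species,
                      a0 = tree$sim_time - tr$t1,
                      a1 = tree$sim_time - tr$t0,
                      range = tr$range, stringsAsFactors = FALSE)
    out$a0[out$a0 < 0] <- 0
    return(out)
  }
  if (is.null(tree$tip_ranges)) stop("tree has neither trajectories nor tip ranges")
  phy <- tree$phy
  tip_id <- match(species, phy$tip.label)
  if (anyNA(tip_id)) stop("unknown species: ",
                          paste(species[is.na(tip_id)], collapse = ", "))
  term <- phy$edge.length[match(tip_id, phy$edge[, 2])]
  data.frame(species = species,
             a0 = unname(tree$tip_ages[species]),
             a1 = unname(tree$tip_ages[species]) + term,
             range = vapply(tree$tip_ranges[species], range_key, character(1)),
             stringsAsFactors = FALSE)
}

# Integrated base preservation intensity over one age interval for a range.
# Widespread ranges accumulate the mean of the occupied continents' rates
# (the per-instant intensity is split uniformly among co-occupied areas).
segment_intensity <- function(a0, a1, range_areas, model) {
  if (a1 <= a0) return(0)
  switch(model$type,
    uniform = model$rates * (a1 - a0),
    species = stop("species-rate model has no per-segment intensity"),
    strata = {
      edges <- model$bin_edges
      q <- rowMeans(model$rates[, range_areas, drop = FALSE])
      lo <- pmax(a0, edges[-length(edges)])
      hi <- pmin(a1, edges[-1])
      sum(q * pmax(0, hi - lo))
    })
}

#' Integrated base detection intensity per species
#'
#' The Poisson intensity integral over each species' lifespan (multiplier
#' `f = 1`), combining the per-stratum rates with the species' continent
#' trajectory.
#'
#' @param tree A `fossil_phylo`.
#' @param model A [preservation_model()].
#' @param species Species to evaluate (default: all extinct tips).
#' @return Named numeric vector of intensity integrals.
#' @export
detection_integrals <- function(tree, model, species = extinct_tips(tree)) {
  if (model$type == "species") {
    segs <- species_segments(tree, species)
    span <- tapply(segs$a1 - segs$a0, segs$species, sum)
    q <- model$rates[species]
    if (anyNA(q)) stop("species-rate model missing rates for some species")
    return(stats::setNames(q * as.numeric(span[species]), species))
  }
  segs <- species_segments(tree, species)
  rng <- key_to_range(segs$range)
  lam <- vapply(seq_len(nrow(segs)), function(i) {
    segment_intensity(segs$a0[i], segs$a1[i], rng[[i]], model)
  }, numeric(1))
  out <- stats::setNames(numeric(length(species)), species)
  agg <- tapply(lam, segs$species, sum)
  out[names(agg)] <- agg
  out
}

#' Detection probability of one species
#'
#' `P(detected) = 1 - exp(-f * integral of the preservation intensity over
#' the species' lifespan)`, the Poisson probability of at least one
#' occurrence.
#'
#' @param species Species name (tip label).
#' @inheritParams detection_integrals
#' @param f Global rate multiplier (>= 0).
#' @return Probability in `[0, 1]`.
#' @export
species_detection_prob <- function(species, model, tree, f = 1) {
  stopifnot(f >= 0)
  lam <- detection_integrals(tree, model, species)
  unname(1 - exp(-f * lam))
}

#' Calibrate the preservation-rate multiplier
#'
#' Finds the factor `f` such that the mean detection probability over the
#' tree's extinct species equals `target_frac_known`, by bisection on the
#' monotone map `f -> mean(1 - exp(-f * Lambda_i))`.
#'
#' @inheritParams detection_integrals
#' @param target_frac_known Desired expected fraction of extinct species
#'   detected at least once, in (0, 1).
#' @param tol Tolerance on the achieved mean detection probability.
#' @return The multiplier `f` (scalar).
#' @export
calibrate_factor <- function(model, tree, target_frac_known, tol = 1e-6) {
  stopifnot(target_frac_known > 0, target_frac_known < 1)
  lam <- detection_integrals(tree, model)
  if (length(lam) == 0) stop("tree has no extinct species to calibrate against")
  if (all(lam <= 0)) stop("all base preservation intensities are zero; target unreachable")
  reachable <- mean(lam > 0)
  if (target_frac_known >= reachable) {
    stop(sprintf("target %.3f unreachable: only %.3f of extinct species have positive intensity",
                 target_frac_known, reachable))
  }
  g <- function(f) mean(1 - exp(-f * lam))
  lo <- 0; hi <- 1
  while (g(hi) < target_frac_known) {
    hi <- hi * 2
    if (hi > 1e12) stop("calibration failed to bracket the target")
  }
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (abs(gm - target_frac_known) < tol) return(mid)
    if (gm < target_frac_known) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Fossil sampling scenario
#'
#' @param frac_known Fraction of all extinct species known (detected), e.g.
#'   0.25, 0.50, 0.75.
#' @param frac_included Fraction of all extinct species included in the
#'   analysis (e.g. 0.05, 0.25). Both fractions refer to the fraction of
#'   all extinct species, so `frac_included <= frac_known`, and equality
#'   means every known species is included.
#' @param mode `"biased"` (Poisson preservation model) or `"random"`
#'   (uniform sampling, the stratum-homogeneous special case).
#' @param seed Optional integer seed for the Bernoulli and subset draws.
#' @return Object of class `sampling_scenario`.
#' @export
sampling_scenario <- function(frac_known, frac_included,
                              mode = c("biased", "random"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(frac_included >= 0, frac_known <= 1, frac_included <= frac_known)
  structure(list(frac_known = frac_known, frac_included = frac_included,
                 mode = mode, seed = seed), class = "sampling_scenario")
}

#' Draw the set of known (detected) extinct species
#'
#' Independent Bernoulli draws per extinct species with its calibrated
#' detection probability. Species in high-rate strata are correspondingly
#' enriched in the known set.
#'
#' @inheritParams calibrate_factor
#' @param scenario A [sampling_scenario()].
#' @param f Calibrated multiplier; if `NULL`, calibrated here against
#'   `scenario$frac_known`.
#' @return Character vector of known extinct species.
#' @export
draw_known_set <- function(tree, model, scenario, f = NULL) {
  if (is.null(f)) f <- calibrate_factor(model, tree, scenario$frac_known)
  lam <- detection_integrals(tree, model)
  p <- 1 - exp(-f * lam)
  with_seed(scenario$seed, {
    names(p)[stats::rbinom(length(p), 1, p) == 1]
  })
}

#' Draw the included subset of known fossils
#'
#' A uniform random subset of the known set, of size
#' `round(frac_included x n_extinct_total)`. When `frac_included` equals
#' `frac_known` the entire known set is returned (all known species are
#' included).
#'
#' @param known_set Character vector of known extinct species.
#' @param n_extinct_total Total number of extinct species in the tree.
#' @param frac_included Fraction of all extinct species to include.
#' @param frac_known If supplied and equal to `frac_included`, the whole
#'   known set is returned.
#' @param seed Optional integer seed.
#' @return Character vector, a subset of `known_set`.
#' @export
draw_included_set <- function(known_set, n_extinct_total, frac_included,
                              frac_known = NULL, seed = NULL) {
  if (!is.null(frac_known) && isTRUE(all.equal(frac_included, frac_known))) {
    return(known_set)
  }
  m <- round(frac_included * n_extinct_total)
  if (m > length(known_set)) {
    stop("requested ", m, " included fossils but only ", length(known_set),
         " are known")
  }
  if (m == 0) return(character(0))
  with_seed(seed, sample(known_set, m))
}

#' Prune a tree to extant species plus a chosen fossil subset
#'
#' All extant tips are retained; extinct tips outside `keep_extinct` are
#' removed; unary nodes are suppressed with branch lengths summed, so path
#' lengths and MRCA ages of retained tips are unchanged. Tip ages are
#' carried over, not recomputed.
#'
#' @param tree A `fossil_phylo`.
#' @param keep_extinct Character vector of extinct tips to retain (may be
#'   empty for an extant-only tree).
#' @return A pruned `fossil_phylo`.
#' @export
prune_to <- function(tree, keep_extinct = character(0)) {
  ext <- extinct_tips(tree)
  unknown <- setdiff(keep_extinct, ext)
  if (length(unknown)) {
    stop("keep set contains species that are not extinct tips: ",
         paste(unknown, collapse = ", "))
  }
  drop <- setdiff(ext, keep_extinct)
  if (length(drop) == 0) return(tree)
  phy2 <- ape::drop.tip(tree$phy, drop, collapse.singles = TRUE)
  keep <- phy2$tip.label
  fossil_phylo(
    phy2,
    tip_ages = tree$tip_ages[keep],
    tip_ranges = if (is.null(tree$tip_ranges)) NULL else tree$tip_ranges[keep],
    last_continent = if (is.null(tree$last_continent)) NULL else {
      tree$last_continent[intersect(names(tree$last_continent), keep)]
    },
    node_true_ranges = tree$node_true_ranges,
    sim_time = tree$sim_time,
    extinct_tol = tree$extinct_tol
  )
}
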