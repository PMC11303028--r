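#' Simulate fossil occurrences along lineages
#'
#' For each lineage, occurrences are drawn from a Poisson process along its
#' lifespan with the intensity of the preservation stratum at each instant
#' (`f` times the base rate). Each occurrence is tagged with the lineage's
#' continent at that instant; when the lineage is widespread the continent
#' is chosen uniformly among the occupied ones.
#'
#' @param tree A `fossil_phylo` (simulated trees use their full trajectory;
#'   other trees use terminal branches with the constant tip range).
#' @param model A [preservation_model()] (uniform or strata).
#' @param f Global rate multiplier.
#' @param species Which species to sample (default: all tips).
#' @param seed Optional integer seed.
#' @return data.frame with columns `species`, `age` (Ma), `continent`.
#' @export
simulate_occurrences <- function(tree, model, f = 1,
                                 species = tree$phy$tip.label, seed = NULL) {
  stopifnot(f >= 0)
  if (model$type == "species") {
    stop("occurrence simulation needs a uniform or strata model")
  }
  segs <- species_segments(tree, species)
  rng <- key_to_range(segs$range)
  edges <- if (model$type == "strata") model$bin_edges else c(0, Inf)

  with_seed(seed, {
    out_sp <- character(0); out_age <- numeric(0); out_cont <- character(0)
    for (i in seq_len(nrow(segs))) {
      a0 <- segs$a0[i]; a1 <- segs$a1[i]
      if (a1 <= a0) next
      areas_i <- rng[[i]]
      # split the lifespan at bin edges so intensity is constant per piece
      cuts <- sort(unique(c(a0, a1, edges[edges > a0 & edges < a1])))
      for (k in seq_len(length(cuts) - 1)) {
        lo <- cuts[k]; hi <- cuts[k + 1]
        q <- if (model$type == "uniform") model$rates else {
          b <- findInterval(lo, model$bin_edges, rightmost.closed = FALSE)
          mean(model$rates[b, areas_i])
        }
        n <- stats::rpois(1, f * q * (hi - lo))
        if (n > 0) {
          out_sp <- c(out_sp, rep(segs$species[i], n))
          out_age <- c(out_age, stats::runif(n, lo, hi))
          out_cont <- c(out_cont, sample(areas_i, n, replace = TRUE))
        }
      }
    }
    data.frame(species = out_sp, age = out_age, continent = out_cont,
               stringsAsFactors = FALSE)
  })
}

#' Ancestral area from the oldest fossil record
#'
#' The phylogeny-free baseline: the inferred ancestral area of a group is
#' the continent of its oldest occurrence. Ties at the maximum age are all
#' reported.
#'
#' @param occurrences data.frame with `species`, `age`, `continent`.
#' @param group Optional character vector of species defining the group
#'   (default: all occurrences).
#' @param tol Ages within `tol` of the maximum are treated as tied.
#' @return Character vector of continent code(s).
#' @export
oldest_record_area <- function(occurrences, group = NULL, tol = 1e-9) {
  occ <- occurrences
  if (!is.null(group)) occ <- occ[occ$species %in% group, , drop = FALSE]
  if (nrow(occ) == 0) stop("no occurrences for the requested group")
  amax <- max(occ$age)
  unique(occ$continent[occ$age >= amax - tol])
}

#' Write an occurrence table as TSV
#'
#' @param occurrences data.frame from [simulate_occurrences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occurrences, path) {
  utils::write.table(occurrences, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
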