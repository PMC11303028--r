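#' Time-calibrated tree with fossil tips and continental ranges
#'
#' The package's central container: an `ape::phylo` topology plus per-tip
#' ages (Ma before present; 0 = extant), per-tip ranges, extinct flags, the
#' last occupied continent of each extinct tip, and (for simulated trees)
#' the true range at every internal node. Trees are strictly binary;
#' polytomies are rejected rather than arbitrarily resolved.
#'
#' @param phy An `ape::phylo` object (rooted, binary, with branch lengths
#'   in Ma).
#' @param tip_ages Named numeric vector of tip ages (names = tip labels).
#' @param tip_ranges Optional named list of character vectors of area codes.
#' @param last_continent Optional named character vector: for each extinct
#'   tip, the single continent occupied at extinction.
#' @param node_true_ranges Optional named list (names = node labels) of true
#'   ranges at internal nodes (simulation truth).
#' @param trajectories Optional data frame of per-lineage range trajectories
#'   (columns `species`, `t0`, `t1`, `range` in forward simulation time).
#' @param events Optional event log data frame from the simulator.
#' @param sim_time Optional total forward-simulation time (Ma), so that
#'   age = `sim_time - t`.
#' @param extinct_tol Tips with age greater than this are flagged extinct
#'   (default 1e-6 Ma). Which marginally extinct species (e.g. Holocene or
#'   Late Pleistocene losses) deserve "extant" coding is the caller's call:
#'   set their ages to 0 before construction.
#' @return Object of class `fossil_phylo`.
#' @export
fossil_phylo <- function(phy, tip_ages, tip_ranges = NULL,
                         last_continent = NULL, node_true_ranges = NULL,
                         trajectories = NULL, events = NULL, sim_time = NULL,
                         extinct_tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape::phylo object")
  if (is.null(phy$edge.length)) stop("branch lengths are required")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  n_tip <- length(phy$tip.label)
  if (n_tip < 2) stop("binary topology requires at least 2 tips")
  if (!ape::is.binary(phy)) stop("polytomies are not supported; resolve before use")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  if (is.null(names(tip_ages))) stop("tip_ages must be named by tip label")
  missing <- setdiff(phy$tip.label, names(tip_ages))
  if (length(missing)) stop("tip_ages missing for: ", paste(missing, collapse = ", "))
  tip_ages <- tip_ages[phy$tip.label]
  if (any(tip_ages < 0)) stop("negative tip age")
  extinct <- tip_ages > extinct_tol
  if (!is.null(tip_ranges)) {
    tip_ranges <- check_tip_ranges(tip_ranges, phy$tip.label)
  }
  if (!is.null(last_continent)) {
    last_continent <- last_continent[intersect(names(last_continent), phy$tip.label)]
  }
  structure(list(
    phy = phy, tip_ages = tip_ages, extinct = extinct,
    tip_ranges = tip_ranges, last_continent = last_continent,
    node_true_ranges = node_true_ranges, trajectories = trajectories,
    events = events, sim_time = sim_time, extinct_tol = extinct_tol
  ), class = "fossil_phylo")
}

check_tip_ranges <- function(tip_ranges, tip_labels) {
  if (is.null(names(tip_ranges))) stop("tip_ranges must be named by tip label")
  missing <- setdiff(tip_labels, names(tip_ranges))
  if (length(missing)) {
    stop("tip_ranges missing for: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(tip_ranges), tip_labels)
  if (length(extra)) {
    stop("tip_ranges given for species not in the tree: ",
         paste(extra, collapse = ", "))
  }
  sizes <- lengths(tip_ranges)
  if (any(sizes < 1)) stop("empty tip range (null ranges are not observable)")
  tip_ranges[tip_labels]
}

#' @export
print.fossil_phylo <- function(x, ...) {
  cat("fossil_phylo:", length(x$phy$tip.label), "tips (",
      sum(x$extinct), "extinct ),", x$phy$Nnode, "internal nodes\n")
  cat("root age:", format(root_age(x), digits = 6), "Ma;",
      if (is.null(x$tip_ranges)) "ranges unbound" else "ranges bound", "\n")
  invisible(x)
}

#' Node and tip ages of a fossil_phylo
#'
#' Ages in Ma before present for every node (tips first, internal nodes
#' after, in `phylo` node numbering). The present is defined by the tips:
#' root age = max over tips of (tip age + path length to root).
#'
#' @param x A `fossil_phylo`.
#' @return Numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(x) {
  phy <- x$phy
  n_tip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth[seq_len(n_tip)] + x$tip_ages)
  root_age - depth
}

#' @rdname node_ages
#' @export
root_age <- function(x) {
  n_tip <- length(x$phy$tip.label)
  depth <- ape::node.depth.edgelength(x$phy)
  max(depth[seq_len(n_tip)] + x$tip_ages)
}

n_extant <- function(x) sum(!x$extinct)
n_extinct <- function(x) sum(x$extinct)
extinct_tips <- function(x) names(x$tip_ages)[x$extinct]
extant_tips <- function(x) names(x$tip_ages)[!x$extinct]
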