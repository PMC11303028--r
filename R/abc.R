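#' ABC summary statistics of a simulated or empirical tree
#'
#' The five rejection criteria: (a) tree length (sum of all branch lengths,
#' extinct subtrees included); (b) root height (age of the root split);
#' (c) fraction of all species still extant; (d) number of extant species
#' occupying two continents; (e) fraction of sister-species pairs
#' (cherries: mutually sister tips) that are single-continent endemics on
#' different continents. Extinct cherry members are scored by the last
#' continent they went extinct on.
#'
#' @param tree A `fossil_phylo` with bound ranges (and `last_continent` for
#'   extinct tips).
#' @return Object of class `abc_summary`: list with the five statistics
#'   plus the raw counts `n_cherries`, `n_split_sisters`, `n_tips`.
#' @export
summary_stats <- function(tree) {
  phy <- tree$phy
  if (is.null(tree$tip_ranges)) stop("tip ranges are not bound")
  n_tip <- length(phy$tip.label)
  tree_length <- sum(phy$edge.length)
  rh <- root_age(tree)
  frac_extant <- mean(!tree$extinct)
  sizes <- lengths(tree$tip_ranges)
  n_two <- sum(!tree$extinct & sizes[phy$tip.label] == 2)

  # cherries: internal nodes whose two children are both tips
  tip_edges <- phy$edge[, 2] <= n_tip
  par_counts <- table(phy$edge[tip_edges, 1])
  cherry_nodes <- as.integer(names(par_counts)[par_counts == 2])
  n_split <- 0L
  for (v in cherry_nodes) {
    tips <- phy$tip.label[phy$edge[phy$edge[, 1] == v & tip_edges, 2]]
    sc <- vapply(tips, function(sp) {
      if (tree$extinct[sp]) {
        lc <- tree$last_continent[sp]
        if (is.null(lc) || is.na(lc)) {
          stop("extinct tip ", sp, " lacks last_continent")
        }
        lc
      } else {
        r <- tree$tip_ranges[[sp]]
        if (length(r) == 1) r else NA_character_
      }
    }, character(1))
    if (!anyNA(sc) && sc[1] != sc[2]) n_split <- n_split + 1L
  }
  n_cherries <- length(cherry_nodes)
  structure(list(
    tree_length = tree_length, root_height = rh, frac_extant = frac_extant,
    n_extant_two_continents = n_two,
    frac_split_sisters = if (n_cherries > 0) n_split / n_cherries else 0,
    n_cherries = n_cherries, n_split_sisters = n_split, n_tips = n_tip
  ), class = "abc_summary")
}

#' @export
print.abc_summary <- function(x, ...) {
  cat(sprintf(paste0("abc_summary: length=%.3g root=%.3g frac_extant=%.3f ",
                     "two-continent extant=%d split sisters=%d/%d\n"),
              x$tree_length, x$root_height, x$frac_extant,
              x$n_extant_two_continents, x$n_split_sisters, x$n_cherries))
  invisible(x)
}

#' Absolute log error
#'
#' `ALE = |log(r_emp / r_sim)|` (natural log), the rejection distance per
#' summary statistic. Both values must be strictly positive; zero-valued
#' count summaries are offset by the caller (see [abc_distances()]).
#'
#' @param r_emp,r_sim Positive values.
#' @return Non-negative scalar.
#' @export
ale <- function(r_emp, r_sim) {
  if (!is.finite(r_emp) || !is.finite(r_sim) || r_emp <= 0 || r_sim <= 0) {
    stop("ale() requires strictly positive finite values")
  }
  abs(log(r_emp) - log(r_sim))
}

# Continuity offsets so ALE is defined for zero-valued summaries: the
# two-continent extant count 0 becomes 0.5; a zero split-sister fraction
# becomes 0.5 / max(1, n_cherries).
adjusted_summary_values <- function(s) {
  c(tree_length = s$tree_length,
    root_height = s$root_height,
    frac_extant = s$frac_extant,
    n_extant_two_continents = if (s$n_extant_two_continents > 0) {
      s$n_extant_two_continents
    } else 0.5,
    frac_split_sisters = if (s$frac_split_sisters > 0) {
      s$frac_split_sisters
    } else 0.5 / max(1L, s$n_cherries))
}

#' ALE distances of candidate summaries from a target
#'
#' @param candidates A list of `abc_summary` objects (or a data.frame with
#'   the summary columns).
#' @param target The empirical/target `abc_summary`.
#' @return Matrix (candidates x 5 criteria) of ALE values plus an
#'   `ale_max` column.
#' @export
abc_distances <- function(candidates, target) {
  tv <- adjusted_summary_values(target)
  rows <- lapply(candidates, function(s) {
    if (is.null(s)) return(rep(Inf, 5))  # failed simulation
    sv <- adjusted_summary_values(s)
    abs(log(tv) - log(sv))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- names(tv)
  cbind(m, ale_max = apply(m, 1, max))
}

#' Select the k candidates closest to the target
#'
#' Ranks candidates by the maximum ALE over the five criteria (ALE_max),
#' ascending, with ties broken deterministically by candidate index, and
#' returns the indices of the `k` best.
#'
#' @inheritParams abc_distances
#' @param k Number of candidates to keep (1 <= k <= number of candidates).
#' @return List with `index` (selected candidate indices, best first),
#'   `ale_max` (their distances) and `distances` (the full matrix).
#' @export
select_trees <- function(candidates, target, k) {
  if (k <= 0) stop("k must be positive")
  n <- length(candidates)
  if (k > n) stop("k exceeds the number of candidates")
  d <- abc_distances(candidates, target)
  ord <- order(d[, "ale_max"], seq_len(n))
  sel <- ord[seq_len(k)]
  list(index = sel, ale_max = d[sel, "ale_max"], distances = d)
}
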