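#' Match clades between a reduced tree and a reference tree
#'
#' Every internal node of the reduced tree is mapped to the smallest clade
#' of the reference tree containing the same species: the MRCA, in the
#' reference tree, of the reduced node's retained tip set (which may
#' subtend additional, e.g. extinct, reference tips).
#'
#' @param reduced_tree,reference_tree `fossil_phylo` objects; the reduced
#'   tree's tips must be a subset of the reference tree's tips.
#' @return Named integer vector: reference node number per reduced internal
#'   node (names = reduced node numbers).
#' @export
match_clades <- function(reduced_tree, reference_tree) {
  rphy <- reduced_tree$phy
  fphy <- reference_tree$phy
  missing <- setdiff(rphy$tip.label, fphy$tip.label)
  if (length(missing)) {
    stop("tips missing from the reference tree: ",
         paste(missing, collapse = ", "))
  }
  n_tip <- length(rphy$tip.label)
  nodes <- (n_tip + 1L):(n_tip + rphy$Nnode)
  desc <- phangorn::Descendants(rphy, nodes, type = "tips")
  ref_tip_id <- match(rphy$tip.label, fphy$tip.label)
  out <- vapply(seq_along(nodes), function(i) {
    tips <- ref_tip_id[desc[[i]]]
    if (length(tips) == 1) tips else ape::getMRCA(fphy, tips)
  }, integer(1))
  stats::setNames(out, nodes)
}

#' Per-continent and total reconstruction accuracy at one node
#'
#' `accuracy_c = 1 - |p_ref_c - p_est_c|` per continent, where `p` is the
#' probability that the continent is part of the ancestral area; total
#' accuracy is the product over continents. The formula is symmetric in
#' its two arguments; which tree plays "reference" is the caller's choice.
#'
#' @param p_ref,p_est Numeric vectors of per-continent inclusion
#'   probabilities in `[0, 1]` (same length and order).
#' @return List with `continental` (named vector) and `total`.
#' @export
node_accuracy <- function(p_ref, p_est) {
  stopifnot(length(p_ref) == length(p_est))
  if (any(p_ref < 0 | p_ref > 1 | p_est < 0 | p_est > 1)) {
    stop("inclusion probabilities must lie in [0, 1]")
  }
  cont <- 1 - abs(p_ref - p_est)
  list(continental = cont, total = prod(cont))
}

#' Truth-mode inclusion probabilities from simulated node ranges
#'
#' Converts the simulator's true node ranges into inclusion probabilities:
#' 1 for member continents, 0 otherwise.
#'
#' @param tree A simulated `fossil_phylo` with `node_true_ranges`.
#' @param areas Area order of the columns.
#' @return Matrix (internal nodes x areas) with rownames = node numbers.
#' @export
true_inclusion <- function(tree, areas = continent_areas()) {
  phy <- tree$phy
  if (is.null(tree$node_true_ranges)) stop("tree has no node_true_ranges")
  if (is.null(phy$node.label)) stop("tree lacks node labels to match truth")
  n_tip <- length(phy$tip.label)
  nodes <- (n_tip + 1L):(n_tip + phy$Nnode)
  out <- matrix(0, length(nodes), length(areas),
                dimnames = list(nodes, areas))
  for (i in seq_along(nodes)) {
    lab <- phy$node.label[i]
    rng <- tree$node_true_ranges[[lab]]
    if (is.null(rng)) stop("no true range recorded for node ", lab)
    out[i, match(rng, areas)] <- 1
  }
  out
}

# Per-continent species counts within a reference-tree clade: extant
# species count once per occupied continent; extinct species count by the
# last continent they went extinct on.
clade_continent_counts <- function(tree, node, areas = continent_areas()) {
  phy <- tree$phy
  n_tip <- length(phy$tip.label)
  tips <- if (node <= n_tip) node else {
    phangorn::Descendants(phy, node, type = "tips")[[1]]
  }
  labs <- phy$tip.label[tips]
  extant <- stats::setNames(numeric(length(areas)), areas)
  all_sp <- stats::setNames(numeric(length(areas)), areas)
  for (sp in labs) {
    if (tree$extinct[sp]) {
      lc <- tree$last_continent[sp]
      if (!is.null(lc) && !is.na(lc)) all_sp[lc] <- all_sp[lc] + 1
    } else {
      r <- tree$tip_ranges[[sp]]
      extant[r] <- extant[r] + 1
      all_sp[r] <- all_sp[r] + 1
    }
  }
  rbind(extant = extant, all = all_sp)
}

#' Evaluate reconstruction accuracy of a reduced tree against a reference
#'
#' Fits the range model on the reduced tree (unless parameters are given),
#' computes marginal ancestral ranges, matches every reduced internal node
#' to the smallest containing clade of the reference tree, and scores the
#' accuracy of the per-continent inclusion probabilities against the
#' reference: either the reference tree's own inferred profile
#' ("empirical" mode) or the simulation truth ("truth" mode, via
#' [true_inclusion()]).
#'
#' @param reference_tree The full/reference `fossil_phylo`.
#' @param reference_inclusion Matrix (reference internal nodes x areas) of
#'   reference inclusion probabilities; rownames must be reference node
#'   numbers (an `ancestry_profile$inclusion` or [true_inclusion()]).
#' @param reduced_tree The pruned `fossil_phylo` to evaluate.
#' @param space A [build_state_space()].
#' @param model `"DEC"` or `"DEC+J"` (used when `params` is `NULL`).
#' @param params Optional [dec_params()] to use instead of fitting.
#' @param restarts Optimiser restarts for the fit.
#' @param root_prior Root prior passed to the likelihood.
#' @param with_similarity Add the Fisher-test sampling-similarity
#'   p-value of each matched reference clade (slower; default FALSE).
#' @return data.frame of class `accuracy_records`: one row per reduced
#'   internal node with node ids, node age, per-continent accuracies,
#'   `total`, clade sizes and optional covariates. The fitted parameters
#'   are attached as attribute `fit`.
#' @export
evaluate_scenario <- function(reference_tree, reference_inclusion,
                              reduced_tree, space,
                              model = "DEC", params = NULL, restarts = 2,
                              root_prior = "uniform",
                              with_similarity = FALSE) {
  fit <- NULL
  if (is.null(params)) {
    fit <- fit_ml(reduced_tree, space, model = model,
                  root_prior = root_prior, restarts = restarts)
    params <- fit$params
  }
  prof <- ancestral_marginals(reduced_tree, space, params, root_prior)
  map <- match_clades(reduced_tree, reference_tree)
  ages <- node_ages(reduced_tree)
  areas <- space$areas

  ref_rows <- match(as.character(map), rownames(reference_inclusion))
  if (anyNA(ref_rows)) {
    stop("reference inclusion matrix lacks rows for matched nodes: ",
         paste(map[is.na(ref_rows)], collapse = ", "))
  }
  est <- prof$inclusion[, areas, drop = FALSE]
  ref <- reference_inclusion[ref_rows, areas, drop = FALSE]
  cont <- 1 - abs(ref - est)
  total <- apply(cont, 1, prod)

  n_tip <- length(reduced_tree$phy$tip.label)
  nodes <- as.integer(names(map))
  desc <- phangorn::Descendants(reduced_tree$phy, nodes, type = "tips")
  rec <- data.frame(
    node = nodes, ref_node = as.integer(map), age = ages[nodes],
    clade_size = lengths(desc), stringsAsFactors = FALSE
  )
  acc <- as.data.frame(cont)
  names(acc) <- paste0("acc_", areas)
  rec <- cbind(rec, acc, total = total)

  if (with_similarity) {
    rec$similarity_p <- vapply(rec$ref_node, function(v) {
      tab <- clade_continent_counts(reference_tree, v, areas)
      tryCatch(sampling_similarity(tab["extant", ], tab["all", ]),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  attr(rec, "fit") <- fit
  attr(rec, "params") <- params
  class(rec) <- c("accuracy_records", class(rec))
  rec
}

#' Shortest (highest-density) interval of a sample
#'
#' The shortest interval containing at least `prob` of the sample points.
#'
#' @param x Numeric sample.
#' @param prob Coverage (default 0.95).
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(c(NA_real_, NA_real_))
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + k - 1L])
}

#' Bin accuracy records by node age and summarise across trees
#'
#' Bins nodes by age — absolute edges, or per-tree age quantiles (used for
#' simulated trees whose root ages differ) — computes the per-tree mean
#' accuracy per bin, and across trees the mean of the per-tree means and
#' their 95% HPD (shortest interval). Empty bins are reported as missing.
#'
#' @param records An `accuracy_records` data.frame (or rbind of several)
#'   with columns `tree`, `age` and `total`.
#' @param mode `"quantile"` (within-tree age quantiles) or `"absolute"`.
#' @param n_bins Number of bins (quantile mode).
#' @param edges Bin edges in Ma (absolute mode).
#' @param value Column to summarise (default `"total"`).
#' @param prob HPD coverage.
#' @return List with `per_tree` (tree x bin means) and `summary`
#'   (data.frame: bin, mean, hpd_lo, hpd_hi, n_trees). Bin 1 is youngest.
#' @export
bin_and_summarize <- function(records, mode = c("quantile", "absolute"),
                              n_bins = 4, edges = NULL, value = "total",
                              prob = 0.95) {
  mode <- match.arg(mode)
  if (!"tree" %in% names(records)) records$tree <- 1L
  trees <- unique(records$tree)
  per_tree <- matrix(NA_real_, length(trees), n_bins,
                     dimnames = list(trees, NULL))
  if (mode == "absolute") {
    if (is.null(edges)) stop("absolute mode needs bin edges")
    n_bins <- length(edges) - 1
    per_tree <- matrix(NA_real_, length(trees), n_bins,
                       dimnames = list(trees, NULL))
  }
  for (ti in seq_along(trees)) {
    r <- records[records$tree == trees[ti], ]
    if (nrow(r) == 0) next
    if (mode == "quantile") {
      qs <- stats::quantile(r$age, probs = seq(0, 1, length.out = n_bins + 1),
                            type = 7)
      qs[1] <- -Inf; qs[length(qs)] <- Inf
      bin <- findInterval(r$age, qs, rightmost.closed = TRUE,
                          all.inside = TRUE)
    } else {
      bin <- findInterval(r$age, edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
    }
    m <- tapply(r[[value]], factor(bin, levels = seq_len(n_bins)), mean)
    per_tree[ti, ] <- as.numeric(m)
  }
  summ <- data.frame(bin = seq_len(n_bins))
  summ$mean <- colMeans(per_tree, na.rm = TRUE)
  hpds <- apply(per_tree, 2, function(col) hpd_interval(col[!is.na(col)], prob))
  summ$hpd_lo <- hpds[1, ]; summ$hpd_hi <- hpds[2, ]
  summ$n_trees <- colSums(!is.na(per_tree))
  summ$mean[summ$n_trees == 0] <- NA_real_
  list(per_tree = per_tree, summary = summ)
}
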