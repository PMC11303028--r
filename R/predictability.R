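#' Sampling similarity of a clade (Fisher's exact test)
#'
#' Tests whether the proportions of species across continents found among
#' extant species and among all species (extant and extinct) are samples
#' from the same distribution, via Fisher's exact test on the 2 x 4 table
#' (rows: extant counts, all-species counts; columns: continents). The two
#' rows are not independent by construction — the extant species are a
#' subset of all species — but this is exactly the comparison being
#' summarised, and the p-value is used as a descriptive covariate, not as
#' a hypothesis test.
#'
#' Columns that are zero in both rows are dropped (degenerate columns carry
#' no information and break exact enumeration). The exact network
#' algorithm is used when the table total is at most `exact_max`; larger
#' tables use a Monte-Carlo estimate over `B` tables drawn with fixed
#' margins, with a fixed seed.
#'
#' @param extant_counts,all_counts Non-negative per-continent counts.
#' @param exact_max Largest table total handled exactly (default 200).
#' @param B Monte-Carlo table count (default 1e5).
#' @param mc_seed Seed for the Monte-Carlo draw (RNG state restored).
#' @return p-value in (0, 1].
#' @export
sampling_similarity <- function(extant_counts, all_counts, exact_max = 200,
                                B = 1e5, mc_seed = 1) {
  stopifnot(length(extant_counts) == length(all_counts),
            all(extant_counts >= 0), all(all_counts >= 0))
  tab <- rbind(extant = extant_counts, all = all_counts)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) == 0) stop("all-zero table")
  if (any(rowSums(tab) == 0)) stop("a row of the table is all zero")
  if (ncol(tab) == 1) return(1)
  p <- if (sum(tab) <= exact_max) {
    stats::fisher.test(tab, workspace = 2e7)$p.value
  } else {
    fisher_mc_p(tab, B = B, seed = mc_seed)
  }
  # snap to 12 digits: float dust from the network algorithm otherwise
  # breaks exact ties between identical tables, perturbing rank statistics
  round(min(max(p, .Machine$double.xmin), 1), 12)
}

# Monte-Carlo two-sided Fisher p: draw B tables with the observed margins
# (r2dtable) and estimate P(table probability <= observed), including the
# observed table itself so p > 0.
fisher_mc_p <- function(tab, B = 1e5, seed = 1) {
  logp <- function(m) {
    sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
      lgamma(sum(m) + 1) - sum(lgamma(m + 1))
  }
  obs <- logp(tab)
  with_seed(seed, {
    sims <- stats::r2dtable(B, rowSums(tab), colSums(tab))
    lp <- vapply(sims, logp, numeric(1))
    (sum(lp <= obs + 1e-7) + 1) / (B + 1)
  })
}

#' Rank correlations of accuracy with its candidate predictors
#'
#' Per tree: the Spearman rank correlation of total accuracy with node age
#' (`rho_age`) and with the sampling-similarity p-value (`rho_sim`), plus
#' medians and ranges across trees. Trees with constant accuracy (or fewer
#' than 3 usable nodes) have undefined correlations, recorded as `NA`.
#'
#' @param records Accuracy records with columns `tree`, `age`, `total` and
#'   `similarity_p`.
#' @param method Correlation estimator: `"spearman"` (default) or
#'   `"pearson"`.
#' @return Object of class `predictability_result`: list with `per_tree`
#'   (data.frame tree, rho_age, rho_sim), `median_rho_age`,
#'   `median_rho_sim`, `range_rho_age`, `range_rho_sim`.
#' @export
correlate_predictors <- function(records, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!"tree" %in% names(records)) records$tree <- 1L
  trees <- unique(records$tree)
  rho <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok], method = method)
  }
  per_tree <- do.call(rbind, lapply(trees, function(tr) {
    r <- records[records$tree == tr, ]
    data.frame(tree = tr,
               rho_age = rho(r$total, r$age),
               rho_sim = if ("similarity_p" %in% names(r)) {
                 rho(r$total, r$similarity_p)
               } else NA_real_)
  }))
  safe_range <- function(x) {
    if (all(is.na(x))) c(NA_real_, NA_real_) else range(x, na.rm = TRUE)
  }
  structure(list(
    per_tree = per_tree,
    median_rho_age = stats::median(per_tree$rho_age, na.rm = TRUE),
    median_rho_sim = stats::median(per_tree$rho_sim, na.rm = TRUE),
    range_rho_age = safe_range(per_tree$rho_age),
    range_rho_sim = safe_range(per_tree$rho_sim),
    method = method
  ), class = "predictability_result")
}

#' @export
print.predictability_result <- function(x, ...) {
  cat(sprintf("rho_age median %.3f (range %.3f, %.3f); rho_sim median %.3f (range %.3f, %.3f)\n",
              x$median_rho_age, x$range_rho_age[1], x$range_rho_age[2],
              x$median_rho_sim, x$range_rho_sim[1], x$range_rho_sim[2]))
  invisible(x)
}

#' Paired comparison of predictor strengths
#'
#' Paired t-test on the per-tree difference in predictor strength. By
#' default strengths are absolute correlations (node age correlates
#' negatively with accuracy, sampling similarity positively, so signs are
#' stripped before comparison); signed comparison by `absolute = FALSE`.
#' Conventions for degenerate inputs: all differences exactly zero gives
#' `t = 0, p = 1`; a constant non-zero difference (zero variance) is
#' reported as `p = 0` with `degenerate = TRUE`.
#'
#' @param rho_age,rho_sim Per-tree correlation vectors (paired; NAs in
#'   either member drop the pair).
#' @param absolute Compare absolute correlation strengths (default TRUE).
#' @return List with `t`, `p_value`, `mean_diff`, `n`, `degenerate`.
#' @export
compare_predictors <- function(rho_age, rho_sim, absolute = TRUE) {
  stopifnot(length(rho_age) == length(rho_sim))
  ok <- is.finite(rho_age) & is.finite(rho_sim)
  a <- rho_age[ok]; b <- rho_sim[ok]
  if (length(a) < 2) stop("need at least 2 trees with both correlations defined")
  if (absolute) { a <- abs(a); b <- abs(b) }
  d <- a - b
  scale <- max(abs(a), abs(b), 1)
  if (all(abs(d) <= 1e-12 * scale)) {
    return(list(t = 0, p_value = 1, mean_diff = 0, n = length(d),
                degenerate = FALSE))
  }
  if (stats::sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.eps)) {
    return(list(t = sign(mean(d)) * Inf, p_value = 0, mean_diff = mean(d),
                n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p_value = tt$p.value, mean_diff = mean(d),
       n = length(d), degenerate = FALSE)
}
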