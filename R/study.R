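#' Default biased preservation model
#'
#' A strata preservation model emulating the familiar structure of the
#' mammalian fossil record: recent time bins are much better sampled than
#' old ones, and northern continents (North America in particular) better
#' than southern ones. Absolute values are irrelevant — the global
#' multiplier is always calibrated to the scenario's fraction of known
#' fossils — only the relative bias matters.
#'
#' @param bin_edges Ages (Ma) delimiting the time bins, youngest first.
#' @return A [preservation_model()].
#' @export
default_preservation <- function(bin_edges = c(0, 5, 15, Inf)) {
  time_eff <- c(3, 1, 0.3)
  area_eff <- c(SA = 0.5, "NA" = 2, EU = 1, AF = 0.5)
  rates <- outer(time_eff, area_eff)
  preservation_model(rates, bin_edges = bin_edges)
}

stage_seed <- function(seed, k) as.integer((seed * 10007 + k * 97) %% 2147483647)

#' Run the simulation study end to end
#'
#' The full experiment: (1) simulate a synthetic target tree under known
#' rates; (2) simulate candidate trees with rates drawn from the uniform
#' priors and keep the `abc_keep` whose summary statistics are closest to
#' the target (smallest maximum absolute log error); (3) simulate the
#' study trees under the accepted rate draws; (4) for each study tree,
#' reconstruct ancestral ranges from the extant-only tree and from trees
#' with a biased subset of fossils included (Poisson preservation model,
#' calibrated to the scenario's fraction of known fossils), scoring
#' accuracy against the simulated truth; (5) bin accuracy by within-tree
#' age quantiles and summarise across trees; (6) correlate extant-only
#' accuracy with node age and sampling similarity.
#'
#' @param seed Master integer seed; every stochastic stage derives its own
#'   seed from it.
#' @param n_trees Number of study trees.
#' @param n_extant Extant tip count of the target and study trees.
#' @param target_params True rates of the synthetic target tree.
#' @param abc_n_candidates,abc_keep ABC candidate count and number kept.
#' @param scenarios Named list of fossil scenarios; each element is a list
#'   with `frac_known`, `frac_included` and `mode` ("biased" or "random").
#'   The extant-only baseline is always run.
#' @param model,restarts Range model and optimiser restarts per fit.
#' @param n_bins Age-quantile bins for the accuracy summary.
#' @param preservation Preservation model for biased scenarios.
#' @param n_batches Batches for the replicate-level comparison of oldest-bin
#'   accuracy (trees are split sequentially into this many batches).
#' @param progress Print per-stage progress lines.
#' @return Object of class `simulation_study`: list with `records` (all
#'   accuracy records), `binned` (per-scenario summaries), `predictability`,
#'   `batch_comparison`, `accepted_params`, `trees` and the configuration.
#' @export
run_simulation_study <- function(seed = 1,
                                 n_trees = 20,
                                 n_extant = 80,
                                 target_params = sim_params(0.2, 0.1, 0.3, 0.05, 0.5),
                                 abc_n_candidates = 300,
                                 abc_keep = 20,
                                 scenarios = list(
                                   fossils25 = list(frac_known = 0.5,
                                                    frac_included = 0.25,
                                                    mode = "biased")),
                                 model = "DEC", restarts = 2, n_bins = 4,
                                 preservation = default_preservation(),
                                 n_batches = 10,
                                 progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))

  say("simulating target tree (%d extant tips)", n_extant)
  target_tree <- simulate_tree(target_params, n_extant,
                               seed = stage_seed(seed, 1),
                               max_attempts = 500)
  target_summary <- summary_stats(target_tree)

  say("simulating %d ABC candidates", abc_n_candidates)
  cand <- with_seed(stage_seed(seed, 2), {
    lapply(seq_len(abc_n_candidates), function(i) {
      p <- draw_params_from_priors()
      sim <- simulate_forward(p, n_extant,
                              max_events = max(2000L, 60L * n_extant))
      s <- if (sim$success) {
        tryCatch(summary_stats(sim_to_fossil_phylo(sim)),
                 error = function(e) NULL)
      } else NULL
      list(params = p, summary = s)
    })
  })
  sel <- select_trees(lapply(cand, `[[`, "summary"), target_summary, abc_keep)
  accepted <- lapply(cand[sel$index], `[[`, "params")
  say("ABC kept %d candidates (worst ALE_max %.3f)", abc_keep, max(sel$ale_max))

  space <- build_state_space(continent_areas(), max_range_size = 3)
  records <- list()
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    p_t <- accepted[[((t - 1) %% length(accepted)) + 1]]
    tree <- simulate_tree(p_t, n_extant, seed = stage_seed(seed, 100 + t),
                          max_attempts = 500)
    trees[[t]] <- tree
    truth <- true_inclusion(tree)
    say("tree %d/%d: %d tips (%d extinct)", t, n_trees,
        length(tree$phy$tip.label), n_extinct(tree))

    rec_ext <- evaluate_scenario(tree, truth, prune_to(tree),
                                 space, model = model, restarts = restarts,
                                 with_similarity = TRUE)
    rec_ext$tree <- t; rec_ext$scenario <- "extant_only"
    records[[length(records) + 1]] <- rec_ext

    for (sc_name in names(scenarios)) {
      sc <- scenarios[[sc_name]]
      sc_seed <- stage_seed(seed, 1000 + t * 13 + match(sc_name, names(scenarios)))
      n_ext <- n_extinct(tree)
      keep <- if (n_ext == 0) {
        character(0)
      } else if (identical(sc$mode, "random")) {
        m <- round(sc$frac_included * n_ext)
        with_seed(sc_seed, sample(extinct_tips(tree), m))
      } else {
        scen <- sampling_scenario(sc$frac_known, sc$frac_included,
                                  mode = "biased", seed = sc_seed)
        known <- draw_known_set(tree, preservation, scen)
        m <- round(sc$frac_included * n_ext)
        if (m > length(known)) known else {
          draw_included_set(known, n_ext, sc$frac_included,
                            frac_known = sc$frac_known,
                            seed = stage_seed(sc_seed, 7))
        }
      }
      rec <- evaluate_scenario(tree, truth, prune_to(tree, keep),
                               space, model = model, restarts = restarts)
      rec$tree <- t; rec$scenario <- sc_name
      rec$similarity_p <- NA_real_
      records[[length(records) + 1]] <- rec
    }
  }
  records <- do.call(rbind, records)

  scen_names <- c("extant_only", names(scenarios))
  binned <- lapply(stats::setNames(scen_names, scen_names), function(sn) {
    bin_and_summarize(records[records$scenario == sn, ],
                      mode = "quantile", n_bins = n_bins)
  })

  pred <- correlate_predictors(records[records$scenario == "extant_only", ])
  cmp <- tryCatch(
    compare_predictors(pred$per_tree$rho_age, pred$per_tree$rho_sim),
    error = function(e) NULL)

  batch_comparison <- batch_oldest_bin_comparison(binned, n_batches)

  structure(list(
    records = records, binned = binned, predictability = pred,
    predictor_test = cmp, batch_comparison = batch_comparison,
    accepted_params = accepted, abc = sel, target_summary = target_summary,
    trees = trees,
    config = list(seed = seed, n_trees = n_trees, n_extant = n_extant,
                  abc_n_candidates = abc_n_candidates, abc_keep = abc_keep,
                  model = model, restarts = restarts, n_bins = n_bins,
                  n_batches = n_batches, scenarios = scenarios)
  ), class = "simulation_study")
}

# Per batch of trees, compare the mean accuracy in the oldest age bin
# between each fossil scenario and the extant-only baseline.
batch_oldest_bin_comparison <- function(binned, n_batches) {
  ext <- binned[["extant_only"]]$per_tree
  n_trees <- nrow(ext)
  n_batches <- min(n_batches, n_trees)
  batch_of <- ((seq_len(n_trees) - 1) %% n_batches) + 1
  oldest <- ncol(ext)
  out <- list()
  for (sn in setdiff(names(binned), "extant_only")) {
    foss <- binned[[sn]]$per_tree
    per_batch <- vapply(seq_len(n_batches), function(b) {
      sel <- batch_of == b
      c(extant = mean(ext[sel, oldest], na.rm = TRUE),
        fossil = mean(foss[sel, oldest], na.rm = TRUE))
    }, numeric(2))
    wins <- sum(per_batch["fossil", ] > per_batch["extant", ], na.rm = TRUE)
    out[[sn]] <- list(per_batch = t(per_batch), n_batches = n_batches,
                      fossil_wins = wins,
                      frac_fossil_better = wins / n_batches,
                      mean_extant_oldest = mean(ext[, oldest], na.rm = TRUE),
                      mean_fossil_oldest = mean(foss[, oldest], na.rm = TRUE))
  }
  out
}

#' @export
print.simulation_study <- function(x, ...) {
  cat("simulation_study:", x$config$n_trees, "trees,",
      x$config$n_extant, "extant tips each, model", x$config$model, "\n")
  for (sn in names(x$batch_comparison)) {
    bc <- x$batch_comparison[[sn]]
    cat(sprintf("  %s vs extant-only, oldest age quantile: %.3f vs %.3f (fossil better in %d/%d batches)\n",
                sn, bc$mean_fossil_oldest, bc$mean_extant_oldest,
                bc$fossil_wins, bc$n_batches))
  }
  if (!is.null(x$predictability)) print(x$predictability)
  invisible(x)
}

#' Empirical-style evaluation of user-supplied trees
#'
#' For each supplied tree (e.g. a posterior sample), the full tree is
#' taken as the reference: the range model is fitted to it, its marginal
#' ancestral profile becomes the reference inclusion probabilities, and
#' reduced trees — extant-only or with a random fraction of extinct
#' species retained — are evaluated against it ("empirical" mode, where
#' accuracy measures agreement with the full-tree inference, not truth).
#'
#' @param trees A `fossil_phylo` or list of them, with bound ranges.
#' @param fractions Fractions of extinct species randomly retained
#'   (0 = extant-only), e.g. `c(0, 0.05, 0.25, 0.5)`.
#' @param space State space (default: 4 continents, max range size 3).
#' @param model,restarts,root_prior Passed to the fits.
#' @param seed Master seed for the random subsets.
#' @param with_similarity Attach sampling-similarity covariates to the
#'   extant-only records.
#' @return data.frame of accuracy records with columns `tree`, `scenario`
#'   (e.g. "frac_0.25") and the per-node accuracy fields.
#' @export
run_empirical_style <- function(trees, fractions = c(0, 0.05, 0.25, 0.5),
                                space = build_state_space(),
                                model = "DEC", restarts = 2,
                                root_prior = "uniform", seed = 1,
                                with_similarity = FALSE) {
  if (inherits(trees, "fossil_phylo")) trees <- list(trees)
  records <- list()
  for (t in seq_along(trees)) {
    tree <- trees[[t]]
    fit <- fit_ml(tree, space, model = model, root_prior = root_prior,
                  restarts = restarts)
    prof <- ancestral_marginals(tree, space, fit$params, root_prior)
    ref_inc <- prof$inclusion
    n_ext <- n_extinct(tree)
    for (fr in fractions) {
      m <- round(fr * n_ext)
      keep <- if (m == 0) character(0) else {
        with_seed(stage_seed(seed, t * 101 + round(1000 * fr)),
                  sample(extinct_tips(tree), m))
      }
      rec <- evaluate_scenario(tree, ref_inc, prune_to(tree, keep), space,
                               model = model, restarts = restarts,
                               root_prior = root_prior,
                               with_similarity = with_similarity && fr == 0)
      rec$tree <- t
      rec$scenario <- paste0("frac_", fr)
      records[[length(records) + 1]] <- rec
    }
  }
  do.call(rbind, records)
}

#' Write study outputs as plain-text tables
#'
#' Writes `records.tsv`, one `summary_<scenario>.tsv` per scenario, the
#' per-tree predictability correlations and (if jsonlite is installed) the
#' accepted simulation parameters as JSON.
#'
#' @param study A `simulation_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- study$records
  num <- vapply(rec, is.double, logical(1))
  num[names(num) == "similarity_p"] <- FALSE  # already snapped; keep as is
  rec[num] <- lapply(rec[num], signif, digits = 8)
  utils::write.table(rec, file.path(dir, "records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sn in names(study$binned)) {
    utils::write.table(study$binned[[sn]]$summary,
                       file.path(dir, paste0("summary_", sn, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(study$predictability$per_tree,
                     file.path(dir, "predictability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    pars <- lapply(study$accepted_params, unclass)
    jsonlite::write_json(pars, file.path(dir, "accepted_params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
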