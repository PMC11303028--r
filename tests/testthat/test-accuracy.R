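space <- build_state_space()

test_that("node accuracy follows the 1 - |difference| product formula", {
  r <- node_accuracy(c(1, 0, 0, 0), c(0.7, 0.3, 0, 0))
  expect_equal(unname(r$continental), c(0.7, 0.7, 1, 1))
  expect_equal(r$total, 0.49)
  same <- node_accuracy(c(0.2, 0.8, 0, 0.5), c(0.2, 0.8, 0, 0.5))
  expect_equal(unname(same$continental), rep(1, 4))
  expect_equal(same$total, 1)
  set.seed(3)
  for (i in 1:10) {
    a <- runif(4); b <- runif(4)
    expect_equal(node_accuracy(a, b)$total, node_accuracy(b, a)$total)
    expect_lte(node_accuracy(a, b)$total, min(node_accuracy(a, b)$continental))
  }
  expect_error(node_accuracy(c(1.2, 0, 0, 0), c(1, 0, 0, 0)), "0, 1")
})

test_that("clade matching maps to the smallest containing reference clade", {
  set.seed(15)
  p <- sim_params(0.35, 0.12, 0.35, 0.06, 0.6)
  for (rep in 1:6) {
    ft <- simulate_tree(p, 12)
    red <- prune_to(ft)  # extant-only
    map <- match_clades(red, ft)
    # identity map when reduced == reference
    self_map <- match_clades(ft, ft)
    n_tip <- length(ft$phy$tip.label)
    expect_identical(unname(self_map), (n_tip + 1L):(n_tip + ft$phy$Nnode))
    # brute-force containment scan agrees
    n_red_tip <- length(red$phy$tip.label)
    for (v in as.integer(names(map))) {
      tips <- red$phy$tip.label[
        phangorn::Descendants(red$phy, v, type = "tips")[[1]]]
      expect_identical(unname(map[as.character(v)]),
                       containment_oracle(ft$phy, tips))
    }
  }
  # missing tip is an error
  ft <- simulate_tree(p, 10, seed = 4)
  red <- prune_to(ft)
  red$phy$tip.label[1] <- "renamed_tip"
  expect_error(match_clades(red, ft), "missing from the reference")
})

test_that("self-comparison accuracy is exactly one at every node", {
  set.seed(19)
  ft <- simulate_tree(sim_params(0.3, 0.1, 0.35, 0.05, 0.5), 20)
  fit <- fit_ml(ft, space, "DEC", restarts = 1)
  prof <- ancestral_marginals(ft, space, fit$params)
  rec <- evaluate_scenario(ft, prof$inclusion, ft, space,
                           params = fit$params)
  expect_true(all(rec$total == 1))
  acc_cols <- paste0("acc_", space$areas)
  expect_lt(max(abs(rec$total - apply(as.matrix(rec[, acc_cols]), 1, prod))),
            1e-12)
})

test_that("truth-mode self-agreement gives accuracy one", {
  truth <- c(0, 1, 0, 0)
  expect_equal(node_accuracy(truth, truth)$total, 1)
})

test_that("accuracy only changes through the inference", {
  set.seed(23)
  ft <- simulate_tree(sim_params(0.3, 0.1, 0.35, 0.05, 0.5), 15)
  truth <- true_inclusion(ft)
  red <- prune_to(ft)
  p <- dec_params(0.1, 0.05)
  rec1 <- evaluate_scenario(ft, truth, red, space, params = p)
  rec2 <- evaluate_scenario(ft, truth, red, space, params = p)
  expect_identical(rec1$total, rec2$total)
})

test_that("HPD intervals are shortest and well calibrated", {
  expect_equal(hpd_interval(rep(0.4, 20)), c(0.4, 0.4))
  x <- with_seed(31, runif(1e4))
  w <- diff(hpd_interval(x, 0.95))
  expect_lt(abs(w - 0.95), 0.02)
  # shorter than the central interval on a skewed sample
  y <- with_seed(32, rexp(5000))
  expect_lte(diff(hpd_interval(y, 0.9)),
             diff(stats::quantile(y, c(0.05, 0.95))) + 1e-12)
})

test_that("quantile binning balances per-tree occupancy", {
  set.seed(35)
  rec <- data.frame(tree = rep(1:3, each = 40),
                    age = runif(120, 0, 30),
                    total = runif(120))
  bs <- bin_and_summarize(rec, mode = "quantile", n_bins = 4)
  expect_equal(dim(bs$per_tree), c(3, 4))
  expect_false(any(is.na(bs$per_tree)))
  # occupancy per bin differs by at most 1 within each tree
  for (tr in 1:3) {
    r <- rec[rec$tree == tr, ]
    qs <- stats::quantile(r$age, probs = seq(0, 1, 0.25))
    qs[1] <- -Inf; qs[5] <- Inf
    occ <- table(findInterval(r$age, qs, rightmost.closed = TRUE,
                              all.inside = TRUE))
    expect_lte(max(occ) - min(occ), 1)
  }
  # identical per-tree means give a degenerate HPD
  rec$total <- 0.7
  bs2 <- bin_and_summarize(rec, mode = "quantile", n_bins = 4)
  expect_equal(unname(unlist(bs2$summary[, c("hpd_lo", "hpd_hi")])),
               rep(0.7, 8))
  # absolute mode with explicit edges; empty bins are missing, not zero
  bs3 <- bin_and_summarize(rec, mode = "absolute", edges = c(0, 30, 60, 90))
  expect_true(is.na(bs3$summary$mean[3]))
  expect_equal(bs3$summary$n_trees[3], 0)
})
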