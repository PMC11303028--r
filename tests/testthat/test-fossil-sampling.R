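# a tree with a known extinct lifespan for closed-form checks (X: ages 2..5)
sampling_tree <- function() {
  phy <- ape::read.tree(text = "((X:3,Y:5):1,Z:6);")
  fossil_phylo(phy, tip_ages = c(X = 2, Y = 0, Z = 0),
               tip_ranges = list(X = "NA", Y = "EU", Z = "NA"),
               last_continent = c(X = "NA"))
}

test_that("detection probability follows the Poisson closed form", {
  ft <- sampling_tree()
  model <- preservation_model(1)
  expect_equal(species_detection_prob("X", model, ft, f = 0), 0)
  # f q L = ln 2 over lifespan L = 3 gives detection 1/2
  expect_equal(species_detection_prob("X", model, ft, f = log(2) / 3), 0.5)
})

test_that("detection probability matches Monte-Carlo occurrence frequency", {
  ft <- sampling_tree()
  rates <- matrix(rep(c(0.4, 1.2), 4), nrow = 2)
  model <- preservation_model(rates, bin_edges = c(0, 4, Inf))
  p_analytic <- species_detection_prob("X", model, ft, f = 0.5)
  hits <- with_seed(19, {
    vapply(1:4000, function(i) {
      nrow(simulate_occurrences(ft, model, f = 0.5, species = "X")) > 0
    }, logical(1))
  })
  se <- sqrt(p_analytic * (1 - p_analytic) / length(hits))
  expect_lt(abs(mean(hits) - p_analytic), 3 * se)
})

test_that("calibration recovers the homogeneous closed form and its target", {
  ft <- sampling_tree()
  q <- 0.7
  model <- preservation_model(q)
  target <- 0.5
  f <- calibrate_factor(model, ft, target)
  expect_equal(f, log(1 / (1 - target)) / (q * 3), tolerance = 1e-4)
  lam <- detection_integrals(ft, model)
  expect_lt(abs(mean(1 - exp(-f * lam)) - target), 1e-6)
  expect_error(calibrate_factor(preservation_model(0), ft, 0.5), "zero")
})

test_that("the calibration objective is monotone in f", {
  set.seed(37)
  ft <- simulate_tree(sim_params(0.4, 0.1, 0.35, 0.05, 0.5), 30)
  model <- default_preservation()
  lam <- detection_integrals(ft, model)
  g <- vapply(seq(0, 5, length.out = 40),
              function(f) mean(1 - exp(-f * lam)), numeric(1))
  expect_true(all(diff(g) >= 0))
})

test_that("biased strata enrich the known set in the high-rate stratum", {
  set.seed(57)
  ft <- simulate_tree(sim_params(0.5, 0.1, 0.35, 0.05, 0.5), 40)
  ra <- root_age(ft)
  # young stratum heavily sampled, old stratum barely
  rates <- matrix(rep(c(5, 0.2), 4), nrow = 2)
  model <- preservation_model(rates, bin_edges = c(0, ra / 3, Inf))
  f <- calibrate_factor(model, ft, 0.5)
  young <- extinct_tips(ft)[ft$tip_ages[extinct_tips(ft)] < ra / 3]
  old <- setdiff(extinct_tips(ft), young)
  expect_gte(length(young), 3)
  expect_gte(length(old), 3)
  wins <- 0
  for (r in 1:100) {
    scen <- sampling_scenario(0.5, 0.25, "biased", seed = 1000 + r)
    known <- draw_known_set(ft, model, scen, f = f)
    fy <- mean(young %in% known); fo <- mean(old %in% known)
    if (fy > fo) wins <- wins + 1
  }
  expect_gt(wins, 80)
  # determinism per seed
  scen <- sampling_scenario(0.5, 0.25, "biased", seed = 11)
  expect_identical(draw_known_set(ft, model, scen, f = f),
                   draw_known_set(ft, model, scen, f = f))
  expect_length(draw_known_set(ft, model, scen, f = 0), 0)
})

test_that("the included subset honours its size contract", {
  known <- paste0("sp", 1:30)
  expect_identical(draw_included_set(known, 100, 0.3, frac_known = 0.3), known)
  expect_length(draw_included_set(known, 100, 0, seed = 1), 0)
  expect_length(draw_included_set(known, 100, 0.05, seed = 1), 5)
  expect_true(all(draw_included_set(known, 100, 0.25, seed = 2) %in% known))
  expect_error(draw_included_set(known, 200, 0.25, seed = 1), "50.*30")
})

test_that("pruning preserves path lengths, MRCA ages and tip ages", {
  set.seed(61)
  p <- sim_params(0.35, 0.12, 0.35, 0.06, 0.6)
  for (rep in 1:5) {
    ft <- simulate_tree(p, 20)
    expect_gte(n_extinct(ft), 4)
    expect_identical(prune_to(ft, extinct_tips(ft)), ft)
    keep <- sample(extinct_tips(ft), 2)
    red <- prune_to(ft, keep)
    expect_setequal(red$phy$tip.label, c(extant_tips(ft), keep))
    d_full <- ape::cophenetic.phylo(ft$phy)
    d_red <- ape::cophenetic.phylo(red$phy)
    common <- rownames(d_red)
    expect_lt(max(abs(d_red - d_full[common, common])), 1e-9)
    ext_only <- prune_to(ft)
    expect_true(all(ext_only$tip_ages == 0))
    # MRCA age of a random retained pair is unchanged
    pair <- sample(common, 2)
    a_full <- node_ages(ft)[ape::getMRCA(ft$phy, pair)]
    a_red <- node_ages(red)[ape::getMRCA(red$phy, pair)]
    expect_equal(a_full, a_red, tolerance = 1e-9)
  }
  ft <- simulate_tree(p, 15, seed = 3)
  expect_error(prune_to(ft, c("nonexistent_tip")), "not extinct tips")
})
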