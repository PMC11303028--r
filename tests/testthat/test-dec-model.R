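space <- build_state_space()

test_that("anagenetic generator honours adjacency and conserves rate", {
  p <- dec_params(0.2, 0.07)
  Q <- anagenetic_generator(space, p)
  expect_equal(Q["NA", "NA+EU"], 0.2)
  expect_equal(Q["NA", "NA+AF"], 0)           # non-adjoining: zero
  expect_equal(Q["SA+NA", "SA+NA+EU"], 0.2)   # only NA adjacent to EU
  expect_equal(Q["SA+NA", "SA+NA+AF"], 0)
  expect_equal(Q["NA+EU", "NA"], 0.07)
  expect_equal(Q["NA", "-"], 0.07)            # singleton -> null
  expect_equal(Q["-", "-"], 0)                # null absorbing
  expect_lt(max(abs(rowSums(Q))), 1e-12)
})

test_that("branch transition matrices are stochastic across time scales", {
  p <- dec_params(0.3, 0.1)
  Q <- anagenetic_generator(space, p)
  Pfun <- fossilareas:::make_branch_prob(Q)
  for (t in c(0.01, 1, 100)) {
    P <- Pfun(t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0))
  }
})

test_that("cladogenetic distribution matches the stated event weighting", {
  na <- state_index("NA", space)
  cd0 <- clado_distribution(space, dec_params(0.1, 0.1, 0))
  ev <- clado_events_for(cd0, na)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$prob, 1)
  expect_equal(ev$left, na)

  # singleton NA with j = 0.5 and adjacent targets SA, EU:
  # sympatry 1/(1+4*0.5) = 1/3; each of 4 ordered jumps 0.5/3
  cdj <- clado_distribution(space, dec_params(0.1, 0.1, 0.5))
  evj <- clado_events_for(cdj, na)
  expect_equal(nrow(evj), 5)
  expect_equal(sort(evj$prob, decreasing = TRUE),
               c(1 / 3, rep(0.5 / 3, 4)))

  for (s in seq_len(space$n_states)) {
    expect_lt(abs(sum(clado_events_for(cdj, s)$prob) - 1), 1e-12)
    # j = 0 puts zero mass on jump events: daughters never leave the
    # ancestor's area set
    ev0 <- clado_events_for(cd0, s)
    anc_areas <- space$states[[s]]
    for (dset in c(ev0$left, ev0$right)) {
      expect_true(all(space$states[[dset]] %in% anc_areas))
    }
  }
})

test_that("two identical extant endemics with zero rates give lnL = ln(1/14)", {
  phy <- ape::read.tree(text = "(A:1,B:1);")
  ft <- fossil_phylo(phy, c(A = 0, B = 0), tip_ranges = list(A = "NA", B = "NA"))
  expect_equal(tree_loglik(ft, space, dec_params(0, 0, 0)), log(1 / 14))
})

test_that("pruning equals exhaustive enumeration on small random trees", {
  set.seed(11)
  for (rep in 1:15) {
    ft <- random_small_ft(sample(3:4, 1))
    p <- dec_params(runif(1), runif(1), runif(1))
    o <- enum_oracle(ft, space, p)
    expect_lt(abs(tree_loglik(ft, space, p) - o$loglik), 1e-8)
    m <- ancestral_marginals(ft, space, p)
    expect_lt(max(abs(m$states - o$marginals)), 1e-8)
    expect_lt(max(abs(rowSums(m$states) - 1)), 1e-9)
  }
})

test_that("fossil tips enter the pruning exactly like extant tips", {
  # same topology and states, but one tip is a dated fossil: the pruning
  # treats it as an indicator at its observed state, so the enumeration
  # oracle must still agree
  set.seed(21)
  phy <- ape::read.tree(text = "((A:1,B:2.5):1,C:3);")
  ages <- fossilareas:::derived_tip_ages(phy)
  ft <- fossil_phylo(phy, ages,
                     tip_ranges = list(A = "NA", B = "EU", C = c("NA", "EU")))
  expect_true(ft$extinct[["A"]])
  p <- dec_params(0.4, 0.15, 0.3)
  o <- enum_oracle(ft, space, p)
  expect_lt(abs(tree_loglik(ft, space, p) - o$loglik), 1e-8)
  expect_lt(max(abs(ancestral_marginals(ft, space, p)$states - o$marginals)), 1e-8)
})

test_that("likelihood is invariant to swapping left and right children", {
  set.seed(31)
  ft <- random_small_ft(4)
  p <- dec_params(0.3, 0.1, 0.4)
  ll1 <- tree_loglik(ft, space, p)
  n_tip <- 4
  rot <- ft
  rot$phy <- ape::rotate(ft$phy, n_tip + 1)
  ll2 <- tree_loglik(rot, space, p)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("mirror-symmetric data yield mirrored marginals", {
  # chain SA-NA-EU-AF is symmetric under reversal; mirror the tip states
  # on a symmetric tree and the node marginals must map onto each other
  phy <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  ages <- c(A = 0, B = 0, C = 0, D = 0)
  ft <- fossil_phylo(phy, ages,
                     tip_ranges = list(A = "SA", B = "NA", C = "AF", D = "EU"))
  p <- dec_params(0.25, 0.08, 0.3)
  m <- ancestral_marginals(ft, space, p)
  mirror <- c(SA = "AF", "NA" = "EU", EU = "NA", AF = "SA")
  mirror_key <- function(k) {
    parts <- mirror[key_to_range(k)[[1]]]
    range_key(unname(parts))
  }
  perm <- match(vapply(space$keys, mirror_key, character(1)), space$keys)
  node_ab <- which(rownames(m$states) == as.character(ape::getMRCA(phy, c("A", "B"))))
  node_cd <- which(rownames(m$states) == as.character(ape::getMRCA(phy, c("C", "D"))))
  expect_equal(unname(m$states[node_ab, perm]), unname(m$states[node_cd, ]),
               tolerance = 1e-10)
  expect_equal(unname(m$states[1, perm]), unname(m$states[1, ]),
               tolerance = 1e-10)  # root marginal is self-mirrored
})

test_that("split-mode divides widespread mass equally among members", {
  # tips {NA} and {NA,EU} with zero rates force the root state to NA+EU
  # (subset sympatry is the only event reaching both tip states):
  # inclusion 1 for both continents, split 0.5 each
  phy <- ape::read.tree(text = "(A:1,B:1);")
  ft <- fossil_phylo(phy, c(A = 0, B = 0),
                     tip_ranges = list(A = "NA", B = c("NA", "EU")))
  m <- ancestral_marginals(ft, space, dec_params(0, 0, 0))
  expect_equal(unname(m$inclusion[1, c("NA", "EU")]), c(1, 1))
  expect_equal(unname(m$split[1, ]), c(0, 0.5, 0.5, 0))
  expect_equal(sum(m$split[1, ]), 1)

  # and on arbitrary profiles the summaries follow their definitions
  set.seed(41)
  ft2 <- random_small_ft(4)
  m2 <- ancestral_marginals(ft2, space, dec_params(0.3, 0.1, 0.2))
  probs <- m2$states
  for (a in continent_areas()) {
    contains <- vapply(space$keys, function(k) a %in% key_to_range(k)[[1]], TRUE)
    sizes <- lengths(key_to_range(space$keys))
    expect_equal(unname(m2$inclusion[, a]), unname(probs %*% (contains * 1))[, 1],
                 tolerance = 1e-12)
    expect_equal(unname(m2$split[, a]),
                 unname(probs %*% (contains / sizes))[, 1], tolerance = 1e-12)
  }
})
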