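test_that("tip ages derive from path lengths with the deepest tip as the present", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", f)
  ft <- read_newick(f)
  expect_equal(unname(ft$tip_ages), c(0, 0))
  expect_false(any(ft$extinct))
  expect_equal(root_age(ft), 1)

  writeLines("((A:1,B:2):1,C:3);", f)
  ft <- read_newick(f)
  expect_equal(ft$tip_ages[["A"]], 1)
  expect_equal(ft$tip_ages[["B"]], 0)
  expect_equal(ft$tip_ages[["C"]], 0)
  expect_identical(unname(ft$extinct[c("A", "B", "C")]), c(TRUE, FALSE, FALSE))
})

test_that("an explicit tip-age table overrides derived ages", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2):1,C:3);", f)
  ft <- read_newick(f, tip_ages = c(A = 0.5))
  expect_equal(ft$tip_ages[["A"]], 0.5)
  expect_true(ft$extinct[["A"]])
})

test_that("newick round trip preserves topology, path lengths and flags", {
  set.seed(4)
  p <- sim_params(0.3, 0.1, 0.4, 0.05, 0.6)
  for (rep in 1:5) {
    ft <- simulate_tree(p, 15)
    f <- withr::local_tempfile(fileext = ".nwk")
    write_newick(ft, f)
    ft2 <- read_newick(f)
    expect_setequal(ft2$phy$tip.label, ft$phy$tip.label)
    d1 <- ape::cophenetic.phylo(ft$phy)
    d2 <- ape::cophenetic.phylo(ft2$phy)
    expect_lt(max(abs(d1 - d2[rownames(d1), colnames(d1)])), 1e-9)
    expect_identical(ft2$extinct[names(ft$extinct)], ft$extinct)
  }
})

test_that("degenerate and malformed trees are rejected", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("not a tree at all (", f)
  expect_error(read_newick(f))
  writeLines("((A:1,B:1):-1,C:1);", f)
  expect_error(read_newick(f), "negative")
  writeLines("((A:1,A:1):1,C:2);", f)
  expect_error(read_newick(f), "duplicate")
  writeLines("((A:1,B:1,C:1):1,D:2);", f)  # polytomy
  expect_error(read_newick(f), "polytom")
  one_tip <- structure(list(tip.label = "A"), class = "phylo")
  expect_error(write_newick(one_tip, f), "at least 2 tips")
})

test_that("geography files decode, reject bad rows, and round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2 4 (SA NA EU AF)", "FelisX 0110", "CanisY 1000"), f)
  geo <- read_geography(f)
  expect_identical(unname(geo["FelisX", ]), c(0L, 1L, 1L, 0L))
  expect_identical(colnames(geo), c("SA", "NA", "EU", "AF"))

  writeLines(c("1 4 (SA NA EU AF)", "FelisX 0000"), f)
  expect_error(read_geography(f), "all-zero")
  writeLines(c("1 4 (SA NA EU AF)", "FelisX 011"), f)
  expect_error(read_geography(f), "malformed")

  ranges <- list(FelisX = c("NA", "EU"), CanisY = "SA", UrsusZ = c("SA", "NA", "EU"))
  write_geography(ranges, f)
  geo2 <- read_geography(f)
  expect_identical(unname(geo2["UrsusZ", ]), c(1L, 1L, 1L, 0L))
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_geography(geo2, f2)
  expect_identical(read_geography(f2), geo2)
})

test_that("bind_ranges matches species exactly and names offenders", {
  phy <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  ft <- fossil_phylo(phy, tip_ages = c(A = 0, B = 0, C = 0))
  f <- withr::local_tempfile(fileext = ".txt")
  write_geography(list(A = "NA", B = "EU", C = c("NA", "EU")), f)
  bound <- bind_ranges(ft, read_geography(f))
  expect_identical(bound$tip_ranges$C, c("NA", "EU"))

  write_geography(list(A = "NA", B = "EU"), f)
  expect_error(bind_ranges(ft, read_geography(f)), "missing species: C")
  write_geography(list(A = "NA", B = "EU", c = c("NA", "EU")), f)
  expect_error(bind_ranges(ft, read_geography(f)), "missing species: C")
  write_geography(list(A = "NA", B = "EU", C = "NA", D = "AF"), f)
  expect_error(bind_ranges(ft, read_geography(f)), "not in the tree: D")
})

test_that("extinct flagging follows the tip, not the label", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((X:1,Y:2):1,Z:3);", f)
  a <- read_newick(f)
  writeLines("((Z:1,X:2):1,Y:3);", f)  # same shape, labels permuted
  b <- read_newick(f)
  expect_true(a$extinct[["X"]] && b$extinct[["Z"]])
  expect_equal(sum(a$extinct), sum(b$extinct))
})
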