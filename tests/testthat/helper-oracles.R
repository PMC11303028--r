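# Independent oracles used across tests. These deliberately avoid the
# package's pruning / ranking / correlation code paths.

# Exhaustive-enumeration likelihood and marginals: sum over every joint
# assignment of states to internal nodes, with per-node factors
# F[s, e1, e2] = sum over daughter pairs of clado(s; l, r) P1[l, e1] P2[r, e2],
# transition matrices computed independently via Matrix::expm.
enum_oracle <- function(ft, space, params) {
  phy <- ft$phy
  n_tip <- length(phy$tip.label)
  K <- space$n_states
  Kn <- K + 1L
  Q <- anagenetic_generator(space, params)
  clado <- clado_distribution(space, params)
  tipidx <- vapply(ft$tip_ranges, state_index, integer(1), space = space)

  kids <- lapply(seq_len(n_tip + phy$Nnode),
                 function(v) phy$edge[phy$edge[, 1] == v, 2])
  Pm <- lapply(seq_len(n_tip + phy$Nnode), function(ch) {
    if (ch == n_tip + 1L) return(NULL)
    as.matrix(Matrix::expm(Q * phy$edge.length[which(phy$edge[, 2] == ch)]))
  })
  internal <- (n_tip + 1L):(n_tip + phy$Nnode)
  Fv <- lapply(internal, function(v) {
    ch <- kids[[v]]
    P1 <- Pm[[ch[1]]]; P2 <- Pm[[ch[2]]]
    arr <- array(0, c(K, Kn, Kn))
    for (tr in seq_along(clado$anc)) {
      s <- clado$anc[tr]
      arr[s, , ] <- arr[s, , ] +
        clado$prob[tr] * outer(P1[clado$left[tr], ], P2[clado$right[tr], ])
    }
    arr
  })
  prior <- rep(1 / K, K)
  m <- length(internal)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), m)))
  endstate <- function(v, row) {
    if (v <= n_tip) tipidx[v] else row[match(v, internal)]
  }
  vals <- apply(grid, 1, function(row) {
    pr <- prior[row[1]]  # internal[1] is the root in ape numbering
    for (i in seq_along(internal)) {
      ch <- kids[[internal[i]]]
      pr <- pr * Fv[[i]][row[i], endstate(ch[1], row), endstate(ch[2], row)]
    }
    pr
  })
  lik <- sum(vals)
  marg <- sapply(seq_along(internal), function(i) {
    out <- tapply(vals, factor(grid[, i], levels = seq_len(K)), sum)
    out[is.na(out)] <- 0
    out / lik
  })
  list(loglik = log(lik), marginals = t(marg))
}

# Two-sided Fisher p for a 2x2 table by direct hypergeometric enumeration.
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Naive O(n^2) Spearman correlation via explicit rank counting (no ties).
spearman_oracle <- function(x, y) {
  rk <- function(v) vapply(seq_along(v), function(i) sum(v <= v[i]), numeric(1))
  rx <- rk(x); ry <- rk(y)
  n <- length(x)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# Brute-force smallest containing clade: scan every internal node of the
# reference tree for the smallest clade containing a given tip set.
containment_oracle <- function(reference_phy, tip_labels) {
  n_tip <- length(reference_phy$tip.label)
  nodes <- (n_tip + 1L):(n_tip + reference_phy$Nnode)
  best <- NA_integer_; best_size <- Inf
  for (v in nodes) {
    tips <- reference_phy$tip.label[
      phangorn::Descendants(reference_phy, v, type = "tips")[[1]]]
    if (all(tip_labels %in% tips) && length(tips) < best_size) {
      best <- v; best_size <- length(tips)
    }
  }
  best
}

# Random small tree with singleton tip states, for likelihood tests.
random_small_ft <- function(n_tips, areas = continent_areas()) {
  phy <- ape::rtree(n_tips)
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.1, 3)
  ages <- stats::setNames(rep(0, n_tips), phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)[seq_len(n_tips)]
  ages[] <- max(depth) - depth
  ages[ages < 1e-12] <- 0
  ranges <- stats::setNames(lapply(seq_len(n_tips), function(i) sample(areas, 1)),
                            phy$tip.label)
  fossil_phylo(phy, ages, tip_ranges = ranges)
}

# Hand-built 6-tip fixture (2 extinct: D age 2 on NA, E age 1 on EU) with
# three cherries; used for the summary-statistics hand enumeration.
fixture_six_tip <- function() {
  phy <- ape::read.tree(text = "((A:4,B:4):1,((C:3,D:1):1,(E:1,F:2):2):1);")
  ages <- c(A = 0, B = 0, C = 0, D = 2, E = 2, F = 0)
  depth <- ape::node.depth.edgelength(phy)[seq_len(6)]
  names(depth) <- phy$tip.label
  ages <- max(depth) - depth  # D = 2, E = 1, others 0
  ranges <- list(A = "NA", B = "EU", C = c("NA", "EU"), D = "NA",
                 E = "EU", F = "SA")
  fossil_phylo(phy, tip_ages = ages, tip_ranges = ranges,
               last_continent = c(D = "NA", E = "EU"))
}
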