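#' DEC / DEC+J model parameters
#'
#' @param d Dispersal (range-expansion) rate per area pair per Ma (>= 0).
#' @param e Per-area range-loss rate per Ma (>= 0).
#' @param j Jump-dispersal (founder-event) cladogenetic weight (>= 0).
#'   DEC is the `j = 0` submodel of DEC+J.
#' @return Object of class `dec_params`.
#' @export
dec_params <- function(d, e, j = 0) {
  stopifnot(is.finite(d), is.finite(e), is.finite(j),
            d >= 0, e >= 0, j >= 0)
  structure(list(d = d, e = e, j = j), class = "dec_params")
}

#' @export
print.dec_params <- function(x, ...) {
  cat(sprintf("DEC%s params: d = %g, e = %g%s\n",
              if (x$j > 0) "+J" else "", x$d, x$e,
              if (x$j > 0) sprintf(", j = %g", x$j) else ""))
  invisible(x)
}

#' Anagenetic rate generator over the range state space
#'
#' Rates of range evolution along branches: expansion from range R to
#' R union \{a\} at rate `d` times the number of areas of R adjacent to `a`
#' (zero between non-adjoining continents); contraction R to R minus \{a\} at
#' rate `e` per member; a singleton contracts to the absorbing null state at
#' rate `e`. Rows sum to zero.
#'
#' @param space A [build_state_space()] object.
#' @param params A [dec_params()].
#' @return Dense (n_states + 1) square matrix; last row/column is the null
#'   state.
#' @export
anagenetic_generator <- function(space, params) {
  K <- space$n_states
  n <- K + 1L
  Q <- matrix(0, n, n, dimnames = list(c(space$keys, "-"), c(space$keys, "-")))
  adj <- space$adjacency
  for (i in seq_len(K)) {
    S <- space$states[[i]]
    size <- length(S)
    if (size < space$max_range_size) {
      for (a in setdiff(seq_len(space$n_areas), S)) {
        n_adj <- sum(adj[S, a])
        if (n_adj > 0) {
          target <- state_key_from_idx(space, sort(c(S, a)))
          Q[i, space$state_id[target]] <- params$d * n_adj
        }
      }
    }
    if (size >= 2) {
      for (a in S) {
        target <- state_key_from_idx(space, setdiff(S, a))
        Q[i, space$state_id[target]] <- Q[i, space$state_id[target]] + params$e
      }
    } else {
      Q[i, n] <- params$e  # singleton -> null (lineage-range extinction)
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

state_key_from_idx <- function(space, idx) paste(space$areas[idx], collapse = "+")

#' Cladogenetic event distribution
#'
#' For each ancestral state, the distribution over ordered daughter-range
#' pairs at speciation. Event weights: narrow sympatry (singleton to two
#' identical copies) 1; subset sympatry (widespread ancestor, one daughter a
#' single member area, the other the full range; both orderings) 1 each;
#' vicariance (disjoint exhaustive split with at least one singleton part;
#' both orderings) 1 each; jump dispersal (one daughter the ancestral range,
#' the other a singleton adjacent to the range and outside it; both
#' orderings) weight `j` each. Weights are normalised to probabilities per
#' ancestral state. With `j = 0` the jump events carry zero mass and the
#' distribution reduces to classic DEC.
#'
#' @inheritParams anagenetic_generator
#' @return Object of class `clado_dist`: parallel vectors `anc`, `left`,
#'   `right` (state indices) and `prob`.
#' @export
clado_distribution <- function(space, params) {
  K <- space$n_states
  anc <- integer(0); left <- integer(0); right <- integer(0); w <- numeric(0)
  add <- function(a, l, r, wt) {
    anc <<- c(anc, a); left <<- c(left, l); right <<- c(right, r); w <<- c(w, wt)
  }
  sid <- function(idx) unname(space$state_id[state_key_from_idx(space, sort(idx))])
  adj <- space$adjacency
  for (i in seq_len(K)) {
    S <- space$states[[i]]
    size <- length(S)
    if (size == 1) {
      add(i, i, i, 1)  # narrow sympatry
    } else {
      for (a in S) {
        sa <- sid(a)
        add(i, sa, i, 1); add(i, i, sa, 1)  # subset sympatry
      }
      # vicariance: disjoint exhaustive split, at least one part a singleton
      for (a in S) {
        rest <- sid(setdiff(S, a)); sa <- sid(a)
        add(i, sa, rest, 1); add(i, rest, sa, 1)
      }
    }
    if (params$j > 0) {
      targets <- which(!seq_len(space$n_areas) %in% S &
                         colSums(adj[S, , drop = FALSE]) > 0)
      for (b in targets) {
        sb <- sid(b)
        add(i, i, sb, params$j); add(i, sb, i, params$j)
      }
    }
  }
  tot <- stats::ave(w, anc, FUN = sum)
  structure(list(anc = anc, left = left, right = right, prob = w / tot,
                 n_states = K), class = "clado_dist")
}

#' Per-ancestral-state daughter pair table
#'
#' @param clado A `clado_dist`.
#' @param state Ancestral state index.
#' @return data.frame with columns `left`, `right`, `prob`.
#' @export
clado_events_for <- function(clado, state) {
  sel <- clado$anc == state
  data.frame(left = clado$left[sel], right = clado$right[sel],
             prob = clado$prob[sel])
}

# Sum x within integer groups 1..K, keeping empty groups as zeros
# (rowsum() drops absent levels, which would silently misalign states).
group_sums <- function(x, idx, K) {
  out <- numeric(K)
  tmp <- rowsum(x, idx)
  out[as.integer(rownames(tmp))] <- tmp[, 1]
  out
}

# Branch transition probability factory: exp(Q t) via eigendecomposition,
# falling back to Matrix::expm if Q is close to defective.
make_branch_prob <- function(Q) {
  n <- nrow(Q)
  eig <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(eig)) {
    Vi <- tryCatch(solve(eig$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      kappa <- max(Mod(eig$vectors)) * max(Mod(Vi))
      use_eigen <- is.finite(kappa) && kappa < 1e8
    }
  }
  if (use_eigen) {
    V <- eig$vectors; lam <- eig$values
    function(t) {
      P <- Re(V %*% (exp(lam * t) * Vi))
      P[P < 0] <- 0
      P
    }
  } else {
    function(t) {
      P <- as.matrix(Matrix::expm(Q * t))
      P[P < 0] <- 0
      P
    }
  }
}

root_prior_vector <- function(space, root_prior) {
  K <- space$n_states
  if (is.character(root_prior)) {
    root_prior <- match.arg(root_prior, "uniform")
    rep(1 / K, K)
  } else {
    stopifnot(length(root_prior) == K, all(root_prior >= 0), sum(root_prior) > 0)
    root_prior / sum(root_prior)
  }
}

tip_state_indices <- function(tree, space) {
  if (is.null(tree$tip_ranges)) stop("tip ranges are not bound; see bind_ranges()")
  vapply(tree$tip_ranges, state_index, integer(1), space = space)
}

# Shared machinery for likelihood and marginals: postorder pruning with
# cladogenetic mixing at internal nodes. Fossil tips need no special
# handling; their conditional likelihood is an indicator at the observed
# state, exactly as for extant tips.
dec_prune <- function(tree, space, params, root_prior = "uniform") {
  phy <- tree$phy
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  K <- space$n_states
  Kn <- K + 1L
  tip_idx <- tip_state_indices(tree, space)

  Q <- anagenetic_generator(space, params)
  Pfun <- make_branch_prob(Q)
  clado <- clado_distribution(space, params)

  po <- ape::reorder.phylo(phy, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  n_edges <- nrow(edge)

  # transition matrix per edge (indexed like po$edge rows)
  Pmats <- lapply(seq_len(n_edges), function(i) Pfun(elen[i]))

  L <- matrix(0, n_tip + n_node, Kn)   # conditional likelihoods at nodes
  D <- matrix(0, n_tip + n_node, Kn)   # branch-top vectors keyed by child node
  for (i in seq_len(n_tip)) L[i, tip_idx[i]] <- 1
  log_scale <- 0
  child_of <- vector("list", n_tip + n_node)

  for (i in seq_len(n_edges)) {
    par <- edge[i, 1]; ch <- edge[i, 2]
    D[ch, ] <- as.vector(Pmats[[i]] %*% L[ch, ])
    child_of[[par]] <- c(child_of[[par]], ch)
    if (length(child_of[[par]]) == 2) {
      c1 <- child_of[[par]][1]; c2 <- child_of[[par]][2]
      u <- clado$prob * D[c1, clado$left] * D[c2, clado$right]
      Lv <- group_sums(u, clado$anc, K)
      s <- max(Lv)
      if (!is.finite(s) || s <= 0) {
        stop("non-finite or zero conditional likelihood at node ", par)
      }
      L[par, seq_len(K)] <- Lv / s
      log_scale <- log_scale + log(s)
    }
  }

  root <- n_tip + 1L
  prior <- root_prior_vector(space, root_prior)
  lik_root <- sum(prior * L[root, seq_len(K)])
  loglik <- log(lik_root) + log_scale

  list(loglik = loglik, L = L, D = D, Pmats = Pmats, edge = edge,
       clado = clado, prior = prior, tip_idx = tip_idx,
       n_tip = n_tip, K = K, root = root, child_of = child_of)
}

#' DEC / DEC+J log-likelihood of tip ranges on a tree
#'
#' Felsenstein pruning with anagenetic transition probabilities
#' `exp(Q t)` along branches and cladogenetic mixing at internal nodes.
#' Fossil tips are handled identically to extant tips. The default root
#' prior is uniform over observable states, with no conditioning on
#' survival.
#'
#' @param tree A `fossil_phylo` with bound tip ranges.
#' @param space A [build_state_space()].
#' @param params A [dec_params()].
#' @param root_prior `"uniform"` or a numeric vector over observable states.
#' @return Log-likelihood (scalar).
#' @export
tree_loglik <- function(tree, space, params, root_prior = "uniform") {
  dec_prune(tree, space, params, root_prior)$loglik
}

#' Marginal ancestral-range probabilities
#'
#' Marginal state probabilities at every internal node, conditioning on all
#' tip data, via a postorder (inside) pass and a preorder (outside) pass.
#' Two continent-level summaries are returned: the inclusion probability
#' P(continent is part of the ancestral area) = sum over states containing
#' the continent, and the split-mode probability where the mass of a
#' widespread state is divided equally among its member continents (e.g. a
#' 20% chance of NA+EU contributes 10% to NA and 10% to EU).
#'
#' @inheritParams tree_loglik
#' @return Object of class `ancestry_profile`: list with `loglik`,
#'   `node` (internal node numbers), `states` (matrix nodes x states),
#'   `inclusion` and `split` (matrices nodes x areas).
#' @export
ancestral_marginals <- function(tree, space, params, root_prior = "uniform") {
  pr <- dec_prune(tree, space, params, root_prior)
  phy <- tree$phy
  n_tip <- pr$n_tip
  K <- pr$K
  Kn <- K + 1L
  clado <- pr$clado

  edge <- pr$edge
  n_nodes <- n_tip + phy$Nnode
  G <- matrix(0, n_nodes, Kn)                 # outside likelihoods
  G[pr$root, seq_len(K)] <- pr$prior

  edge_of_child <- integer(n_nodes)
  edge_of_child[edge[, 2]] <- seq_len(nrow(edge))

  # preorder over internal nodes: parents before children
  internal <- (n_tip + 1L):n_nodes
  # order internal nodes by depth (root first)
  depth <- ape::node.depth.edgelength(phy)
  internal <- internal[order(depth[internal])]

  for (v in internal) {
    ch <- pr$child_of[[v]]
    c1 <- ch[1]; c2 <- ch[2]
    Gv <- G[v, seq_len(K)]
    w_anc <- Gv[clado$anc] * clado$prob
    # child in the left slot, sibling in the right slot (the event list
    # contains both orderings, so slot assignment is symmetric)
    h1 <- c(group_sums(w_anc * pr$D[c2, clado$right], clado$left, K), 0)
    h2 <- c(group_sums(w_anc * pr$D[c1, clado$left], clado$right, K), 0)
    P1 <- pr$Pmats[[edge_of_child[c1]]]
    P2 <- pr$Pmats[[edge_of_child[c2]]]
    g1 <- as.vector(crossprod(P1, h1))
    g2 <- as.vector(crossprod(P2, h2))
    s1 <- sum(g1); s2 <- sum(g2)
    if (s1 > 0) g1 <- g1 / s1
    if (s2 > 0) g2 <- g2 / s2
    G[c1, ] <- g1
    G[c2, ] <- g2
  }

  node_ids <- (n_tip + 1L):n_nodes
  probs <- matrix(0, length(node_ids), K,
                  dimnames = list(node_ids, space$keys))
  for (i in seq_along(node_ids)) {
    v <- node_ids[i]
    m <- G[v, seq_len(K)] * pr$L[v, seq_len(K)]
    tot <- sum(m)
    if (!is.finite(tot) || tot <= 0) {
      stop("non-finite marginal at node ", v)
    }
    probs[i, ] <- m / tot
  }

  M <- space$membership
  inclusion <- probs %*% (M * 1)
  split <- probs %*% ((M * 1) / rowSums(M))
  dimnames(inclusion) <- dimnames(split) <- list(node_ids, space$areas)

  structure(list(loglik = pr$loglik, node = node_ids, states = probs,
                 inclusion = inclusion, split = split, space = space),
            class = "ancestry_profile")
}

#' @export
print.ancestry_profile <- function(x, ...) {
  cat("ancestry_profile:", length(x$node), "internal nodes, lnL =",
      format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' Maximum-likelihood fit of DEC or DEC+J
#'
#' Bounded quasi-Newton (`L-BFGS-B`) optimisation of (d, e) or (d, e, j),
#' with deterministic multi-start from a fixed grid of starting points.
#' Bounds: d, e in \[1e-8, 5\], j in \[0, 3\]. Rates are optimised on the
#' log10 scale (j on the natural scale).
#'
#' @inheritParams tree_loglik
#' @param model `"DEC"` or `"DEC+J"`.
#' @param restarts Number of starting points (1-5). Fewer restarts are
#'   cheaper; all starts are from a fixed deterministic grid.
#' @return List with `params` ([dec_params()]), `loglik`, `model`,
#'   `converged` (logical: did any start converge), `starts` (per-start
#'   table).
#' @export
fit_ml <- function(tree, space, model = c("DEC", "DEC+J"),
                   root_prior = "uniform", restarts = 3) {
  model <- match.arg(model)
  if (length(tree$phy$tip.label) < 3) stop("need at least 3 tips to fit")
  restarts <- max(1L, min(5L, as.integer(restarts)))
  with_j <- model == "DEC+J"

  start_grid <- rbind(
    c(0.05, 0.05, 0.05),
    c(0.30, 0.02, 0.50),
    c(0.01, 0.20, 0.00),
    c(0.50, 0.50, 1.00),
    c(0.005, 0.005, 0.01)
  )[seq_len(restarts), , drop = FALSE]

  negll <- function(par) {
    d <- 10^par[1]; e <- 10^par[2]
    j <- if (with_j) par[3] else 0
    ll <- tryCatch(
      tree_loglik(tree, space, dec_params(d, e, j), root_prior),
      error = function(err) -Inf
    )
    if (!is.finite(ll)) 1e10 else -ll
  }

  lb <- c(log10(1e-8), log10(1e-8)); ub <- c(log10(5), log10(5))
  if (with_j) { lb <- c(lb, 0); ub <- c(ub, 3) }

  rows <- vector("list", restarts)
  best <- NULL
  for (s in seq_len(restarts)) {
    p0 <- c(log10(start_grid[s, 1]), log10(start_grid[s, 2]))
    if (with_j) p0 <- c(p0, start_grid[s, 3])
    fit <- tryCatch(
      stats::optim(p0, negll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 200, factr = 1e9)),
      error = function(err) NULL
    )
    if (is.null(fit)) next
    rows[[s]] <- data.frame(start = s, loglik = -fit$value,
                            convergence = fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  starts <- do.call(rbind, rows)
  params <- dec_params(10^best$par[1], 10^best$par[2],
                       if (with_j) best$par[3] else 0)
  list(params = params, loglik = -best$value, model = model,
       converged = any(starts$convergence == 0), starts = starts)
}
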