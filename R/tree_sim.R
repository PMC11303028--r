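#' Range-evolution simulation parameters
#'
#' The five rates of the four-area forward model (all per Ma, identical
#' across continents): `mu` per-continent extinction, `delta` range
#' expansion to each adjacent continent, `lambda1` sympatric speciation,
#' `lambda2` jump-dispersal speciation per adjacent continent, `lambda3`
#' allopatric speciation of widespread species.
#'
#' @param mu,delta,lambda1,lambda2,lambda3 Non-negative finite rates.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(mu, delta, lambda1, lambda2, lambda3) {
  v <- c(mu = mu, delta = delta, lambda1 = lambda1, lambda2 = lambda2,
         lambda3 = lambda3)
  stopifnot(all(is.finite(v)), all(v >= 0))
  structure(as.list(v), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("sim_params: mu=%g delta=%g lambda1=%g lambda2=%g lambda3=%g\n",
              x$mu, x$delta, x$lambda1, x$lambda2, x$lambda3))
  invisible(x)
}

#' Draw simulation parameters from the uniform priors
#'
#' Independent uniforms: mu, delta, lambda1 ~ U(0,1); lambda2 ~ U(0,0.25);
#' lambda3 ~ U(0,3).
#'
#' @param n Number of draws.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A `sim_params` for `n = 1`, else a list of them.
#' @export
draw_params_from_priors <- function(n = 1, seed = NULL) {
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      sim_params(mu = stats::runif(1), delta = stats::runif(1),
                 lambda1 = stats::runif(1),
                 lambda2 = stats::runif(1, 0, 0.25),
                 lambda3 = stats::runif(1, 0, 3))
    })
  })
  if (n == 1) draws[[1]] else draws
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded draws do not perturb the surrounding random
#' stream. A `NULL` seed evaluates the code under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Per-lineage event rates given an area-index range S (length 1 or 2).
lineage_rates <- function(S, params, adjacency, allow_widespread_jumps = TRUE) {
  if (length(S) == 1) {
    adj_free <- which(adjacency[S, ])
    k <- length(adj_free)
    c(sympatric = params$lambda1, allopatric = 0,
      expansion = params$delta * k, contraction = 0,
      extinction = params$mu, jump = params$lambda2 * k)
  } else {
    adj_free <- which(colSums(adjacency[S, , drop = FALSE]) > 0)
    adj_free <- setdiff(adj_free, S)
    m <- if (allow_widespread_jumps) length(adj_free) else 0
    c(sympatric = 2 * params$lambda1, allopatric = params$lambda3,
      expansion = 0, contraction = 2 * params$mu,
      extinction = 0, jump = params$lambda2 * m)
  }
}

#' Forward Gillespie simulation of the four-area range-evolution model
#'
#' Simulates one realisation from a single ancestor endemic to a uniformly
#' drawn continent (no rejection/retry; see [simulate_tree()]). Ranges are
#' capped at two adjacent continents. The run stops the first time the
#' extant count reaches `n_extant_target`, or on total extinction, or after
#' `max_events` events.
#'
#' @param params A [sim_params()].
#' @param n_extant_target Extant species count at which to stop (>= 2).
#' @param max_events Hard cap on events (guards runaway or stalled runs).
#' @param areas,adjacency Area set and adjacency (defaults: the four
#'   continents on a chain).
#' @param start_area Optional area code for the root lineage; default is a
#'   uniform draw.
#' @param allow_widespread_jumps Allow jump speciation from widespread
#'   ranges to adjacent unoccupied continents (default TRUE).
#' @return List with `success`, `reason`, `time`, `lineages` (data frame),
#'   `events`, `segments` (per-lineage range trajectories), `params`.
#' @export
simulate_forward <- function(params, n_extant_target, max_events = NULL,
                             areas = continent_areas(),
                             adjacency = chain_adjacency(areas),
                             start_area = NULL,
                             allow_widespread_jumps = TRUE) {
  stopifnot(inherits(params, "sim_params"), n_extant_target >= 2)
  n_areas <- length(areas)
  adjacency <- validate_adjacency(adjacency, n_areas)
  if (is.null(max_events)) max_events <- max(2000L, 100L * n_extant_target)

  cap <- 512L
  parent <- integer(cap); t_birth <- numeric(cap); t_end <- rep(NA_real_, cap)
  fate <- character(cap); last_cont <- rep(NA_character_, cap)
  ranges <- vector("list", cap)
  rate_tot <- numeric(cap)
  seg_start <- numeric(cap)
  n_lin <- 0L

  scap <- 1024L; n_seg <- 0L
  seg_lin <- integer(scap); seg_t0 <- numeric(scap); seg_t1 <- numeric(scap)
  seg_range <- character(scap)
  ecap <- 1024L; n_ev <- 0L
  ev_time <- numeric(ecap); ev_lin <- integer(ecap); ev_type <- character(ecap)
  ev_src <- character(ecap); ev_out <- character(ecap)

  grow <- function() {
    cap2 <- cap * 2L
    length(parent) <<- cap2; length(t_birth) <<- cap2; length(t_end) <<- cap2
    length(fate) <<- cap2; length(last_cont) <<- cap2
    length(ranges) <<- cap2; length(rate_tot) <<- cap2; length(seg_start) <<- cap2
    cap <<- cap2
  }
  new_lineage <- function(par, t, S) {
    if (n_lin >= cap) grow()
    n_lin <<- n_lin + 1L
    i <- n_lin
    parent[i] <<- par; t_birth[i] <<- t; fate[i] <<- "alive"
    ranges[[i]] <<- S; seg_start[i] <<- t
    rate_tot[i] <<- sum(lineage_rates(S, params, adjacency, allow_widespread_jumps))
    i
  }
  close_segment <- function(i, t) {
    if (n_seg >= scap) {
      scap <<- scap * 2L
      length(seg_lin) <<- scap; length(seg_t0) <<- scap
      length(seg_t1) <<- scap; length(seg_range) <<- scap
    }
    n_seg <<- n_seg + 1L
    seg_lin[n_seg] <<- i; seg_t0[n_seg] <<- seg_start[i]; seg_t1[n_seg] <<- t
    seg_range[n_seg] <<- paste(areas[ranges[[i]]], collapse = "+")
  }
  log_event <- function(t, i, type, src, out) {
    if (n_ev >= ecap) {
      ecap <<- ecap * 2L
      length(ev_time) <<- ecap; length(ev_lin) <<- ecap
      length(ev_type) <<- ecap; length(ev_src) <<- ecap
      length(ev_out) <<- ecap
    }
    n_ev <<- n_ev + 1L
    ev_time[n_ev] <<- t; ev_lin[n_ev] <<- i; ev_type[n_ev] <<- type
    ev_src[n_ev] <<- src; ev_out[n_ev] <<- out
  }
  rkey <- function(S) paste(areas[sort(S)], collapse = "+")

  root_area <- if (is.null(start_area)) sample.int(n_areas, 1) else match(start_area, areas)
  if (is.na(root_area)) stop("unknown start_area")
  alive <- new_lineage(0L, 0, root_area)
  alive <- c(alive)
  t <- 0
  n_events <- 0L
  success <- FALSE; reason <- NA_character_

  while (TRUE) {
    R <- sum(rate_tot[alive])
    if (length(alive) == 0) { reason <- "total_extinction"; break }
    if (R <= 0) { reason <- "stuck"; break }
    if (n_events >= max_events) { reason <- "max_events"; break }
    t <- t + stats::rexp(1, R)
    i <- if (length(alive) == 1) alive else {
      alive[sample.int(length(alive), 1, prob = rate_tot[alive])]
    }
    S <- ranges[[i]]
    comp <- lineage_rates(S, params, adjacency, allow_widespread_jumps)
    type <- names(comp)[sample.int(6, 1, prob = comp)]
    n_events <- n_events + 1L
    src <- rkey(S)

    if (type == "sympatric") {
      trig <- if (length(S) == 1) S else S[sample.int(2, 1)]
      close_segment(i, t); fate[i] <- "speciated"; t_end[i] <- t
      alive <- setdiff(alive, i)
      d1 <- new_lineage(i, t, trig)
      d2 <- new_lineage(i, t, S)
      alive <- c(alive, d1, d2)
      log_event(t, i, "sympatric", src, paste(rkey(trig), rkey(S), sep = "|"))
    } else if (type == "allopatric") {
      close_segment(i, t); fate[i] <- "speciated"; t_end[i] <- t
      alive <- setdiff(alive, i)
      d1 <- new_lineage(i, t, S[1]); d2 <- new_lineage(i, t, S[2])
      alive <- c(alive, d1, d2)
      log_event(t, i, "allopatric", src, paste(rkey(S[1]), rkey(S[2]), sep = "|"))
    } else if (type == "jump") {
      free <- if (length(S) == 1) which(adjacency[S, ]) else {
        setdiff(which(colSums(adjacency[S, , drop = FALSE]) > 0), S)
      }
      b <- if (length(free) == 1) free else free[sample.int(length(free), 1)]
      close_segment(i, t); fate[i] <- "speciated"; t_end[i] <- t
      alive <- setdiff(alive, i)
      d1 <- new_lineage(i, t, S); d2 <- new_lineage(i, t, b)
      alive <- c(alive, d1, d2)
      log_event(t, i, "jump", src, paste(rkey(S), rkey(b), sep = "|"))
    } else if (type == "expansion") {
      free <- which(adjacency[S, ])
      b <- if (length(free) == 1) free else free[sample.int(length(free), 1)]
      close_segment(i, t)
      ranges[[i]] <- sort(c(S, b)); seg_start[i] <- t
      rate_tot[i] <- sum(lineage_rates(ranges[[i]], params, adjacency,
                                       allow_widespread_jumps))
      log_event(t, i, "expansion", src, rkey(ranges[[i]]))
    } else if (type == "contraction") {
      lost <- S[sample.int(2, 1)]
      close_segment(i, t)
      ranges[[i]] <- setdiff(S, lost); seg_start[i] <- t
      rate_tot[i] <- sum(lineage_rates(ranges[[i]], params, adjacency,
                                       allow_widespread_jumps))
      log_event(t, i, "contraction", src, rkey(ranges[[i]]))
    } else { # extinction of an endemic lineage
      close_segment(i, t); fate[i] <- "extinct"; t_end[i] <- t
      last_cont[i] <- areas[S]
      alive <- setdiff(alive, i)
      log_event(t, i, "extinction", src, "-")
    }

    if (length(alive) >= n_extant_target) { success <- TRUE; break }
  }

  # close open segments and terminal times at the stop instant
  for (i in alive) {
    close_segment(i, t)
    t_end[i] <- t
  }

  idx <- seq_len(n_lin)
  lineages <- data.frame(
    id = idx, parent = parent[idx], t_birth = t_birth[idx],
    t_end = t_end[idx], fate = fate[idx],
    range = vapply(ranges[idx], rkey, character(1)),
    last_continent = last_cont[idx], stringsAsFactors = FALSE
  )
  se <- seq_len(n_ev)
  events <- data.frame(time = ev_time[se], lineage = ev_lin[se],
                       type = ev_type[se], source_range = ev_src[se],
                       outcome = ev_out[se], stringsAsFactors = FALSE)
  ss <- seq_len(n_seg)
  segments <- data.frame(lineage = seg_lin[ss], t0 = seg_t0[ss],
                         t1 = seg_t1[ss], range = seg_range[ss],
                         stringsAsFactors = FALSE)
  list(success = success, reason = reason, time = t, n_events = n_events,
       lineages = lineages, events = events, segments = segments,
       params = params, areas = areas)
}

#' Simulate a tree with extinct lineages retained
#'
#' Repeats [simulate_forward()] until a run first reaches
#' `n_extant_target` extant species (runs ending in total extinction, or
#' stalling, are rejected), then converts the accepted run into a
#' [fossil_phylo()]: extinct lineages become dated tips carrying their
#' range at extinction and last occupied continent; true ranges (the
#' ancestor's range at the instant of speciation) are stored at every
#' internal node. The stem branch below the root split is kept as
#' `phy$root.edge`.
#'
#' @inheritParams simulate_forward
#' @param max_attempts Maximum number of rejected runs before giving up.
#' @param seed Optional integer seed.
#' @return A `fossil_phylo` with `trajectories`, `events` and `sim_time`
#'   populated; attribute `attempts` records how many runs were needed.
#' @export
simulate_tree <- function(params, n_extant_target, seed = NULL,
                          max_attempts = 100, max_events = NULL,
                          areas = continent_areas(),
                          adjacency = chain_adjacency(areas),
                          start_area = NULL, allow_widespread_jumps = TRUE) {
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      sim <- simulate_forward(params, n_extant_target, max_events, areas,
                              adjacency, start_area, allow_widespread_jumps)
      if (sim$success) {
        ft <- sim_to_fossil_phylo(sim)
        attr(ft, "attempts") <- attempt
        return(ft)
      }
    }
    stop("no successful simulation in ", max_attempts,
         " attempts (last failure: ", sim$reason, ")")
  })
}

# Convert an accepted forward run into a fossil_phylo.
sim_to_fossil_phylo <- function(sim) {
  lin <- sim$lineages
  T_stop <- sim$time
  kids <- split(lin$id, factor(lin$parent, levels = lin$id))

  build <- function(i) {
    bl <- lin$t_end[i] - lin$t_birth[i]
    if (lin$fate[i] == "speciated") {
      ch <- kids[[as.character(i)]]
      sprintf("(%s,%s)n%d:%.17g", build(ch[1]), build(ch[2]), i, bl)
    } else {
      sprintf("t%d:%.17g", i, bl)
    }
  }
  root <- lin$id[lin$parent == 0]
  if (lin$fate[root] != "speciated") stop("degenerate simulation: root never speciated")
  ch <- kids[[as.character(root)]]
  stem <- lin$t_end[root] - lin$t_birth[root]
  nwk <- sprintf("(%s,%s)n%d:%.17g;", build(ch[1]), build(ch[2]), root, stem)
  phy <- ape::read.tree(text = nwk)

  is_tip <- lin$fate != "speciated"
  tip_names <- paste0("t", lin$id[is_tip])
  tip_ages <- stats::setNames(T_stop - lin$t_end[is_tip], tip_names)
  tip_ages[tip_ages < 1e-12] <- 0
  tip_ranges <- stats::setNames(
    key_to_range(lin$range[is_tip]), tip_names)
  last_cont <- stats::setNames(lin$last_continent[is_tip], tip_names)
  last_cont <- last_cont[!is.na(last_cont)]
  node_true <- stats::setNames(
    key_to_range(lin$range[!is_tip]), paste0("n", lin$id[!is_tip]))

  species <- paste0(ifelse(is_tip, "t", "n"), lin$id)
  segments <- sim$segments
  segments$species <- paste0(ifelse(lin$fate[segments$lineage] != "speciated",
                                    "t", "n"), segments$lineage)

  fossil_phylo(phy, tip_ages = tip_ages, tip_ranges = tip_ranges,
               last_continent = last_cont, node_true_ranges = node_true,
               trajectories = segments, events = sim$events,
               sim_time = T_stop)
}

#' Realised event-rate bookkeeping for a forward run
#'
#' For each event type, the realised count and the total lineage-time at
#' risk implied by the trajectory (e.g. jump exposure is lineage-time
#' weighted by the number of adjacent unoccupied continents), plus the
#' nominal rate from the parameters. Used for rate-recovery checks:
#' count / exposure should estimate the nominal rate.
#'
#' @param sim Result of [simulate_forward()].
#' @param adjacency Adjacency used in the simulation.
#' @return data.frame with columns `type`, `count`, `exposure`, `nominal`.
#' @export
event_exposures <- function(sim, adjacency = chain_adjacency(sim$areas)) {
  segs <- sim$segments
  areas <- sim$areas
  dt <- segs$t1 - segs$t0
  rng <- key_to_range(segs$range)
  size <- lengths(rng)
  n_adj_free <- vapply(rng, function(r) {
    S <- match(r, areas)
    if (length(S) == 1) sum(adjacency[S, ]) else {
      length(setdiff(which(colSums(adjacency[S, , drop = FALSE]) > 0), S))
    }
  }, numeric(1))

  p <- sim$params
  expo <- c(
    sympatric = sum(size * dt),
    allopatric = sum(dt[size == 2]),
    expansion = sum((n_adj_free * dt)[size == 1]),
    contraction = sum((size * dt)[size == 2]),
    extinction = sum(dt[size == 1]),
    jump = sum(n_adj_free * dt)
  )
  nominal <- c(sympatric = p$lambda1, allopatric = p$lambda3,
               expansion = p$delta, contraction = p$mu,
               extinction = p$mu, jump = p$lambda2)
  counts <- table(factor(sim$events$type, levels = names(expo)))
  data.frame(type = names(expo), count = as.integer(counts),
             exposure = as.numeric(expo), nominal = as.numeric(nominal),
             stringsAsFactors = FALSE)
}
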