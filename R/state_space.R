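#' Build the DEC range state space
#'
#' Enumerates every permitted geographic range (non-empty subset of areas up
#' to `max_range_size`) and appends one internal "null" (empty-range) state
#' used as an absorbing anagenetic state for lineage-range extinction along
#' branches. The null state is never assignable to a tip and is excluded from
#' the root prior and from cladogenesis.
#'
#' Observable states are ordered deterministically: by range size first, then
#' lexicographically by area index within the fixed area order. For 4 areas
#' and `max_range_size = 3` this yields 14 observable states.
#'
#' @param areas Character vector of 2-8 area codes.
#' @param max_range_size Largest permitted range size (>= 1). Reconstruction
#'   uses 3, the forward simulator 2.
#' @param adjacency Logical adjacency matrix; defaults to [chain_adjacency()]
#'   over `areas`.
#' @return An object of class `range_state_space`: a list with `areas`,
#'   `n_areas`, `max_range_size`, `adjacency`, `states` (list of integer area
#'   index vectors), `keys`, `n_states` (observable count), `null_state`
#'   (index of the null state, `n_states + 1`), and `membership` (observable
#'   states x areas logical matrix).
#' @export
build_state_space <- function(areas = continent_areas(), max_range_size = 3,
                              adjacency = NULL) {
  n <- length(areas)
  if (n < 2 || n > 8) stop("between 2 and 8 areas are supported")
  if (anyDuplicated(areas)) stop("duplicate area codes")
  if (max_range_size < 1) stop("max_range_size must be >= 1")
  max_range_size <- min(max_range_size, n)
  if (is.null(adjacency)) adjacency <- chain_adjacency(areas)
  adjacency <- validate_adjacency(adjacency, n)
  dimnames(adjacency) <- list(areas, areas)

  states <- list()
  for (size in seq_len(max_range_size)) {
    combs <- utils::combn(n, size, simplify = FALSE)
    states <- c(states, combs)
  }
  keys <- vapply(states, function(idx) paste(areas[idx], collapse = "+"),
                 character(1))
  K <- length(states)
  membership <- matrix(FALSE, K, n, dimnames = list(keys, areas))
  for (i in seq_len(K)) membership[i, states[[i]]] <- TRUE

  structure(list(
    areas = areas, n_areas = n, max_range_size = max_range_size,
    adjacency = adjacency, states = states, keys = keys,
    n_states = K, null_state = K + 1L, membership = membership,
    state_id = stats::setNames(seq_len(K), keys)
  ), class = "range_state_space")
}

#' @export
print.range_state_space <- function(x, ...) {
  cat("Range state space:", x$n_states, "observable states (+1 null) over",
      x$n_areas, "areas, max range size", x$max_range_size, "\n")
  cat("States:", paste(x$keys, collapse = " "), "\n")
  invisible(x)
}

#' Map ranges to state indices
#'
#' @param x Character vector of area codes (one range), a range key, or a
#'   list of ranges.
#' @param space A `range_state_space`.
#' @return Integer state index (or vector of indices for a list input).
#' @export
state_index <- function(x, space) {
  if (is.list(x)) return(vapply(x, state_index, integer(1), space = space))
  key <- if (length(x) == 1 && grepl("+", x, fixed = TRUE)) {
    range_key(key_to_range(x)[[1]], space$areas)
  } else {
    range_key(x, space$areas)
  }
  id <- space$state_id[key]
  if (is.na(id)) {
    stop("range '", key, "' is not in the state space (max size ",
         space$max_range_size, ")")
  }
  unname(id)
}
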