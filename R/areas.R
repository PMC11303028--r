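#' Continental areas used throughout the package
#'
#' The four continents considered by the biogeographic model, in the fixed
#' order used everywhere (bit order of geography files, columns of rate
#' matrices, membership matrices): South America, North America, Eurasia,
#' Africa.
#'
#' Note that the code for North America is the two-letter string `"NA"`;
#' it is an ordinary character value, not R's missing value. All functions in
#' the package treat area codes as character strings, so this is safe, but
#' callers reading area columns from text files should pass
#' `na.strings = character()` (as [read_occurrences()] does).
#'
#' @return Character vector `c("SA", "NA", "EU", "AF")`.
#' @export
continent_areas <- function() c("SA", "NA", "EU", "AF")

#' Chain adjacency between ordered areas
#'
#' Builds the adjacency matrix for areas arranged on a line: each area is
#' adjacent to its immediate neighbours only. For the default continents this
#' yields the pairs SA-NA, NA-EU and EU-AF, with dispersal between
#' non-adjoining continents (SA-EU, SA-AF, NA-AF) impossible.
#'
#' @param areas Character vector of area codes, in chain order.
#' @return Symmetric logical matrix with `FALSE` on the diagonal.
#' @export
chain_adjacency <- function(areas = continent_areas()) {
  n <- length(areas)
  adj <- matrix(FALSE, n, n, dimnames = list(areas, areas))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      adj[i, i + 1] <- TRUE
      adj[i + 1, i] <- TRUE
    }
  }
  adj
}

validate_adjacency <- function(adjacency, n_areas) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == n_areas,
            ncol(adjacency) == n_areas)
  if (!is.logical(adjacency)) storage.mode(adjacency) <- "logical"
  if (any(diag(adjacency))) stop("adjacency must be irreflexive")
  if (!isTRUE(all(adjacency == t(adjacency)))) {
    stop("adjacency must be symmetric")
  }
  adjacency
}

#' Canonical key for a set of areas
#'
#' Area sets are canonicalised by sorting into the fixed area order and
#' joining with `"+"`, e.g. `c("EU", "NA")` becomes `"NA+EU"`. Used as the
#' state label of the DEC state space and in range columns of output tables.
#'
#' @param x Character vector of area codes (a range), or a list of such
#'   vectors.
#' @param areas Reference area ordering.
#' @return Character key(s).
#' @export
range_key <- function(x, areas = continent_areas()) {
  if (is.list(x)) return(vapply(x, range_key, character(1), areas = areas))
  idx <- match(x, areas)
  if (anyNA(idx)) stop("unknown area code(s): ", paste(setdiff(x, areas), collapse = ", "))
  if (anyDuplicated(idx)) stop("duplicate area codes in range")
  paste(areas[sort(idx)], collapse = "+")
}

#' @rdname range_key
#' @param key Character key as produced by [range_key()].
#' @export
key_to_range <- function(key) strsplit(key, "+", fixed = TRUE)
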