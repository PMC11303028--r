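#' Read a Newick tree with fossil tips
#'
#' Parses a Newick file (branch lengths mandatory, in Ma) and derives tip
#' ages from root-to-tip path lengths: the deepest tip defines the present
#' (age 0). An explicit tip-age table overrides the derived ages. Tips older
#' than `tip_age_tolerance` are flagged extinct.
#'
#' @param path Path to a Newick file containing one tree.
#' @param tip_age_tolerance Age (Ma) above which a tip is considered extinct.
#' @param tip_ages Optional override: a named numeric vector, or a path to a
#'   TSV with columns `species` and `age_Ma`.
#' @return A [fossil_phylo()] (ranges unbound; see [bind_ranges()]).
#' @export
read_newick <- function(path, tip_age_tolerance = 1e-6, tip_ages = NULL) {
  phy <- tryCatch(suppressWarnings(ape::read.tree(path)),
                  error = function(e) NULL)
  if (is.null(phy)) stop("could not parse Newick file: ", path)
  if (inherits(phy, "multiPhylo")) stop("file contains multiple trees; read them individually")
  if (is.null(phy$edge.length)) stop("Newick file lacks branch lengths: ", path)
  if (any(phy$edge.length < 0)) stop("negative branch length in ", path)
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels in ", path)
  ages <- derived_tip_ages(phy)
  if (!is.null(tip_ages)) {
    if (is.character(tip_ages) && length(tip_ages) == 1) {
      tab <- utils::read.table(tip_ages, header = TRUE, sep = "\t",
                               colClasses = c("character", "numeric"),
                               na.strings = character())
      tip_ages <- stats::setNames(tab$age_Ma, tab$species)
    }
    known <- intersect(names(tip_ages), phy$tip.label)
    ages[known] <- tip_ages[known]
  }
  fossil_phylo(phy, tip_ages = ages, extinct_tol = tip_age_tolerance)
}

derived_tip_ages <- function(phy) {
  n_tip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)[seq_len(n_tip)]
  ages <- max(depth) - depth
  # snap float dust so extant tips compare exactly to 0
  ages[ages < 1e-12] <- 0
  stats::setNames(ages, phy$tip.label)
}

#' Write a tree to Newick
#'
#' Branch lengths are written at full double precision so a write/read
#' round trip preserves the path-length matrix to well below 1e-9 Ma.
#'
#' @param tree A `fossil_phylo` or `ape::phylo`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "fossil_phylo")) tree$phy else tree
  if (!inherits(phy, "phylo")) stop("tree must be a fossil_phylo or phylo")
  if (length(phy$tip.label) < 2) stop("binary topology requires at least 2 tips")
  ok <- tryCatch({
    ape::write.tree(phy, file = path, digits = 17)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) stop("could not write Newick to ", path)
  invisible(path)
}

#' Read a Lagrange-style geography file
#'
#' Format: a header line `n_species n_areas (CODE1 CODE2 ...)` followed by
#' one row per species, `name 0110`, where the bit order matches the header
#' area order. The fixed order SA NA EU AF is used throughout this package.
#'
#' @param path Path to the geography file.
#' @return A `geography_table`: binary matrix (species x areas) with an
#'   `areas` attribute.
#' @export
read_geography <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("geography file too short: ", path)
  hdr <- lines[[1]]
  m <- regmatches(hdr, regexec("^(\\d+)\\s+(\\d+)\\s*(?:\\(([^)]*)\\))?\\s*$", hdr))[[1]]
  if (length(m) == 0) stop("malformed geography header: '", hdr, "'")
  n_species <- as.integer(m[2]); n_areas <- as.integer(m[3])
  areas <- if (nzchar(m[4])) strsplit(trimws(m[4]), "\\s+")[[1]] else continent_areas()[seq_len(n_areas)]
  if (length(areas) != n_areas) stop("header declares ", n_areas, " areas but lists ", length(areas))
  rows <- lines[-1]
  if (length(rows) != n_species) {
    stop("header declares ", n_species, " species but file has ", length(rows), " rows")
  }
  parts <- strsplit(rows, "\\s+")
  names_ <- vapply(parts, `[[`, character(1), 1)
  bits <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
  bad <- nchar(bits) != n_areas | grepl("[^01]", bits)
  if (any(bad)) {
    stop("malformed geography row(s): ", paste(names_[bad], collapse = ", "))
  }
  mat <- t(vapply(strsplit(bits, ""), function(b) as.integer(b), integer(n_areas)))
  dimnames(mat) <- list(names_, areas)
  if (any(rowSums(mat) == 0)) {
    stop("all-zero range for: ",
         paste(names_[rowSums(mat) == 0], collapse = ", "),
         " (null ranges are not observable)")
  }
  if (anyDuplicated(names_)) stop("duplicate species in geography file")
  structure(mat, areas = areas, class = c("geography_table", class(mat)))
}

#' Write a Lagrange-style geography file
#'
#' @param x A `geography_table`, or a named list of ranges (character
#'   vectors of area codes).
#' @param path Output file path.
#' @param areas Area order for the bit columns.
#' @return `path`, invisibly.
#' @export
write_geography <- function(x, path, areas = continent_areas()) {
  if (is.list(x)) {
    mat <- matrix(0L, length(x), length(areas),
                  dimnames = list(names(x), areas))
    for (i in seq_along(x)) mat[i, match(x[[i]], areas)] <- 1L
    x <- mat
  }
  areas <- colnames(x)
  hdr <- sprintf("%d %d (%s)", nrow(x), ncol(x), paste(areas, collapse = " "))
  rows <- vapply(seq_len(nrow(x)), function(i) {
    sprintf("%s %s", rownames(x)[i], paste(x[i, ], collapse = ""))
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Attach tip ranges from a geography table
#'
#' Species names must match the tree's tip labels exactly (case-sensitive,
#' no fuzzy rescue); any mismatch is an error naming the offending species.
#'
#' @param tree A `fossil_phylo`.
#' @param table A `geography_table` from [read_geography()].
#' @return The tree with `tip_ranges` populated.
#' @export
bind_ranges <- function(tree, table) {
  stopifnot(inherits(tree, "fossil_phylo"))
  tips <- tree$phy$tip.label
  missing <- setdiff(tips, rownames(table))
  if (length(missing)) {
    stop("geography table is missing species: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(rownames(table), tips)
  if (length(extra)) {
    stop("geography table has species not in the tree: ",
         paste(extra, collapse = ", "))
  }
  areas <- colnames(table)
  tree$tip_ranges <- stats::setNames(lapply(tips, function(sp) {
    areas[table[sp, ] == 1]
  }), tips)
  tree
}

#' Read an occurrence table (species, age, continent)
#'
#' @param path TSV with columns `species`, `age`, `continent`.
#' @return data.frame. The continent column is read as character with no
#'   `NA` coercion (the code "NA" means North America).
#' @export
read_occurrences <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(species = "character", age = "numeric",
                                   continent = "character"),
                    na.strings = character())
}
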