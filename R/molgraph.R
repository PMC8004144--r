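## molgraph: hydrogen-suppressed molecular graphs, atomic properties,
## topological distance matrices.

# Covalent radii (Angstrom) for distance-based bond perception in formats
# that carry no bond records.
.covalent_radii <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
                     I = 1.39)

#' Atomic property table for autocorrelation weighting
#'
#' Per-element atomic mass (`m`), van der Waals volume (`v`), Sanderson
#' electronegativity (`e`) and polarizability (`p`), from the standard
#' descriptor-handbook tabulation.  The default `carbon_scaled` mode
#' divides each column by its carbon value, the convention used by the
#' classic 2D-autocorrelation descriptor software; `raw` keeps the
#' tabulated units (amu, A^3, Sanderson units, A^3).
#'
#' @param scaling `"carbon_scaled"` (default) or `"raw"`.
#' @return data.frame with columns `element`, `m`, `v`, `e`, `p`.
#' @examples
#' atomic_properties()[1:4, ]
#' @export
atomic_properties <- function(scaling = c("carbon_scaled", "raw")) {
  scaling <- match.arg(scaling)
  path <- system.file("extdata", "atomic_properties.csv",
                      package = "dpdaqsar", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (scaling == "carbon_scaled") {
    cref <- tab[tab$element == "C", c("m", "v", "e", "p")]
    for (k in c("m", "v", "e", "p")) tab[[k]] <- tab[[k]] / cref[[k]]
  }
  attr(tab, "scaling") <- scaling
  tab
}

#' Build a hydrogen-suppressed molecular graph
#'
#' Drops hydrogens, keeps the heavy-atom bond graph, computes the
#' topological distance matrix (bond counts, breadth-first search) and
#' attaches the four atomic properties used by the autocorrelation
#' descriptors.  For structures without bond records (e.g. PDB ligands)
#' bonds are perceived from interatomic distances against the sum of
#' covalent radii plus a tolerance.
#'
#' @param structure a `structure_file` from [read_structure()], or any list
#'   with `$atoms` (`element`, `x`, `y`, `z`) and optional `$bonds`.
#' @param properties property table from [atomic_properties()].
#' @param bond_tolerance Angstrom slack added to covalent-radius sums when
#'   perceiving bonds (default 0.45).
#' @return a `molecular_graph`: list with `n_atoms`, `elements`,
#'   `adjacency` (logical matrix), `dist` (topological distances), `props`
#'   (n x 4 matrix, columns `m`, `v`, `e`, `p`) and `coords` (n x 3 or
#'   `NULL`).
#' @examples
#' g <- build_graph(read_structure("CCC", format = "smiles"))
#' g$dist
#' @export
build_graph <- function(structure, properties = atomic_properties(),
                        bond_tolerance = 0.45) {
  atoms <- structure$atoms
  heavy <- which(atoms$element != "H")
  n <- length(heavy)
  if (n < 1L) stop("structure has no heavy atoms")
  el <- atoms$element[heavy]
  coords <- NULL
  has_coords <- all(c("x", "y", "z") %in% names(atoms)) &&
    any(abs(c(atoms$x, atoms$y, atoms$z)) > 0)
  if (has_coords)
    coords <- as.matrix(atoms[heavy, c("x", "y", "z")])

  adj <- matrix(FALSE, n, n)
  if (!is.null(structure$bonds)) {
    map <- match(seq_len(nrow(atoms)), heavy)  # old index -> heavy index
    for (r in seq_len(nrow(structure$bonds))) {
      i <- map[structure$bonds$i[r]]; j <- map[structure$bonds$j[r]]
      if (!is.na(i) && !is.na(j)) adj[i, j] <- adj[j, i] <- TRUE
    }
  } else {
    if (is.null(coords))
      stop("structure has neither bonds nor coordinates; cannot build graph")
    rad <- .covalent_radii[el]
    if (anyNA(rad))
      stop("no covalent radius for element(s): ",
           paste(unique(el[is.na(rad)]), collapse = ", "))
    d3 <- as.matrix(stats::dist(coords))
    thr <- outer(rad, rad, "+") + bond_tolerance
    adj <- d3 <= thr & upper.tri(d3) | t(d3 <= thr & upper.tri(d3))
  }
  diag(adj) <- FALSE

  if (n == 1L) {
    dist <- matrix(0, 1, 1)
  } else {
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    dist <- igraph::distances(ig)
    if (any(is.infinite(dist)))
      stop("disconnected heavy-atom graph (salts/mixtures unsupported)")
    dimnames(dist) <- NULL
  }

  unknown <- setdiff(unique(el), properties$element)
  if (length(unknown) > 0)
    stop("unknown element(s) in property table: ", paste(unknown, collapse = ", "))
  props <- as.matrix(properties[match(el, properties$element),
                                c("m", "v", "e", "p")])
  rownames(props) <- NULL
  if (any(props <= 0)) stop("atomic properties must be strictly positive")

  structure(list(n_atoms = n, elements = el, adjacency = adj,
                 dist = dist, props = props, coords = coords,
                 scaling = attr(properties, "scaling") %||% "carbon_scaled"),
            class = "molecular_graph")
}

#' Topological diameter of a molecular graph
#'
#' @param g a `molecular_graph`.
#' @return largest topological distance between any two atoms (0 for a
#'   single atom).
#' @export
graph_diameter <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  max(g$dist)
}

# Induced subgraph on a set of atoms (keeps coords and props, recomputes
# distances); used by the fragment RMSD machinery.
subgraph <- function(g, atoms) {
  stopifnot(inherits(g, "molecular_graph"))
  atoms <- sort(unique(as.integer(atoms)))
  if (any(atoms < 1L | atoms > g$n_atoms)) stop("atom index out of range")
  n <- length(atoms)
  adj <- g$adjacency[atoms, atoms, drop = FALSE]
  if (n == 1L) {
    dist <- matrix(0, 1, 1)
  } else {
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    dist <- igraph::distances(ig)
    if (any(is.infinite(dist))) stop("selected atoms do not form a connected subgraph")
    dimnames(dist) <- NULL
  }
  structure(list(n_atoms = n, elements = g$elements[atoms],
                 adjacency = adj, dist = dist,
                 props = g$props[atoms, , drop = FALSE],
                 coords = if (is.null(g$coords)) NULL else
                   g$coords[atoms, , drop = FALSE],
                 scaling = g$scaling),
            class = "molecular_graph")
}

# Atoms that belong to at least one cycle (used by the flexible MCS mode
# and the aromatic interaction typing).
ring_atoms <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  # an edge is a bridge iff it lies on no cycle; a vertex is a ring atom iff
  # it has at least one non-bridge incident edge
  br <- igraph::bridges(ig)
  em <- igraph::as_edgelist(ig)
  if (nrow(em) == 0) return(logical(g$n_atoms))
  nonbridge <- rep(TRUE, nrow(em))
  if (length(br) > 0) nonbridge[as.integer(br)] <- FALSE
  out <- logical(g$n_atoms)
  out[unique(as.integer(em[nonbridge, ]))] <- TRUE
  out
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph>", x$n_atoms, "heavy atoms (",
      paste(unique(x$elements), collapse = ","), "), diameter",
      max(x$dist), if (!is.null(x$coords)) "- with coordinates", "\n")
  invisible(x)
}
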