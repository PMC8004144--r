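## poserms: maximum-common-substructure pose comparison and in-place RMSD.
##
## The matcher finds a maximum common connected induced subgraph by
## branch-and-bound backtracking (exact for ligand-sized molecules; a node
## limit aborts with an explicit error rather than approximating).  Among
## all matches of maximal size it keeps the one with minimal RMSD, which
## makes the comparison symmetry-aware (e.g. a benzene ring matched onto a
## relabeled copy of itself gives RMSD 0).

# Atom-pair compatibility.  strict: same element.  flexible: additionally
# allows C/N/O/S swaps when both atoms are ring members of equal degree
# (heteroaromatic ring atoms treated as equivalent to ring carbons).
.flexible_elements <- c("C", "N", "O", "S")

mcs_compatible <- function(ref, mol, mode) {
  n1 <- ref$n_atoms; n2 <- mol$n_atoms
  comp <- outer(ref$elements, mol$elements, "==")
  if (mode == "flexible") {
    r1 <- ring_atoms(ref); r2 <- ring_atoms(mol)
    d1 <- rowSums(ref$adjacency); d2 <- rowSums(mol$adjacency)
    ok1 <- ref$elements %in% .flexible_elements & r1
    ok2 <- mol$elements %in% .flexible_elements & r2
    comp <- comp | (outer(ok1, ok2, "&") & outer(d1, d2, "=="))
  }
  comp
}

#' Maximum-common-substructure atom mapping between two molecules
#'
#' Exact search for the largest connected common induced subgraph.  In
#' `strict` mode matched atoms must share the element; in `flexible` mode
#' ring atoms of C/N/O/S with equal degree are interchangeable (so e.g. a
#' pyridine nitrogen can stand in for a benzene carbon).  When both
#' molecules carry coordinates, ties among maximum-size mappings are
#' broken by minimal in-place RMSD.
#'
#' @param ref,mol `molecular_graph` objects (see [build_graph()]).
#' @param mode `"strict"` (default) or `"flexible"`.
#' @param node_limit abort (with an error) after this many search-tree
#'   nodes (default 1e6).
#' @return an `atom_mapping`: list with `pairs` (two-column matrix of ref
#'   and mol atom indices), `mode`, `pct_ref_match`, `pct_mol_match`,
#'   `rmsd` (NA without coordinates) and `n_nodes_searched`.
#' @export
mcs_match <- function(ref, mol, mode = c("strict", "flexible"),
                      node_limit = 1e6) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "molecular_graph"), inherits(mol, "molecular_graph"))
  n1 <- ref$n_atoms; n2 <- mol$n_atoms
  comp <- mcs_compatible(ref, mol, mode)
  use_coords <- !is.null(ref$coords) && !is.null(mol$coords)
  # squared inter-atom coordinate distances for incremental RMSD
  sqd <- if (use_coords)
    outer(rowSums(ref$coords^2), rowSums(mol$coords^2), "+") -
      2 * ref$coords %*% t(mol$coords)
  else NULL

  env <- new.env(parent = emptyenv())
  env$best_size <- 0L
  env$best_ss <- Inf
  env$best_map <- integer(0)
  env$nodes <- 0L

  record <- function(map_ref, map_mol, ss) {
    k <- length(map_ref)
    if (k > env$best_size ||
        (k == env$best_size && use_coords && ss < env$best_ss - 1e-12)) {
      env$best_size <- k
      env$best_ss <- ss
      env$best_map <- rbind(map_ref, map_mol)
    }
  }

  extend <- function(map_ref, map_mol, used2, excluded, ss) {
    env$nodes <- env$nodes + 1L
    if (env$nodes > node_limit)
      stop("MCS search limit exceeded (", node_limit,
           " nodes); molecules too large or symmetric for exact matching")
    k <- length(map_ref)
    record(map_ref, map_mol, ss)
    # frontier: unmapped, unexcluded ref atoms adjacent to the mapped set
    cand <- if (k == 0L) which(!excluded)
            else {
              adj <- which(colSums(ref$adjacency[map_ref, , drop = FALSE]) > 0)
              adj[!excluded[adj] & !(adj %in% map_ref)]
            }
    if (length(cand) == 0L) return(invisible())
    # bound: can never beat the best size -> prune (ties kept for RMSD)
    ub <- k + min(sum(!excluded) - k, n2 - k)
    if (ub < env$best_size) return(invisible())
    u <- cand[1L]
    vs <- which(comp[u, ] & !used2)
    for (v in vs) {
      ok <- TRUE
      for (t in seq_len(k)) {  # induced-subgraph consistency
        if (ref$adjacency[u, map_ref[t]] != mol$adjacency[v, map_mol[t]]) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      used2[v] <- TRUE
      extend(c(map_ref, u), c(map_mol, v), used2, excluded,
             ss + if (use_coords) sqd[u, v] else 0)
      used2[v] <- FALSE
    }
    excluded[u] <- TRUE
    extend(map_ref, map_mol, used2, excluded, ss)
  }

  extend(integer(0), integer(0), logical(n2), logical(n1), 0)

  if (env$best_size < 3L)
    stop("no meaningful match: largest common substructure has ",
         env$best_size, " atom(s) (< 3)")
  pairs <- t(env$best_map)
  colnames(pairs) <- c("ref", "mol")
  structure(list(pairs = pairs, mode = mode,
                 pct_ref_match = 100 * nrow(pairs) / n1,
                 pct_mol_match = 100 * nrow(pairs) / n2,
                 rmsd = if (use_coords) sqrt(max(env$best_ss, 0) / nrow(pairs))
                        else NA_real_,
                 n_nodes_searched = env$nodes),
            class = "atom_mapping")
}

#' @export
print.atom_mapping <- function(x, ...) {
  cat(sprintf("<atom_mapping> %d pairs (%s mode), %%Ref = %.1f, %%Mol = %.1f",
              nrow(x$pairs), x$mode, x$pct_ref_match, x$pct_mol_match))
  if (is.finite(x$rmsd)) cat(sprintf(", RMSD = %.3f A", x$rmsd))
  cat("\n")
  invisible(x)
}

# Kabsch least-squares superposition of b onto a (n x 3 matrices).
kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(b0, a0))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(b0 %*% t(rot), 2, ca, "+")
}

#' In-place RMSD between two docked poses over their common substructure
#'
#' Matches the maximum common substructure (see [mcs_match()]) and reports
#' the heavy-atom RMSD over the matched pairs, minimized over all
#' maximum-size matchings (symmetry-aware).  Poses are compared in place
#' -- in the common receptor frame -- by default; `superpose = TRUE`
#' applies a least-squares fit first.
#'
#' @inheritParams mcs_match
#' @param superpose least-squares-superpose `mol` onto `ref` over the
#'   matched atoms before measuring (default `FALSE`).
#' @return a `pose_comparison`: list with `rmsd` (Angstrom), `mapping`
#'   (the `atom_mapping`) and `n_isomorphisms_searched`.
#' @export
pose_rmsd <- function(ref, mol, mode = c("strict", "flexible"),
                      superpose = FALSE, node_limit = 1e6) {
  mode <- match.arg(mode)
  if (is.null(ref$coords) || is.null(mol$coords))
    stop("pose_rmsd requires coordinates on both molecules")
  m <- mcs_match(ref, mol, mode, node_limit = node_limit)
  rmsd <- m$rmsd
  if (superpose) {
    a <- ref$coords[m$pairs[, 1], , drop = FALSE]
    b <- mol$coords[m$pairs[, 2], , drop = FALSE]
    bfit <- kabsch(a, b)
    rmsd <- sqrt(mean(rowSums((a - bfit)^2)))
  }
  structure(list(rmsd = rmsd, mapping = m,
                 n_isomorphisms_searched = m$n_nodes_searched),
            class = "pose_comparison")
}

#' @export
print.pose_comparison <- function(x, ...) {
  cat(sprintf("<pose_comparison> RMSD = %.3f A over %d matched atoms (%s mode)\n",
              x$rmsd, nrow(x$mapping$pairs), x$mapping$mode))
  invisible(x)
}

#' Fragment-restricted in-place RMSD
#'
#' Restricts the reference to a connected fragment (e.g. the
#' pentadienamide neck or the heterocyclic head of a DPDA) and matches
#' that whole fragment into the other molecule, reporting the in-place
#' RMSD over the fragment atoms.
#'
#' @inheritParams pose_rmsd
#' @param fragment integer vector of reference atom indices forming a
#'   connected subgraph.
#' @return the fragment RMSD in Angstrom (a single number).
#' @export
fragment_rmsd <- function(ref, mol, fragment, mode = c("strict", "flexible"),
                          node_limit = 1e6) {
  mode <- match.arg(mode)
  frag <- subgraph(ref, fragment)
  if (is.null(frag$coords) || is.null(mol$coords))
    stop("fragment_rmsd requires coordinates on both molecules")
  m <- mcs_match(frag, mol, mode, node_limit = node_limit)
  if (nrow(m$pairs) < frag$n_atoms)
    stop("fragment not matchable: only ", nrow(m$pairs), " of ",
         frag$n_atoms, " fragment atoms matched")
  m$rmsd
}
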