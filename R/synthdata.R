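## synthdata: synthetic inputs with known ground truth for every pipeline
## stage -- planted sparse linear activity models, toy protein-ligand
## complexes with prescribed geometry, and perturbed pose replicas.

#' Specification of a planted sparse linear activity model
#'
#' Defaults mirror the modelling scale of the DPDA study: 64 compounds,
#' 96 candidate descriptors, 6 true descriptors, 52/12 training/test
#' split.  Descriptors are block-correlated Gaussians; the activity is a
#' sparse linear combination plus Gaussian noise.
#'
#' @param n_compounds number of rows (default 64).
#' @param n_descriptors number of candidate descriptors (default 96).
#' @param k_true number of descriptors carrying signal (default 6).
#' @param coef_range absolute-value range of true coefficients (default
#'   `c(1, 3)`; signs random).
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   the activity (default 0.1).
#' @param block_size descriptors per correlated block (default 8).
#' @param block_rho within-block correlation (default 0.5; pairwise
#'   r^2 = 0.25, safely below the collinearity filter).
#' @param intercept true intercept (default 0).
#' @param seed RNG seed.
#' @return a list of class `planted_qsar_spec`.
#' @export
planted_qsar_spec <- function(n_compounds = 64, n_descriptors = 96,
                              k_true = 6, coef_range = c(1, 3),
                              noise_sd = 0.1, block_size = 8,
                              block_rho = 0.5, intercept = 0, seed = 1) {
  stopifnot(k_true <= n_descriptors, noise_sd >= 0,
            block_rho >= 0, block_rho < 1)
  structure(list(n_compounds = n_compounds, n_descriptors = n_descriptors,
                 k_true = k_true, coef_range = coef_range,
                 noise_sd = noise_sd, block_size = block_size,
                 block_rho = block_rho, intercept = intercept, seed = seed),
            class = "planted_qsar_spec")
}

#' Generate a descriptor table with a planted activity relationship
#'
#' @param spec a [planted_qsar_spec()].
#' @return list with `table` (n x p matrix, columns `X001`, ...), `y`
#'   (activities) and `truth` (true descriptor names, coefficients,
#'   intercept, noise_sd and the spec itself).  Deterministic per seed.
#' @examples
#' sim <- gen_planted_qsar(planted_qsar_spec(noise_sd = 0, seed = 7))
#' m <- fit_mlr(sim$table[, sim$truth$descriptors], sim$y)
#' m$r2  # 1: noiseless planted model
#' @export
gen_planted_qsar <- function(spec = planted_qsar_spec()) {
  stopifnot(inherits(spec, "planted_qsar_spec"))
  with_seed(spec$seed, {
    n <- spec$n_compounds; p <- spec$n_descriptors
    # block-correlated Gaussians via shared block factors
    nblock <- ceiling(p / spec$block_size)
    block <- rep(seq_len(nblock), each = spec$block_size)[seq_len(p)]
    f <- matrix(rnorm(n * nblock), n, nblock)
    rho <- spec$block_rho
    X <- sqrt(rho) * f[, block, drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    colnames(X) <- sprintf("X%03d", seq_len(p))
    truth_idx <- sort(sample.int(p, spec$k_true))
    beta <- runif(spec$k_true, spec$coef_range[1], spec$coef_range[2]) *
      sample(c(-1, 1), spec$k_true, replace = TRUE)
    y <- spec$intercept + drop(X[, truth_idx, drop = FALSE] %*% beta) +
      rnorm(n, sd = spec$noise_sd)
    list(table = X, y = y,
         truth = list(descriptors = colnames(X)[truth_idx],
                      indices = truth_idx, coefficients = beta,
                      intercept = spec$intercept, noise_sd = spec$noise_sd,
                      spec = spec))
  })
}

#' Specification of a toy protein-ligand complex
#'
#' Each prescribed interaction is realized geometrically around a small
#' amide-bearing ligand; residues are placed in well-separated directions
#' so that no unintended heavy-atom pair falls under the contact cutoff.
#'
#' @param interactions list of interaction prescriptions; each a list with
#'   `resname`, `resnum`, optional `chain` (default `"A"`), `type` (one of
#'   `"hydrophobic"`, `"polar"`, `"hbond_donor"` (residue donates),
#'   `"hbond_acceptor"` (residue accepts)), and geometry: `distance`
#'   (heavy-atom or H...A distance, Angstrom), plus for hydrogen bonds
#'   `donor_angle` (D-H...A, degrees, default 170) and `acceptor_angle`
#'   (at the acceptor, default 120).
#' @param seed RNG seed (placement directions are deterministic; the seed
#'   covers optional jitter hooks).
#' @return a list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(interactions, seed = 1) {
  stopifnot(length(interactions) >= 1)
  structure(list(interactions = interactions, seed = seed),
            class = "toy_complex_spec")
}

# Well-separated unit directions (vertices of an icosahedron, normalized).
.toy_directions <- local({
  phi <- (1 + sqrt(5)) / 2
  # out-of-plane directions first: the ligand lies in the z = 0 plane
  m <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
             c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1),
             c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0))
  m / sqrt(rowSums(m^2))
})

#' Construct a toy complex frame satisfying prescribed interactions
#'
#' The ligand is a fixed five-heavy-atom amide fragment
#' (CH3-C(=O)-NH-CH3 with an explicit amide hydrogen): carbonyl oxygen
#' `O1` (acceptor, antecedent `C1`), amide `N1`-`H1` (donor) and carbons
#' `C1`, `C2`, `C3`.  Each prescribed interaction gets its own residue
#' placed along a separate direction with the requested geometry; after
#' construction every unintended protein-ligand heavy-atom pair is
#' verified to lie above 4.0 A, otherwise the prescription is rejected.
#'
#' @param spec a [toy_complex_spec()].
#' @return a `complex_frame`.
#' @examples
#' cx <- gen_toy_complex(toy_complex_spec(list(
#'   list(resname = "SER", resnum = 512, type = "hbond_donor",
#'        distance = 2.0, donor_angle = 170, acceptor_angle = 120))))
#' detect_hbonds(cx)$category  # "D"
#' @export
gen_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  ints <- spec$interactions
  if (length(ints) > nrow(.toy_directions))
    stop("at most ", nrow(.toy_directions), " prescribed interactions supported")

  # ligand: CH3-C(=O)-NH-CH3, amide plane z = 0
  lig_atoms <- data.frame(
    name = c("C1", "O1", "N1", "C2", "C3", "H1"),
    element = c("C", "O", "N", "C", "C", "H"),
    x = c(0.000, 0.600, -0.700, -2.150, 0.720, -0.940),
    y = c(0.000, 1.060, -0.980, -0.900, -1.280, -1.960),
    z = c(0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  lig_bonds <- data.frame(i = c(1, 1, 1, 3, 3), j = c(2, 3, 5, 4, 6),
                          order = c(2, 1, 1, 1, 1))
  lxyz <- as.matrix(lig_atoms[, c("x", "y", "z")])
  rownames(lxyz) <- lig_atoms$name
  unit <- function(v) v / sqrt(sum(v^2))

  rot <- function(v, axis, ang) {  # Rodrigues rotation
    axis <- unit(axis)
    v * cos(ang) + c(axis[2] * v[3] - axis[3] * v[2],
                     axis[3] * v[1] - axis[1] * v[3],
                     axis[1] * v[2] - axis[2] * v[1]) * sin(ang) +
      axis * sum(axis * v) * (1 - cos(ang))
  }
  lheavy <- lxyz[lig_atoms$element != "H", , drop = FALSE]

  # Build the residue atoms for one interaction along a candidate
  # direction; returns a matrix of rows (name, element, x, y, z) or NULL.
  build_residue <- function(it, dirn) {
    atoms <- list()
    add_atom <- function(name, element, xyz)
      atoms[[length(atoms) + 1L]] <<- list(name = name, element = element,
                                           xyz = xyz)
    if (it$type == "hydrophobic") {
      cb <- lxyz["C2", ] + it$distance * dirn
      add_atom("CB", "C", cb)
      add_atom("CA", "C", cb + 1.53 * dirn)
    } else if (it$type == "polar") {
      og <- lxyz["O1", ] + it$distance * dirn
      add_atom("OG", "O", og)
      add_atom("CB", "C", og + 1.43 * dirn)
      add_atom("CA", "C", og + 2.96 * dirn)
    } else if (it$type == "hbond_donor") {
      # residue O-H donating to ligand acceptor O1 (antecedent C1):
      # H at `distance` from O1 making the acceptor angle with O1->C1,
      # donor O beyond H making the donor angle at H.
      th_a <- (it$acceptor_angle %||% 120) * pi / 180
      th_d <- (it$donor_angle %||% 170) * pi / 180
      a <- lxyz["O1", ]
      ante_dir <- unit(lxyz["C1", ] - a)
      perp <- unit(dirn - sum(dirn * ante_dir) * ante_dir)
      hdir <- cos(th_a) * ante_dir + sin(th_a) * perp
      h <- a + it$distance * hdir
      to_a <- unit(a - h)
      ax <- c(ante_dir[2] * perp[3] - ante_dir[3] * perp[2],
              ante_dir[3] * perp[1] - ante_dir[1] * perp[3],
              ante_dir[1] * perp[2] - ante_dir[2] * perp[1])
      ddir <- rot(to_a, ax, th_d)
      dpos <- h + 0.96 * ddir
      add_atom("OG", "O", dpos)
      add_atom("HG", "H", h)
      # CB at the tetrahedral angle from the O-H bond, leaning away from
      # the ligand
      to_h <- unit(h - dpos)
      cb_dir <- rot(to_h, ax, 109.5 * pi / 180)
      if (sum((dpos + 1.43 * cb_dir - a)^2) <
            sum((dpos + 1.43 * rot(to_h, ax, -109.5 * pi / 180) - a)^2))
        cb_dir <- rot(to_h, ax, -109.5 * pi / 180)
      add_atom("CB", "C", dpos + 1.43 * cb_dir)
    } else if (it$type == "hbond_acceptor") {
      # ligand N1-H1 donates to a residue acceptor placed off the N-H
      # axis so that the donor angle at H1 is as prescribed.
      th_d <- (it$donor_angle %||% 170) * pi / 180
      th_a <- (it$acceptor_angle %||% 120) * pi / 180
      n1 <- lxyz["N1", ]; h1 <- lxyz["H1", ]
      nh <- unit(h1 - n1)
      perp <- unit(dirn - sum(dirn * nh) * nh)
      adir <- cos(pi - th_d) * nh + sin(pi - th_d) * perp
      apos <- h1 + it$distance * adir
      to_h <- unit(h1 - apos)
      perp2 <- unit(nh - sum(nh * to_h) * to_h)
      cdir <- cos(th_a) * to_h + sin(th_a) * perp2
      add_atom("O", "O", apos)
      add_atom("C", "C", apos + 1.23 * cdir)
    } else stop("unknown interaction type: ", it$type)
    atoms
  }

  # acceptability of a candidate placement against the ligand
  placement_ok <- function(it, atoms) {
    hxyz <- do.call(rbind, lapply(atoms, `[[`, "xyz"))
    hxyz <- hxyz[vapply(atoms, `[[`, "", "element") != "H", , drop = FALSE]
    dm <- sqrt(outer(rowSums(hxyz^2), rowSums(lheavy^2), "+") -
                 2 * hxyz %*% t(lheavy))
    if (min(dm) < 2.2) return(FALSE)
    if (it$type %in% c("hydrophobic", "polar") &&
        abs(min(dm) - it$distance) > 0.05) return(FALSE)
    TRUE
  }

  prot <- list()
  used_dir <- logical(nrow(.toy_directions))
  for (i in seq_along(ints)) {
    it <- ints[[i]]
    chain <- it$chain %||% "A"
    placed <- FALSE
    for (di in which(!used_dir)) {
      atoms <- build_residue(it, .toy_directions[di, ])
      if (placement_ok(it, atoms)) {
        used_dir[di] <- TRUE
        for (a in atoms)
          prot[[length(prot) + 1L]] <- data.frame(
            chain = chain, resname = it$resname, resnum = it$resnum,
            name = a$name, element = a$element,
            x = a$xyz[1], y = a$xyz[2], z = a$xyz[3],
            stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("unsatisfiable prescription for ",
           res_key(chain, it$resname, it$resnum),
           ": no clash-free placement direction found")
  }
  protein <- do.call(rbind, prot)
  cx <- complex_frame(protein, list(atoms = lig_atoms, bonds = lig_bonds))

  # post-hoc verification: each residue realizes its prescription and
  # nothing unintended falls under the 4.0 A contact cutoff
  lh <- cx$ligand$atoms[cx$ligand$atoms$element != "H", , drop = FALSE]
  lhxyz <- as.matrix(lh[, c("x", "y", "z")])
  for (i in seq_along(ints)) {
    it <- ints[[i]]
    key_i <- res_key(it$chain %||% "A", it$resname, it$resnum)
    rows <- cx$protein[res_key(cx$protein$chain, cx$protein$resname,
                               cx$protein$resnum) == key_i &
                         cx$protein$element != "H", , drop = FALSE]
    rxyz <- as.matrix(rows[, c("x", "y", "z")])
    dm <- sqrt(outer(rowSums(rxyz^2), rowSums(lhxyz^2), "+") -
                 2 * rxyz %*% t(lhxyz))
    if (min(dm) < 2.2)
      stop("unsatisfiable prescription for ", key_i,
           ": steric clash at ", round(min(dm), 2), " A")
    if (it$type %in% c("hydrophobic", "polar")) {
      if (abs(min(dm) - it$distance) > 0.05)
        stop("unsatisfiable prescription for ", key_i,
             ": realized closest distance ", round(min(dm), 2),
             " A, prescribed ", it$distance)
      # a non-contact prescription must stay a non-contact
      if (it$distance > 4.0 && min(dm) <= 4.0)
        stop("unintended contact constructed for ", key_i)
    }
  }
  cx
}

#' Rigidly transform and perturb a pose
#'
#' Applies a rigid rotation (about the centroid) and translation to a
#' molecule's coordinates, then adds i.i.d. Gaussian displacement per
#' coordinate.  Deterministic for a given seed.
#'
#' @param g a `molecular_graph` with coordinates (or any matrix-like of
#'   n x 3 coordinates).
#' @param translation length-3 numeric (default none).
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param per_atom_sd standard deviation of the per-coordinate Gaussian
#'   displacement (default 0).
#' @param seed RNG seed.
#' @return a `molecular_graph` with transformed coordinates (or a matrix
#'   when `g` is a matrix).
#' @export
gen_perturbed_pose <- function(g, translation = c(0, 0, 0),
                               rotation = diag(3), per_atom_sd = 0,
                               seed = 1) {
  coords <- if (inherits(g, "molecular_graph")) g$coords else as.matrix(g)
  if (is.null(coords)) stop("molecule has no coordinates")
  ctr <- colMeans(coords)
  out <- sweep(sweep(coords, 2, ctr) %*% t(rotation), 2, ctr + translation, "+")
  if (per_atom_sd > 0)
    out <- out + with_seed(seed,
      matrix(rnorm(length(out), sd = per_atom_sd), nrow(out), 3))
  if (inherits(g, "molecular_graph")) { g$coords <- out; g } else out
}
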