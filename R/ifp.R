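## ifp: geometric interaction fingerprints for protein-ligand complexes and
## the vanilloid-pocket distance rule.

.backbone_names <- c("N", "CA", "C", "O", "OXT")
.standard_resnames <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                        "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                        "PRO", "SER", "THR", "TRP", "TYR", "VAL")
.aromatic_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
.charged_atoms <- list(
  ARG = c("NE", "NH1", "NH2", "CZ"),
  LYS = c("NZ"),
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"))

#' Atom-class rules used by the interaction fingerprints
#'
#' Packaged, overridable definitions of which atoms count as polar,
#' hydrophobic, aromatic or charged.  The published fingerprinting tool's
#' internal typing is not public; these rules are this package's
#' documented interpretation.
#'
#' @return a list with elements `polar_elements`, `hydrophobic_elements`,
#'   `aromatic_atoms` (per-residue atom names), `charged_atoms`
#'   (per-residue atom names).
#' @export
ifp_atom_classes <- function() {
  list(polar_elements = c("N", "O", "S"),
       hydrophobic_elements = "C",
       aromatic_atoms = .aromatic_atoms,
       charged_atoms = .charged_atoms)
}

#' Assemble a protein-ligand complex frame
#'
#' @param protein data.frame of protein atoms: `chain`, `resname`,
#'   `resnum`, `name`, `element`, `x`, `y`, `z` (hydrogens optional,
#'   element `"H"`).
#' @param ligand a `structure_file`, or a list with `$atoms` (data.frame
#'   `name`, `element`, `x`, `y`, `z`) and optional `$bonds`.
#' @return a `complex_frame`; protein atoms gain a `backbone` flag (atom
#'   names N/CA/C/O/OXT in standard residues).
#' @export
complex_frame <- function(protein, ligand) {
  stopifnot(is.data.frame(protein),
            all(c("chain", "resname", "resnum", "name", "element",
                  "x", "y", "z") %in% names(protein)))
  if (is.null(ligand$atoms)) stop("ligand absent from complex")
  protein$backbone <- protein$name %in% .backbone_names &
    protein$resname %in% .standard_resnames
  la <- ligand$atoms
  stopifnot(all(c("name", "element", "x", "y", "z") %in% names(la)))
  if (!all(is.finite(c(protein$x, protein$y, protein$z, la$x, la$y, la$z))))
    stop("non-finite coordinates in complex")
  structure(list(protein = protein,
                 ligand = list(atoms = la, bonds = ligand$bonds %||% NULL)),
            class = "complex_frame")
}

#' Build a complex frame from a PDB file
#'
#' @param path PDB file containing both the protein and the ligand.
#' @param ligand_resname residue name identifying ligand atoms
#'   (default `"LIG"`).
#' @param ligand_bonds optional `structure_file` (e.g. from a mol2 file)
#'   supplying ligand bonds.
#' @return a `complex_frame`.
#' @export
read_complex <- function(path, ligand_resname = "LIG", ligand_bonds = NULL) {
  s <- read_structure(path, format = "pdb")
  a <- s$atoms
  is_lig <- a$resid == ligand_resname
  if (!any(is_lig)) stop("ligand absent: no residue named ", ligand_resname)
  protein <- data.frame(chain = a$chain[!is_lig], resname = a$resid[!is_lig],
                        resnum = a$resno[!is_lig], name = a$name[!is_lig],
                        element = a$element[!is_lig], x = a$x[!is_lig],
                        y = a$y[!is_lig], z = a$z[!is_lig],
                        stringsAsFactors = FALSE)
  lig <- list(atoms = data.frame(name = a$name[is_lig],
                                 element = a$element[is_lig],
                                 x = a$x[is_lig], y = a$y[is_lig],
                                 z = a$z[is_lig], stringsAsFactors = FALSE),
              bonds = ligand_bonds$bonds %||% NULL)
  complex_frame(protein, lig)
}

res_key <- function(chain, resname, resnum) paste0(chain, ":", resname, resnum)

lig_ring_atoms <- function(cx) {
  la <- cx$ligand$atoms
  heavy <- which(la$element != "H")
  if (is.null(cx$ligand$bonds) || length(heavy) < 3) return(character(0))
  g <- tryCatch(
    build_graph(list(atoms = la, bonds = cx$ligand$bonds)),
    error = function(e) NULL)
  if (is.null(g)) return(character(0))
  la$name[heavy][ring_atoms(g)]
}

#' Detect per-residue contacts and classify them
#'
#' A residue is in contact with the ligand when any heavy-atom pair is
#' within `cutoff`.  Contacts are sub-classified: polar (`P`, both atoms
#' N/O/S), hydrophobic (`H`, both atoms carbon), aromatic (`Ar`, both
#' atoms aromatic-ring members) and charged (`Ch`, a formally charged
#' residue group near a polar ligand atom).  Backbone/side-chain
#' assignment (`B`/`S`) follows the closest contacting residue atom.
#'
#' @param cx a `complex_frame`.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.0).
#' @param classes atom-class rules, see [ifp_atom_classes()].
#' @return data.frame of interaction records: `chain`, `resname`,
#'   `resnum`, `residue`, `category`, `backbone_or_sidechain`, `min_dist`.
#' @export
detect_contacts <- function(cx, cutoff = 4.0, classes = ifp_atom_classes()) {
  stopifnot(inherits(cx, "complex_frame"))
  prot <- cx$protein[cx$protein$element != "H", , drop = FALSE]
  lig <- cx$ligand$atoms[cx$ligand$atoms$element != "H", , drop = FALSE]
  if (nrow(lig) == 0) stop("ligand absent from complex")
  lring <- lig_ring_atoms(cx)
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  keys <- unique(res_key(prot$chain, prot$resname, prot$resnum))
  recs <- list()
  for (key in keys) {
    rows <- prot[res_key(prot$chain, prot$resname, prot$resnum) == key, ,
                 drop = FALSE]
    pxyz <- as.matrix(rows[, c("x", "y", "z")])
    dm <- sqrt(outer(rowSums(pxyz^2), rowSums(lxyz^2), "+") -
                 2 * pxyz %*% t(lxyz))
    if (min(dm) > cutoff + 1e-9) next
    within <- which(dm <= cutoff + 1e-9, arr.ind = TRUE)
    closest <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    resname <- rows$resname[1]
    add <- function(category, sel) {
      if (nrow(sel) == 0) return()
      dmin <- min(dm[sel])
      cl <- sel[which.min(dm[sel]), ]
      recs[[length(recs) + 1L]] <<- data.frame(
        chain = rows$chain[1], resname = resname, resnum = rows$resnum[1],
        residue = key, category = category,
        backbone_or_sidechain = if (rows$backbone[cl[1]]) "B" else "S",
        min_dist = dmin, stringsAsFactors = FALSE)
    }
    sel2 <- function(cond) within[cond, , drop = FALSE]
    add("C", within)
    pe <- classes$polar_elements
    add("P", sel2(rows$element[within[, 1]] %in% pe &
                    lig$element[within[, 2]] %in% pe))
    he <- classes$hydrophobic_elements
    add("H", sel2(rows$element[within[, 1]] %in% he &
                    lig$element[within[, 2]] %in% he))
    ar <- classes$aromatic_atoms[[resname]]
    if (!is.null(ar) && length(lring) > 0)
      add("Ar", sel2(rows$name[within[, 1]] %in% ar &
                       lig$name[within[, 2]] %in% lring))
    ch <- classes$charged_atoms[[resname]]
    if (!is.null(ch))
      add("Ch", sel2(rows$name[within[, 1]] %in% ch &
                       lig$element[within[, 2]] %in% pe))
  }
  if (length(recs) == 0)
    return(data.frame(chain = character(0), resname = character(0),
                      resnum = integer(0), residue = character(0),
                      category = character(0),
                      backbone_or_sidechain = character(0),
                      min_dist = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

# Donor hydrogens: explicit H within bonding distance of an N/O heavy
# atom.  Returns data.frame donor heavy-atom row index, H coordinates.
find_donor_hydrogens <- function(atoms, max_dh = 1.3) {
  heavy <- which(atoms$element %in% c("N", "O"))
  hs <- which(atoms$element == "H")
  out <- list()
  if (length(hs) == 0 || length(heavy) == 0) return(out)
  for (h in hs) {
    hx <- c(atoms$x[h], atoms$y[h], atoms$z[h])
    d <- sqrt((atoms$x[heavy] - hx[1])^2 + (atoms$y[heavy] - hx[2])^2 +
                (atoms$z[heavy] - hx[3])^2)
    if (min(d) <= max_dh) {
      don <- heavy[which.min(d)]
      out[[length(out) + 1L]] <- list(donor = don, h = hx)
    }
  }
  out
}

# Idealized donor-H placement for structures lacking explicit hydrogens:
# backbone/secondary amide N gets an in-plane H opposite the bisector of
# its two heavy neighbours (N-H 1.01 A); hydroxyl O gets a 0.96 A H at
# the tetrahedral angle, with the rotatable orientation scanned in 30-deg
# steps and the HB-best (closest approach to any opposing polar atom)
# kept.  Deterministic.  Only plausible donors receive a hydrogen: O atoms
# must be hydroxyl-like (single-bonded to one heavy atom, and for protein
# atoms named like a side-chain hydroxyl), never carbonyl/carboxylate.
place_donor_hydrogens <- function(atoms, opposing_polar_xyz, bonds = NULL,
                                  hydroxyl_names = c("OG", "OG1", "OH")) {
  res <- list()
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  heavy <- which(atoms$element != "H")
  has_h <- vapply(seq_len(nrow(atoms)), function(i) {
    if (!atoms$element[i] %in% c("N", "O")) return(TRUE)
    hs <- which(atoms$element == "H")
    length(hs) > 0 &&
      min(sqrt(rowSums(sweep(xyz[hs, , drop = FALSE], 2, xyz[i, ])^2))) <= 1.3
  }, logical(1))
  double_bonded <- rep(FALSE, nrow(atoms))
  if (!is.null(bonds) && nrow(bonds) > 0) {
    dbl <- bonds[bonds$order >= 2, , drop = FALSE]
    double_bonded[unique(c(dbl$i, dbl$j))] <- TRUE
  }
  for (i in which(!has_h)) {
    if (atoms$element[i] == "O") {
      if (double_bonded[i]) next                      # carbonyl-like
      if (is.null(bonds) && !(atoms$name[i] %in% hydroxyl_names)) next
    }
    cand <- setdiff(heavy, i)
    dcand <- sqrt(rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])^2))
    nb <- cand[dcand <= 1.8]
    if (length(nb) == 0) next
    unit <- function(v) v / sqrt(sum(v^2))
    if (atoms$element[i] == "N" && length(nb) >= 2) {
      bis <- unit(unit(xyz[nb[1], ] - xyz[i, ]) + unit(xyz[nb[2], ] - xyz[i, ]))
      res[[length(res) + 1L]] <- list(donor = i, h = xyz[i, ] - 1.01 * bis)
    } else if (atoms$element[i] == "O" && length(nb) == 1) {
      axis <- unit(xyz[i, ] - xyz[nb[1], ])
      ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- unit(ref - sum(ref * axis) * axis)
      v <- c(axis[2] * u[3] - axis[3] * u[2], axis[3] * u[1] - axis[1] * u[3],
             axis[1] * u[2] - axis[2] * u[1])
      best <- NULL; bestd <- Inf
      for (ang in seq(0, 330, by = 30) * pi / 180) {
        dirn <- cos(70.5 * pi / 180) * axis +
          sin(70.5 * pi / 180) * (cos(ang) * u + sin(ang) * v)
        hpos <- xyz[i, ] + 0.96 * dirn
        d <- if (nrow(opposing_polar_xyz) > 0)
          min(sqrt(rowSums(sweep(opposing_polar_xyz, 2, hpos)^2))) else 0
        if (d < bestd) { bestd <- d; best <- hpos }
      }
      res[[length(res) + 1L]] <- list(donor = i, h = best)
    }
  }
  res
}

hb_angle <- function(a, b, c) {
  # angle at b (degrees)
  u <- a - b; v <- c - b
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

#' Detect interface hydrogen bonds with geometric criteria
#'
#' A hydrogen bond is recorded when the hydrogen-acceptor distance is at
#' most `max_ha`, the donor angle (D-H...A, at the hydrogen) is at least
#' `min_donor_angle`, and the acceptor angle (H...A-antecedent, at the
#' acceptor) is at least `min_acceptor_angle`.  The residue role is `D`
#' when the residue provides the donor hydrogen and `A` when it provides
#' the acceptor.  Donors are N/O atoms with an attached hydrogen; explicit
#' hydrogens are used when present, otherwise idealized positions are
#' placed deterministically on donor N/O atoms.
#'
#' @param cx a `complex_frame`.
#' @param max_ha maximum H...acceptor distance in Angstrom (default 2.5).
#' @param min_donor_angle minimum D-H...A angle in degrees (default 120).
#' @param min_acceptor_angle minimum acceptor angle in degrees
#'   (default 90).
#' @param place_hydrogens add idealized donor hydrogens where explicit
#'   ones are missing (default `TRUE`).
#' @return data.frame of interaction records (same layout as
#'   [detect_contacts()], `min_dist` = H...A distance).
#' @export
detect_hbonds <- function(cx, max_ha = 2.5, min_donor_angle = 120,
                          min_acceptor_angle = 90, place_hydrogens = TRUE) {
  stopifnot(inherits(cx, "complex_frame"))
  prot <- cx$protein
  lig <- cx$ligand$atoms
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  polar <- c("N", "O")

  donors <- function(atoms, opposing, bonds = NULL) {
    dh <- find_donor_hydrogens(atoms)
    if (place_hydrogens) {
      placed <- place_donor_hydrogens(atoms, opposing, bonds = bonds)
      have <- vapply(dh, `[[`, 0L, "donor")
      for (p in placed) if (!(p$donor %in% have)) dh[[length(dh) + 1L]] <- p
    }
    dh
  }
  opp_prot <- lxyz[lig$element %in% polar, , drop = FALSE]
  opp_lig <- pxyz[prot$element %in% polar, , drop = FALSE]
  prot_donors <- donors(prot, opp_prot)
  lig_donors <- donors(lig, opp_lig, bonds = cx$ligand$bonds)

  acceptors <- function(atoms, xyz) {
    idx <- which(atoms$element %in% polar)
    lapply(idx, function(i) {
      heavy <- which(atoms$element != "H")
      heavy <- heavy[heavy != i]
      d <- sqrt(rowSums(sweep(xyz[heavy, , drop = FALSE], 2, xyz[i, ])^2))
      ante <- if (length(d) > 0 && min(d) <= 1.8) xyz[heavy[which.min(d)], ]
              else NULL
      list(acc = i, xyz = xyz[i, ], ante = ante)
    })
  }
  prot_acc <- acceptors(prot, pxyz)
  lig_acc <- acceptors(lig, lxyz)

  recs <- list()
  emit <- function(res_row, role, dist) {
    recs[[length(recs) + 1L]] <<- data.frame(
      chain = prot$chain[res_row], resname = prot$resname[res_row],
      resnum = prot$resnum[res_row],
      residue = res_key(prot$chain[res_row], prot$resname[res_row],
                        prot$resnum[res_row]),
      category = role,
      backbone_or_sidechain = if (prot$backbone[res_row]) "B" else "S",
      min_dist = dist, stringsAsFactors = FALSE)
  }
  eps <- 1e-6  # absorb acos/cos roundoff at exact criterion boundaries
  check <- function(dxyz, hxyz, axyz, ante) {
    dist <- sqrt(sum((hxyz - axyz)^2))
    if (dist > max_ha + eps) return(NA_real_)
    if (hb_angle(dxyz, hxyz, axyz) < min_donor_angle - eps) return(NA_real_)
    if (!is.null(ante) &&
        hb_angle(hxyz, axyz, ante) < min_acceptor_angle - eps)
      return(NA_real_)
    dist
  }
  for (d in prot_donors) {          # residue donates -> role D
    for (a in lig_acc) {
      dist <- check(pxyz[d$donor, ], d$h, a$xyz, a$ante)
      if (is.finite(dist)) emit(d$donor, "D", dist)
    }
  }
  for (d in lig_donors) {           # ligand donates, residue accepts -> A
    for (a in prot_acc) {
      dist <- check(lxyz[d$donor, ], d$h, a$xyz, a$ante)
      if (is.finite(dist)) emit(a$acc, "A", dist)
    }
  }
  if (length(recs) == 0)
    return(data.frame(chain = character(0), resname = character(0),
                      resnum = integer(0), residue = character(0),
                      category = character(0),
                      backbone_or_sidechain = character(0),
                      min_dist = numeric(0), stringsAsFactors = FALSE))
  unique(do.call(rbind, recs))
}

#' Interaction occurrence percentages across a set of complexes
#'
#' Counts, for every residue and interaction category, the fraction of
#' complexes in which the interaction occurs (a complex counts once per
#' residue-category however many atom pairs realize it), expressed in
#' percent.  Hydrogen-bond records imply a contact record for the same
#' residue in the aggregation.
#'
#' @param complexes list of `complex_frame` objects.
#' @param cutoff contact cutoff passed to [detect_contacts()].
#' @param ... further arguments passed to [detect_hbonds()].
#' @return an `occurrence_table`: numeric matrix residues x categories
#'   (`C`, `P`, `H`, `Ar`, `A`, `D`, `Ch`) of percentages, with attribute
#'   `n_complexes`.
#' @export
aggregate_ifp <- function(complexes, cutoff = 4.0, ...) {
  stopifnot(length(complexes) >= 1)
  cats <- c("C", "P", "H", "Ar", "A", "D", "Ch")
  tallies <- lapply(complexes, function(cx) {
    rc <- detect_contacts(cx, cutoff = cutoff)
    rh <- detect_hbonds(cx, ...)
    r <- rbind(rc, rh)
    if (nrow(rh) > 0) {  # an HB implies a contact for that residue
      extra <- rh[!(rh$residue %in% rc$residue), , drop = FALSE]
      if (nrow(extra) > 0) { extra$category <- "C"; r <- rbind(r, extra) }
    }
    unique(r[, c("residue", "category")])
  })
  residues <- unique(unlist(lapply(tallies, function(t) t$residue)))
  out <- matrix(0, length(residues), length(cats),
                dimnames = list(residues, cats))
  for (t in tallies)
    for (r in seq_len(nrow(t)))
      out[t$residue[r], t$category[r]] <- out[t$residue[r], t$category[r]] + 1
  out <- 100 * out / length(complexes)
  attr(out, "n_complexes") <- length(complexes)
  class(out) <- c("occurrence_table", class(out))
  out
}

#' Define a named distance between two atoms of a complex
#'
#' @param name distance label (e.g. `"D1"`, `"d2"`).
#' @param a,b atom selectors: either `list(chain=, resnum=, atom=)` for a
#'   protein atom or `list(ligand = TRUE, atom =)` for a ligand atom.
#' @return a `distance_spec` list.
#' @export
distance_spec <- function(name, a, b) {
  structure(list(name = name, a = a, b = b), class = "distance_spec")
}

resolve_selector <- function(cx, sel, spec_name) {
  if (isTRUE(sel$ligand)) {
    hit <- which(cx$ligand$atoms$name == sel$atom)
    xyz <- as.matrix(cx$ligand$atoms[, c("x", "y", "z")])
  } else {
    p <- cx$protein
    hit <- which(p$name == sel$atom &
                   (is.null(sel$resnum) | p$resnum == (sel$resnum %||% -1)) &
                   (is.null(sel$chain) | p$chain == (sel$chain %||% "")))
    xyz <- as.matrix(p[, c("x", "y", "z")])
  }
  if (length(hit) == 0)
    stop("distance spec '", spec_name, "': selector matches no atom")
  if (length(hit) > 1)
    stop("distance spec '", spec_name, "': selector is ambiguous (",
         length(hit), " atoms)")
  xyz[hit, ]
}

#' Measure named atom-atom distances in a complex
#'
#' @param cx a `complex_frame`.
#' @param specs list of [distance_spec()] objects.
#' @return named numeric vector of Euclidean distances in Angstrom,
#'   reported at 0.1 A precision.
#' @export
measure_distances <- function(cx, specs) {
  stopifnot(inherits(cx, "complex_frame"), length(specs) >= 1)
  out <- vapply(specs, function(sp) {
    a <- resolve_selector(cx, sp$a, sp$name)
    b <- resolve_selector(cx, sp$b, sp$name)
    round(sqrt(sum((a - b)^2)), 1)
  }, numeric(1))
  names(out) <- vapply(specs, `[[`, "", "name")
  out
}

#' Antagonist-compatibility distance rule
#'
#' Compares receptor-side hydrogen-bonding distances `D1..D3` with the
#' matching ligand-side distances `d1..d3`.  A pocket conformation is
#' compatible with antagonist binding when every supplied pair satisfies
#' `D_i > d_i`; the agonist-bound (open) conformation characteristically
#' fails the third pair.  Ligand-side `d2`/`d3` may be absent (series A
#' ligands define only `d1`).
#'
#' @param D named numeric vector, names like `"D1"`, `"D2"`, `"D3"`.
#' @param d named numeric vector, names like `"d1"`, `"d2"`, `"d3"`.
#' @return list with `pairs` (data.frame `pair`, `D`, `d`, `pass`) and
#'   `compatible` (`TRUE` iff all supplied pairs pass).
#' @export
antagonist_rule <- function(D, d) {
  di <- sub("^[Dd]", "", names(D))
  si <- sub("^[Dd]", "", names(d))
  shared <- intersect(di, si)
  if (length(shared) == 0) stop("no matching D/d distance pairs supplied")
  pairs <- data.frame(pair = paste0("D", shared, "/d", shared),
                      D = as.numeric(D[match(shared, di)]),
                      d = as.numeric(d[match(shared, si)]),
                      stringsAsFactors = FALSE)
  pairs$pass <- pairs$D > pairs$d
  list(pairs = pairs, compatible = all(pairs$pass))
}
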