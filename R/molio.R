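## molio: dataset fixture + structure-file input/output.

# md5 of the packaged activity table; guards against silent corruption.
.table1_md5 <- "e4984395b7bf9e73989603d9bc4b1b6a"

# Substituent name -> SMILES branch (attachment atom first).  Ring-bond
# digits 5/6 only, so branches can be spliced into scaffold templates that
# use digits 1/2.
.substituent_smiles <- c(
  "4-(CF3)-phenyl"            = "c5ccc(cc5)C(F)(F)F",
  "Phenyl"                    = "c5ccccc5",
  "6-(CF3)-pyridin-3-yl"      = "c5ccc(nc5)C(F)(F)F",
  "4-(OCF3)-phenyl"           = "c5ccc(OC(F)(F)F)cc5",
  "4-(tBu)-phenyl"            = "c5ccc(cc5)C(C)(C)C",
  "3-(CF3)-phenyl"            = "c5cccc(c5)C(F)(F)F",
  "4-(OMe)-phenyl"            = "c5ccc(OC)cc5",
  "4-(F)-phenyl"              = "c5ccc(F)cc5",
  "4-(OH)-phenyl"             = "c5ccc(O)cc5",
  "3-(CN)-phenyl"             = "c5cccc(c5)C#N",
  "4-Morpholinophenyl"        = "c5ccc(cc5)N5CCOCC5",
  "Thiophen-2-yl"             = "c5cccs5",
  "Thiophen-3-yl"             = "c5cscc5",
  "Furan-2-yl"                = "c5ccco5",
  "Furan-3-yl"                = "c5cocc5",
  "5-(Me)-furan-2-yl"         = "c5ccc(C)o5",
  "Pyridin-3-yl"              = "c5cccnc5",
  "Pyridin-4-yl"              = "c5ccncc5",
  "Pyrimidin-5-yl"            = "c5cncnc5",
  "Cyclohex-1-en-1-yl"        = "C5=CCCCC5",
  "3,6-Dihydro-2H-pyran-4-yl" = "C5=CCOCC5",
  "4-(NMe2)-phenyl"           = "c5ccc(N(C)C)cc5",
  "H"                         = "[H]",
  "Me"                        = "C",
  "nBu"                       = "CCCC",
  "4-(Morpholinomethyl)-phenyl" = "c5ccc(CN6CCOCC6)cc5",
  "2-(Piperidin-1-yl)-pyrimidin-5-yl" = "c5cnc(nc5)N5CCCCC5",
  "4-(OEt)-phenyl"            = "c5ccc(OCC)cc5",
  "2-(OEt)-phenyl"            = "c5ccccc5OCC",
  "3-(OEt)-phenyl"            = "c5cccc(OCC)c5",
  "6-(OEt)-pyridin-3-yl"      = "c5ccc(OCC)nc5",
  "4-(Cl)-phenyl"             = "c5ccc(Cl)cc5",
  "4-(Me)-phenyl"             = "c5ccc(C)cc5",
  "4-(Piperidin-1-yl)-phenyl" = "c5ccc(cc5)N5CCCCC5",
  "6-(NMe2)-pyridin-3-yl"     = "c5ccc(nc5)N(C)C",
  "6-(Pyrrolidin-1-yl)-pyridin-3-yl" = "c5ccc(nc5)N5CCCC5",
  "6-(Piperidin-1-yl)-pyridin-3-yl"  = "c5ccc(nc5)N5CCCCC5",
  "2-(NMe2)-pyrimidin-5-yl"   = "c5cnc(nc5)N(C)C",
  "4-(O-nPr)-phenyl"          = "c5ccc(OCCC)cc5",
  "4-(O-iPr)-phenyl"          = "c5ccc(OC(C)C)cc5",
  "4-(O-tBu)-phenyl"          = "c5ccc(OC(C)(C)C)cc5",
  "4-Cyclobutoxyphenyl"       = "c5ccc(OC6CCC6)cc5",
  "4-(Cyclopropylmethoxy)phenyl" = "c5ccc(OCC6CC6)cc5",
  "4-((Tetrahydro-2H-pyran-4-yl)oxy)-phenyl" = "c5ccc(OC6CCOCC6)cc5",
  "4-(Cyanomethoxy)-phenyl"   = "c5ccc(OCC#N)cc5",
  "4-(Oxetan-3-yloxy)-phenyl" = "c5ccc(OC6COC6)cc5",
  "2-(NMe2)-6-(CF3)-pyridin-3-yl" = "c5ccc(C(F)(F)F)nc5N(C)C",
  "2-(Piperidin-1-yl)-6-(CF3)-pyridin-3-yl" = "c5ccc(C(F)(F)F)nc5N5CCCCC5"
)

# Series C head groups, attached to the amide nitrogen via a benzo-ring
# carbon adjacent to the ring fusion.  R configuration on stereocentres.
.series_c_heads <- c(
  "1,2,3,4-Tetrahydroquinolin-3-ol"  = "c1cccc2NC[C@H](O)Cc12",
  "2-Oxo-1,2-dihydro-quinoline"      = "c1cccc2NC(=O)C=Cc12",
  "3,4-Dihydroquinolin-2(1H)-one"    = "c1cccc2NC(=O)CCc12",
  "Indolin-2-one"                    = "c1cccc2NC(=O)Cc12",
  "2H-benzo[b][1,4]oxazin-3(4H)-one" = "c1cccc2NC(=O)COc12"
)

#' Reconstruct a DPDA SMILES from series and substituent names
#'
#' The activity table prints substituent names, not structures; the SMILES
#' returned here are reconstructed from the series scaffolds (isoquinoline
#' head for series A, (R)-3-hydroxy-3,4-dihydroquinolin-2(1H)-one head for
#' series B, the named heterocycle for series C) and the tabulated
#' 5-position substituents.  They carry the topology needed by the 2D
#' descriptor engine but have not been verified against deposited
#' coordinates (none exist).
#'
#' @param series `"A"`, `"B"` or `"C"`.
#' @param r1,r2 substituent names exactly as printed in the activity table.
#'   For series C, `r1` names the head heterocycle and `r2` the para-alkoxy
#'   group (`"OEt"` or `"O-iPr"`) of the cis 5-phenyl.
#' @return a single SMILES string.
#' @examples
#' dpda_smiles("A", "4-(CF3)-phenyl", "Phenyl")
#' @export
dpda_smiles <- function(series, r1, r2) {
  stopifnot(length(series) == 1L, length(r1) == 1L, length(r2) == 1L)
  lookup <- function(name) {
    smi <- .substituent_smiles[name]
    if (is.na(smi)) stop("unknown substituent name: ", name)
    unname(smi)
  }
  if (series == "A") {
    head <- "c1cccc2cnccc12"
    cis <- lookup(r2); trans <- lookup(r1)
  } else if (series == "B") {
    head <- "c1cccc2NC(=O)[C@H](O)Cc12"
    cis <- lookup(r2); trans <- lookup(r1)
  } else if (series == "C") {
    head <- .series_c_heads[r1]
    if (is.na(head)) stop("unknown series C head group: ", r1)
    head <- unname(head)
    trans <- lookup("4-(CF3)-phenyl")
    cis <- switch(r2,
      "OEt"   = lookup("4-(OEt)-phenyl"),
      "O-iPr" = lookup("4-(O-iPr)-phenyl"),
      stop("unknown series C tail: ", r2))
  } else stop("series must be A, B or C, got: ", series)
  paste0("O=C(N", head, ")C=CC=C(", cis, ")", trans)
}

#' Load the packaged 64-compound DPDA activity table
#'
#' Returns the transcribed activity table: compound id, series, substituent
#' names, experimental and model-predicted log(1/IC50) (IC50 in nM against
#' human TRPV1), Glide XP docking score (kcal/mol) and test-set membership,
#' plus a reconstructed SMILES per compound (see [dpda_smiles()]).  The
#' fixture is integrity-checked against a recorded checksum.
#'
#' @param path optional override of the packaged CSV (mainly for testing).
#' @param check_integrity verify the file checksum (default `TRUE`; forced
#'   off when `path` is supplied).
#' @return a `data.frame` of 64 rows with class `"dpda_dataset"`; the
#'   attribute `smiles_source` is `"reconstructed"`.
#' @examples
#' d <- load_paper_dataset()
#' table(d$series)
#' sum(d$is_test)
#' @export
load_paper_dataset <- function(path = NULL, check_integrity = is.null(path)) {
  if (is.null(path))
    path <- system.file("extdata", "dpda_table1.csv", package = "dpdaqsar",
                        mustWork = TRUE)
  if (check_integrity) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .table1_md5))
      stop("integrity error: activity-table fixture checksum mismatch (",
           md5, " != ", .table1_md5, ")")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$is_test <- as.logical(d$is_test)
  if (nrow(d) != 64L) stop("integrity error: expected 64 compounds, got ", nrow(d))
  if (anyDuplicated(d$id)) stop("integrity error: duplicated compound ids")
  if (sum(d$is_test) != 12L)
    stop("integrity error: expected 12 test-set compounds, got ", sum(d$is_test))
  cnt <- table(d$series)
  if (!identical(as.integer(cnt[c("A", "B", "C")]), c(28L, 29L, 7L)))
    stop("integrity error: series counts are not A=28, B=29, C=7")
  d$smiles <- mapply(dpda_smiles, d$series, d$r1, d$r2, USE.NAMES = FALSE)
  attr(d, "smiles_source") <- "reconstructed"
  class(d) <- c("dpda_dataset", "data.frame")
  d
}

# Infer an element symbol from an atom name: leading alphabetic characters,
# recognising two-letter halogens; "CA"/"CB"/... resolve to carbon.
infer_element <- function(name) {
  vapply(name, function(nm) {
    alpha <- sub("^[^A-Za-z]*", "", nm)
    alpha <- sub("[^A-Za-z].*$", "", alpha)
    if (nchar(alpha) == 0L) stop("cannot infer element from atom name: ", nm)
    two <- paste0(toupper(substr(alpha, 1, 1)), tolower(substr(alpha, 2, 2)))
    if (two %in% c("Cl", "Br")) two else toupper(substr(alpha, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

new_structure_file <- function(format, atoms, bonds = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in structure")
  if (any(!nzchar(atoms$name))) stop("empty atom names in structure")
  structure(list(format = format, atoms = atoms, bonds = bonds),
            class = "structure_file")
}

#' Read a small-molecule or macromolecular structure file
#'
#' Thin, format-dispatching reader producing a uniform atom/bond container.
#' SMILES are converted through OpenBabel (via ChemmineR), SDF through
#' ChemmineR, mol2 and PDB through bio3d.  Elements missing from the format
#' (mol2 atom types, PDB names) are inferred from the leading alphabetic
#' characters of the atom name.
#'
#' @param path file path, or (for `format = "smiles"`) a SMILES string.
#' @param format one of `"smiles"`, `"sdf"`, `"mol2"`, `"pdb"`.
#' @return a `structure_file`: list with `format`, `atoms` (data.frame
#'   `name`, `element`, `x`, `y`, `z`, and for PDB `resid`, `resno`,
#'   `chain`) and `bonds` (data.frame `i`, `j`, `order`, or `NULL` for PDB).
#' @examples
#' s <- read_structure("CCO", format = "smiles")
#' nrow(s$atoms)  # 3 heavy atoms
#' @export
read_structure <- function(path, format = c("smiles", "sdf", "mol2", "pdb")) {
  format <- match.arg(format)
  switch(format,
    smiles = {
      smi <- if (file.exists(path)) readLines(path, warn = FALSE)[1] else path
      sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                      error = function(e) stop("parse error in SMILES '", smi,
                                               "': ", conditionMessage(e)))
      if (isTRUE(suppressWarnings(ChemmineR::validSDF(sdf))[1]))
        sdf_to_structure(sdf[[1]], format = "smiles")
      else {
        # ChemmineR cannot represent molecules with < 2 atoms or no bonds;
        # convert through OpenBabel and read the molblock directly
        txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\n"))
        molblock_to_structure(strsplit(txt, "\n")[[1]], format = "smiles")
      }
    },
    sdf = {
      sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                         error = function(e) stop("parse error in SDF ", path,
                                                  ": ", conditionMessage(e)))
      if (isTRUE(suppressWarnings(ChemmineR::validSDF(sdfset))[1]))
        sdf_to_structure(sdfset[[1]], format = "sdf")
      else
        molblock_to_structure(readLines(path, warn = FALSE), format = "sdf")
    },
    mol2 = {
      lines <- readLines(path, warn = FALSE)
      if (!any(grepl("^@<TRIPOS>ATOM", lines)))
        stop("parse error in mol2 ", path, ": missing @<TRIPOS>ATOM record ",
             "(searched lines 1-", length(lines), ")")
      m <- tryCatch(bio3d::read.mol2(path),
                    error = function(e) stop("parse error in mol2 ", path,
                                             ": ", conditionMessage(e)))
      a <- m$atom
      atoms <- data.frame(name = as.character(a$elena),
                          element = infer_element(as.character(a$elena)),
                          x = as.numeric(a$x), y = as.numeric(a$y),
                          z = as.numeric(a$z), stringsAsFactors = FALSE)
      bonds <- NULL
      if (!is.null(m$bond) && nrow(m$bond) > 0) {
        ord <- suppressWarnings(as.numeric(m$bond$type))
        ord[is.na(ord)] <- 1.5  # "ar"/"am" types
        bonds <- data.frame(i = as.integer(m$bond$origin),
                            j = as.integer(m$bond$target), order = ord)
      }
      new_structure_file("mol2", atoms, bonds)
    },
    pdb = {
      p <- tryCatch(bio3d::read.pdb(path),
                    error = function(e) stop("parse error in PDB ", path,
                                             ": ", conditionMessage(e)))
      a <- p$atom
      el <- a$elesy
      bad <- is.na(el) | !nzchar(trimws(el))
      el[bad] <- infer_element(a$elety[bad])
      el <- trimws(el)
      atoms <- data.frame(name = a$elety, element = el,
                          x = a$x, y = a$y, z = a$z,
                          resid = a$resid, resno = a$resno,
                          chain = ifelse(is.na(a$chain), "A", a$chain),
                          stringsAsFactors = FALSE)
      new_structure_file("pdb", atoms, bonds = NULL)
    })
}

#' Write a structure to SDF (V2000) or PDB
#'
#' @param x a `structure_file` (or anything with `$atoms`/`$bonds` in the
#'   same layout).
#' @param path output file path.
#' @param format `"sdf"` or `"pdb"`.
#' @param name molecule name for the SDF header / PDB residue name.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = c("sdf", "pdb"), name = "MOL") {
  format <- match.arg(format)
  atoms <- x$atoms
  if (format == "sdf") {
    n <- nrow(atoms)
    bonds <- x$bonds
    nb <- if (is.null(bonds)) 0L else nrow(bonds)
    ab <- cbind(as.matrix(atoms[, c("x", "y", "z")]), matrix(0, n, 13))
    colnames(ab) <- paste0("C", 1:16)
    rownames(ab) <- paste(atoms$element, seq_len(n), sep = "_")
    bb <- if (nb > 0) {
      m <- cbind(bonds$i, bonds$j, round(pmax(1, pmin(3, bonds$order))))
      colnames(m) <- c("C1", "C2", "C3"); rownames(m) <- seq_len(nb); m
    } else matrix(numeric(0), 0, 3, dimnames = list(NULL, c("C1", "C2", "C3")))
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
    sdf <- methods::new("SDF",
                        header = c(Molecule_Name = name, Source = "dpdaqsar",
                                   Comment = "", Counts_Line = counts),
                        atomblock = ab, bondblock = bb,
                        datablock = character(0))
    ChemmineR::write.SDF(sdf, path)
  } else {
    n <- nrow(atoms)
    bio3d::write.pdb(pdb = NULL, file = path,
                     xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                     resno = atoms$resno %||% rep(1L, n),
                     resid = atoms$resid %||% rep(name, n),
                     eleno = seq_len(n), elety = atoms$name,
                     chain = atoms$chain %||% rep("A", n))
  }
  invisible(path)
}

# Minimal V2000 molblock reader for the degenerate molecules (< 2 atoms
# or no bonds) that the SDF container class cannot represent.
molblock_to_structure <- function(lines, format) {
  if (length(lines) < 4) stop("parse error: molblock shorter than 4 lines")
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb))
    stop("parse error in molblock counts line (line 4): '", counts, "'")
  at <- lines[5:(4 + na)]
  atoms <- data.frame(
    name = paste0(trimws(substr(at, 32, 34)), seq_len(na)),
    element = trimws(substr(at, 32, 34)),
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    z = as.numeric(substr(at, 21, 30)), stringsAsFactors = FALSE)
  bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  if (nb > 0) {
    bt <- lines[(5 + na):(4 + na + nb)]
    bonds <- data.frame(i = as.integer(substr(bt, 1, 3)),
                        j = as.integer(substr(bt, 4, 6)),
                        order = as.numeric(substr(bt, 7, 9)))
  }
  new_structure_file(format, atoms, bonds)
}

# Convert a ChemmineR SDF object to a structure_file.
sdf_to_structure <- function(sdf, format) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(name = rownames(ab), element = el,
                      x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  # bond records are authoritative for SMILES/SDF; an empty table (not
  # NULL) marks a genuinely bondless molecule
  bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  if (!is.null(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.numeric(bb[, 3]))
    bonds <- bonds[bonds$i >= 1 & bonds$j >= 1, , drop = FALSE]
  }
  new_structure_file(format, atoms, bonds)
}

#' @export
print.structure_file <- function(x, ...) {
  cat("<structure_file> format:", x$format, "-", nrow(x$atoms), "atoms,",
      if (is.null(x$bonds)) "no bond records" else paste(nrow(x$bonds), "bonds"),
      "\n")
  invisible(x)
}

#' @export
print.dpda_dataset <- function(x, ...) {
  cat("DPDA activity dataset: 64 compounds (A=28, B=29, C=7), 12 test-set\n")
  cat("SMILES source:", attr(x, "smiles_source"), "\n")
  NextMethod()
}
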