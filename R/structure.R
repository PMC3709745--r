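# Atomistic structure container. Coordinates are stored in nm (GROMACS
# convention); PDB I/O converts from/to Angstrom at the file boundary.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- stats::setNames(names(AA3TO1), unname(AA3TO1))

#' Construct an atomistic structure object
#'
#' Low-level constructor assembling a `structure3d` object from a per-atom
#' table. Most users obtain structures from [read_pdb()] or the fixture
#' builders ([build_ideal_helix()], [build_extended_pentapeptide()]).
#'
#' @param atoms data.frame with columns `serial` (integer), `name` (atom
#'   name), `element` (element symbol), `resid` (3-letter residue code),
#'   `chain` (chain identifier), `resno` (author residue number), `ins`
#'   (insertion code, `""` if none) and coordinates `x`, `y`, `z` in nm.
#'   An optional `occ` column carries occupancies.
#' @param source_id free-text provenance label.
#'
#' @details Residues are identified by `(chain, resno, ins)`; the ordinal
#'   position of a residue within its chain (`res_ord`, 1-based, in order
#'   of appearance) is what all sequence-separation filters use, so author
#'   numbering gaps do not distort separations. Standard residues missing
#'   any of N, CA, C, O are flagged `complete = FALSE` with a warning.
#'
#' @return An object of class `structure3d`: a list with elements `atoms`
#'   (per-atom table augmented with `res_uid`, a global 1-based residue
#'   index), `residues` (one row per residue: `res_uid`, `chain`,
#'   `res_ord`, `resno`, `ins`, `resid`, `complete`) and `source_id`.
#' @export
structure3d <- function(atoms, source_id = "") {
  need <- c("serial", "name", "element", "resid", "chain", "resno", "ins",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty atom table")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (any(!nzchar(atoms$name))) stop("empty atom names")
  if (is.null(atoms$occ)) atoms$occ <- 1
  atoms$ins[is.na(atoms$ins)] <- ""

  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
  uid <- match(key, unique(key))
  atoms$res_uid <- uid

  first <- !duplicated(uid)
  residues <- data.frame(
    res_uid = uid[first],
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    ins = atoms$ins[first],
    resid = atoms$resid[first],
    stringsAsFactors = FALSE
  )
  residues <- residues[order(residues$res_uid), ]
  residues$res_ord <- stats::ave(residues$res_uid, residues$chain,
                                 FUN = seq_along)

  bb <- c("N", "CA", "C", "O")
  residues$complete <- vapply(residues$res_uid, function(u) {
    all(bb %in% atoms$name[uid == u])
  }, logical(1))
  n_inc <- sum(!residues$complete & residues$resid %in% names(AA3TO1))
  if (n_inc > 0) {
    warning(n_inc, " residue(s) missing backbone atoms (flagged incomplete)")
  }

  out <- list(atoms = atoms, residues = residues, source_id = source_id)
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  ch <- unique(x$residues$chain)
  cat("structure3d:", nrow(x$residues), "residues,",
      nrow(x$atoms), "atoms,", length(ch), "chain(s)",
      paste0("[", paste(ch, collapse = ","), "]"))
  if (nzchar(x$source_id)) cat(" -", x$source_id)
  cat("\n")
  invisible(x)
}

n_residues <- function(structure) nrow(structure$residues)

#' Coordinates of one named atom per residue
#'
#' @param structure a `structure3d` object.
#' @param name atom name to extract (e.g. `"CA"`).
#' @return matrix of nm coordinates, one row per residue that has the atom,
#'   with `res_uid` rownames.
#' @export
atom_coords <- function(structure, name = "CA") {
  sel <- structure$atoms$name == name
  a <- structure$atoms[sel, ]
  a <- a[!duplicated(a$res_uid), ]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$res_uid
  m
}

# coordinates of atom `name` in residue res_uid, or NULL
residue_atom <- function(structure, res_uid, name) {
  sel <- structure$atoms$res_uid == res_uid & structure$atoms$name == name
  if (!any(sel)) return(NULL)
  unlist(structure$atoms[which(sel)[1], c("x", "y", "z")], use.names = FALSE)
}

#' Apply a rigid-body transform to a structure
#'
#' Utility used mainly to verify that surface areas, hydrogen bonds and
#' networks are invariant under global rotation/translation.
#'
#' @param structure a `structure3d` object.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector, nm.
#' @return the transformed `structure3d`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

element_from_name <- function(name) {
  s <- sub("^[0-9]+", "", name)
  substr(s, 1, 1)
}
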