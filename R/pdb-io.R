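# PDB reading/writing. Parsing and formatting of the fixed-width records is
# delegated to bio3d; this layer handles model selection, altloc resolution,
# HETATM filtering, unit conversion (A <-> nm) and assembly into the
# package's structure3d container.

#' Read an atomistic structure from a PDB file
#'
#' @param path path to a PDB file containing ATOM records.
#' @param model model number to extract from multi-model files (default 1).
#'
#' @details Alternate locations are resolved to the highest-occupancy copy
#'   of each atom. HETATM records (ligands, waters) are dropped with a
#'   message giving the count; modified amino acids present as ATOM records
#'   are kept. Insertion codes are preserved in residue identity.
#'   Coordinates are converted from Angstrom to nm.
#'
#' @return a [structure3d] object.
#' @seealso [write_pdb()]
#' @export
read_pdb <- function(path, model = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("not a parseable PDB file (", path, "): ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no ATOM records in ", path)

  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  if (model > nmod) stop("model ", model, " requested but file has ", nmod)
  if (is.matrix(pdb$xyz) && nmod > 1) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]
    at$y <- xyz[, 2]
    at$z <- xyz[, 3]
  }

  n_het <- sum(at$type == "HETATM")
  if (n_het > 0) {
    message("dropping ", n_het, " HETATM atom(s)")
    at <- at[at$type == "ATOM", ]
  }
  if (nrow(at) == 0) stop("no ATOM records in ", path)

  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1

  # altloc: keep the highest-occupancy copy of each (residue, atom name)
  if (any(nzchar(at$alt))) {
    akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    ord <- order(akey, -at$o, at$alt)
    at <- at[ord, ]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "|")), ]
    at <- at[order(at$eleno), ]
  }

  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- element_from_name(at$elety[bad])

  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = trimws(elem),
    resid = at$resid,
    chain = at$chain,
    resno = at$resno,
    ins = at$insert,
    x = at$x / 10,
    y = at$y / 10,
    z = at$z / 10,
    occ = at$o,
    stringsAsFactors = FALSE
  )
  structure3d(atoms, source_id = basename(path))
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-format ATOM records (8.3 coordinates, Angstrom);
#' internal nm coordinates are converted on output.
#'
#' @param structure a [structure3d] object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  if (nrow(structure$atoms) == 0) stop("refusing to write empty structure")
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) * 10
  if (any(abs(xyz) > 9999)) {
    stop("coordinate magnitude exceeds 9999 A; not representable in PDB")
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(xyz)),
    resno = a$resno,
    resid = a$resid,
    eleno = a$serial,
    elety = a$name,
    chain = ifelse(a$chain == " ", "", a$chain),
    insert = ifelse(nzchar(a$ins), a$ins, NA),
    o = a$occ,
    elesy = a$element
  )
  invisible(path)
}
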