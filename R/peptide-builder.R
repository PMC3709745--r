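# Synthetic peptide builder: constructs all-atom models from internal
# coordinates (bond lengths/angles from standard peptide geometry, torsions
# supplied by the caller). Used for the ideal-helix and extended-
# pentapeptide fixtures; not a general modelling tool.

# backbone geometry (Angstrom / degrees, Engh-Huber-like values)
.BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.0,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

# Side-chain Z-matrix templates: each row places `name` bonded to `c` with
# the given bond (A), angle b-c-name (deg) and torsion a-b-c-name (deg).
# Chi angles are fixed in a canonical (mostly trans) rotamer; rings are
# placed planar. Accuracy targets fixture realism, not crystallographic
# refinement.
.SC_ROW <- function(name, a, b, c, bond, angle, dih) {
  list(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
       dih = dih)
}

.CB <- .SC_ROW("CB", "C", "N", "CA", 1.53, 110.5, -122.0)

.SC_TEMPLATES <- list(
  GLY = list(),
  ALA = list(.CB),
  SER = list(.CB, .SC_ROW("OG", "N", "CA", "CB", 1.41, 110.5, 180)),
  CYS = list(.CB, .SC_ROW("SG", "N", "CA", "CB", 1.81, 113.0, 180)),
  THR = list(.CB,
             .SC_ROW("OG1", "N", "CA", "CB", 1.41, 109.5, 180),
             .SC_ROW("CG2", "N", "CA", "CB", 1.52, 110.5, 60)),
  VAL = list(.CB,
             .SC_ROW("CG1", "N", "CA", "CB", 1.52, 110.5, 180),
             .SC_ROW("CG2", "N", "CA", "CB", 1.52, 110.5, 60)),
  LEU = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.52, 116.0, 180),
             .SC_ROW("CD1", "CA", "CB", "CG", 1.52, 110.5, 180),
             .SC_ROW("CD2", "CA", "CB", "CG", 1.52, 110.5, 60)),
  ILE = list(.CB,
             .SC_ROW("CG1", "N", "CA", "CB", 1.52, 110.5, 180),
             .SC_ROW("CG2", "N", "CA", "CB", 1.52, 110.5, -60),
             .SC_ROW("CD1", "CA", "CB", "CG1", 1.52, 113.0, 180)),
  MET = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.52, 114.0, 180),
             .SC_ROW("SD", "CA", "CB", "CG", 1.81, 112.7, 180),
             .SC_ROW("CE", "CB", "CG", "SD", 1.79, 100.9, 180)),
  PRO = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.50, 104.0, -25),
             .SC_ROW("CD", "CA", "CB", "CG", 1.51, 105.0, 35)),
  PHE = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.50, 114.0, 180),
             .SC_ROW("CD1", "CA", "CB", "CG", 1.39, 120.0, 90),
             .SC_ROW("CD2", "CA", "CB", "CG", 1.39, 120.0, -90),
             .SC_ROW("CE1", "CB", "CG", "CD1", 1.39, 120.0, 180),
             .SC_ROW("CE2", "CB", "CG", "CD2", 1.39, 120.0, 180),
             .SC_ROW("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0)),
  TYR = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.50, 114.0, 180),
             .SC_ROW("CD1", "CA", "CB", "CG", 1.39, 120.0, 90),
             .SC_ROW("CD2", "CA", "CB", "CG", 1.39, 120.0, -90),
             .SC_ROW("CE1", "CB", "CG", "CD1", 1.39, 120.0, 180),
             .SC_ROW("CE2", "CB", "CG", "CD2", 1.39, 120.0, 180),
             .SC_ROW("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0),
             .SC_ROW("OH", "CD1", "CE1", "CZ", 1.38, 120.0, 180)),
  TRP = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.50, 114.0, 180),
             .SC_ROW("CD1", "CA", "CB", "CG", 1.37, 127.0, 90),
             .SC_ROW("CD2", "CA", "CB", "CG", 1.43, 126.6, -90),
             .SC_ROW("NE1", "CB", "CG", "CD1", 1.38, 110.1, 180),
             .SC_ROW("CE2", "CB", "CG", "CD2", 1.41, 107.3, 180),
             .SC_ROW("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0),
             .SC_ROW("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 180),
             .SC_ROW("CZ3", "CG", "CD2", "CE3", 1.39, 118.7, 180),
             .SC_ROW("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0)),
  HIS = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.50, 114.0, 180),
             .SC_ROW("ND1", "CA", "CB", "CG", 1.38, 122.7, 90),
             .SC_ROW("CD2", "CA", "CB", "CG", 1.36, 131.0, -90),
             .SC_ROW("CE1", "CB", "CG", "ND1", 1.32, 109.0, 180),
             .SC_ROW("NE2", "CB", "CG", "CD2", 1.37, 107.0, 180)),
  ASP = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.52, 112.6, 180),
             .SC_ROW("OD1", "CA", "CB", "CG", 1.25, 118.4, 0),
             .SC_ROW("OD2", "CA", "CB", "CG", 1.25, 118.4, 180)),
  ASN = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.52, 112.6, 180),
             .SC_ROW("OD1", "CA", "CB", "CG", 1.23, 120.8, 0),
             .SC_ROW("ND2", "CA", "CB", "CG", 1.33, 116.4, 180)),
  GLU = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.52, 114.0, 180),
             .SC_ROW("CD", "CA", "CB", "CG", 1.52, 112.6, 180),
             .SC_ROW("OE1", "CB", "CG", "CD", 1.25, 118.4, 0),
             .SC_ROW("OE2", "CB", "CG", "CD", 1.25, 118.4, 180)),
  GLN = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.52, 114.0, 180),
             .SC_ROW("CD", "CA", "CB", "CG", 1.52, 112.6, 180),
             .SC_ROW("OE1", "CB", "CG", "CD", 1.23, 120.8, 0),
             .SC_ROW("NE2", "CB", "CG", "CD", 1.33, 116.4, 180)),
  LYS = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.52, 114.0, 180),
             .SC_ROW("CD", "CA", "CB", "CG", 1.52, 111.3, 180),
             .SC_ROW("CE", "CB", "CG", "CD", 1.52, 111.3, 180),
             .SC_ROW("NZ", "CG", "CD", "CE", 1.49, 111.9, 180)),
  ARG = list(.CB,
             .SC_ROW("CG", "N", "CA", "CB", 1.52, 114.0, 180),
             .SC_ROW("CD", "CA", "CB", "CG", 1.52, 111.3, 180),
             .SC_ROW("NE", "CB", "CG", "CD", 1.46, 112.0, 180),
             .SC_ROW("CZ", "CG", "CD", "NE", 1.33, 124.2, 180),
             .SC_ROW("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
             .SC_ROW("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180))
)

# amide H from the bisector rule: in the C(prev)-N-CA plane, opposite the
# bisector of the two bonds at N. Shared with place_amide_hydrogens().
amide_h_position <- function(c_prev, n, ca, bond = .BB$n_h) {
  u <- vunit(c_prev - n)
  v <- vunit(ca - n)
  n + bond * vunit(-(u + v))
}

#' Build an all-atom peptide from backbone torsions
#'
#' @param sequence character vector of 1-letter residue codes, or a single
#'   string (e.g. `"GARAG"`).
#' @param phi,psi backbone torsions in degrees; recycled to the sequence
#'   length.
#' @param omega peptide-bond torsion, degrees (default 180, trans).
#' @param chain chain identifier.
#'
#' @details Backbone atoms N, CA, C, O are built from standard bond
#'   geometry; the amide H is added for every residue after the first
#'   (prolines excepted) at 1.0 A from N in the C(i-1)-N-CA plane. Side
#'   chains are built in a fixed canonical rotamer from per-residue
#'   internal-coordinate templates.
#'
#' @return a [structure3d] object (coordinates in nm).
#' @export
build_peptide <- function(sequence, phi, psi, omega = 180, chain = "A") {
  seq1 <- if (length(sequence) == 1 && nchar(sequence[1]) > 1) {
    strsplit(sequence, "")[[1]]
  } else sequence
  n <- length(seq1)
  if (n < 1) stop("empty sequence")
  bad <- setdiff(unique(seq1), names(AA1TO3))
  if (length(bad) > 0) stop("unknown residue code(s): ",
                            paste(bad, collapse = ", "))
  res3 <- AA1TO3[seq1]
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  omega <- rep_len(omega, n)

  # per-residue named coordinate lists (Angstrom)
  coords <- vector("list", n)
  g <- .BB
  for (i in seq_len(n)) {
    res <- list()
    if (i == 1) {
      res$N <- c(0, 0, 0)
      res$CA <- c(g$n_ca, 0, 0)
      th <- (180 - g$ang_n_ca_c) * pi / 180
      res$C <- res$CA + g$ca_c * c(cos(th), sin(th), 0)
    } else {
      prev <- coords[[i - 1]]
      res$N <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n,
                          psi[i - 1])
      res$CA <- place_atom(prev$CA, prev$C, res$N, g$n_ca, g$ang_c_n_ca,
                           omega[i - 1])
      res$C <- place_atom(prev$C, res$N, res$CA, g$ca_c, g$ang_n_ca_c,
                          phi[i])
      if (res3[i] != "PRO") {
        res$H <- amide_h_position(prev$C, res$N, res$CA)
      }
    }
    # side chain before O (templates reference N, CA, C only)
    for (row in .SC_TEMPLATES[[res3[i]]]) {
      res[[row$name]] <- place_atom(res[[row$a]], res[[row$b]], res[[row$c]],
                                    row$bond, row$angle, row$dih)
    }
    res$O <- place_atom(res$N, res$CA, res$C, g$c_o, g$ang_ca_c_o,
                        psi[i] + 180)
    coords[[i]] <- res
  }

  rows <- list()
  serial <- 0L
  order_names <- function(res) {
    base <- c("N", "H", "CA", "C", "O")
    c(intersect(base, names(res)), setdiff(names(res), base))
  }
  for (i in seq_len(n)) {
    res <- coords[[i]]
    for (nm in order_names(res)) {
      serial <- serial + 1L
      p <- res[[nm]]
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, element = element_from_name(nm),
        resid = unname(res3[i]), chain = chain, resno = i, ins = "",
        x = p[1] / 10, y = p[2] / 10, z = p[3] / 10, occ = 1,
        stringsAsFactors = FALSE
      )
    }
  }
  structure3d(do.call(rbind, rows),
              source_id = paste0("built:", paste(seq1, collapse = "")))
}

#' Build an ideal alpha-helix fixture
#'
#' Backbone torsions phi = -57, psi = -47, omega = 180 degrees; successive
#' CA-CA distances come out at ~0.38 nm with a rise of ~0.15 nm per
#' residue along the helix axis.
#'
#' @param n_residues number of residues (>= 4).
#' @param sequence 1-letter code used for every residue (default `"A"`),
#'   or a full-length sequence string.
#' @return a [structure3d] object.
#' @export
build_ideal_helix <- function(n_residues, sequence = "A") {
  if (n_residues < 4) stop("a helix fixture needs at least 4 residues")
  seq1 <- if (nchar(sequence) == 1) strrep(sequence, n_residues) else sequence
  if (nchar(seq1) != n_residues) stop("sequence length != n_residues")
  build_peptide(seq1, phi = -57, psi = -47, omega = 180)
}

#' Build an extended G-X1-R-X2-G pentapeptide
#'
#' The reference construct used for solvent-accessibility normalization:
#' the measured residue sits at the center of a glycine-capped
#' pentapeptide in extended conformation.
#'
#' @param central 1-letter code of the central (measured) residue.
#' @param x1,x2 1-letter codes of the two variable neighbors.
#' @param phi,psi extended-form backbone torsions, degrees (defaults
#'   -139/+135, antiparallel-beta extended).
#' @return a [structure3d] object with 5 residues `G x1 central x2 G`.
#' @export
build_extended_pentapeptide <- function(central, x1 = "A", x2 = "A",
                                        phi = -139, psi = 135) {
  codes <- c("G", x1, central, x2, "G")
  bad <- setdiff(codes, names(AA1TO3))
  if (length(bad) > 0) stop("unknown residue code(s): ",
                            paste(bad, collapse = ", "))
  build_peptide(codes, phi = phi, psi = psi)
}

#' Enumerate the pentapeptide sequences for one central residue
#'
#' All G-X1-R-X2-G sequences with X1, X2 ranging over the 20 standard
#' amino acids: 400 sequences per central residue type.
#'
#' @param central 1-letter code of the central residue.
#' @return character vector of 400 5-letter sequences.
#' @export
pentapeptide_sequences <- function(central) {
  if (!central %in% names(AA1TO3)) stop("unknown residue code: ", central)
  aa <- names(AA1TO3)
  g <- expand.grid(x1 = aa, x2 = aa, stringsAsFactors = FALSE)
  paste0("G", g$x1, central, g$x2, "G")
}
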