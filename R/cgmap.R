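# Mapping of atomistic residues to MARTINI-style coarse-grained beads:
# one backbone (BB) bead per residue plus zero or more side-chain (SC)
# beads whose member atoms follow the MARTINI 2.1 amino-acid mapping.

# atom groups per SC bead, MARTINI 2.1 protein mapping (martinize layout)
.MARTINI_21 <- list(
  GLY = list(),
  ALA = list(),
  CYS = list(SC1 = c("CB", "SG")),
  VAL = list(SC1 = c("CB", "CG1", "CG2")),
  LEU = list(SC1 = c("CB", "CG", "CD1", "CD2")),
  ILE = list(SC1 = c("CB", "CG1", "CG2", "CD1")),
  MET = list(SC1 = c("CB", "CG", "SD", "CE")),
  PRO = list(SC1 = c("CB", "CG", "CD")),
  ASN = list(SC1 = c("CB", "CG", "OD1", "ND2")),
  GLN = list(SC1 = c("CB", "CG", "CD", "OE1", "NE2")),
  ASP = list(SC1 = c("CB", "CG", "OD1", "OD2")),
  GLU = list(SC1 = c("CB", "CG", "CD", "OE1", "OE2")),
  THR = list(SC1 = c("CB", "OG1", "CG2")),
  SER = list(SC1 = c("CB", "OG")),
  LYS = list(SC1 = c("CB", "CG", "CD"), SC2 = c("CE", "NZ")),
  ARG = list(SC1 = c("CB", "CG", "CD"), SC2 = c("NE", "CZ", "NH1", "NH2")),
  HIS = list(SC1 = c("CB", "CG"), SC2 = c("CD2", "NE2"),
             SC3 = c("ND1", "CE1")),
  PHE = list(SC1 = c("CB", "CG", "CD1"), SC2 = c("CD2", "CE2"),
             SC3 = c("CE1", "CZ")),
  TYR = list(SC1 = c("CB", "CG", "CD1"), SC2 = c("CD2", "CE2"),
             SC3 = c("CE1", "CZ", "OH")),
  TRP = list(SC1 = c("CB", "CG", "CD2"), SC2 = c("CD1", "NE1", "CE2"),
             SC3 = c("CE3", "CZ3"), SC4 = c("CZ2", "CH2"))
)

.ATOMIC_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  H = 1.008, P = 30.974)

#' The packaged MARTINI 2.1 amino-acid bead mapping
#'
#' @return named list (3-letter residue code -> named list of SC beads,
#'   each a character vector of member atom names); the backbone bead
#'   always maps N, CA, C, O. Attribute `version` tags the mapping.
#' @export
martini_mapping <- function() {
  m <- .MARTINI_21
  attr(m, "version") <- "martini-2.1"
  m
}

#' Map an atomistic structure to coarse-grained beads
#'
#' @param structure a [structure3d] object.
#' @param bb_mode `"com"` (backbone bead at the center of mass of
#'   N, CA, C, O; the default, used for SAHBNET construction) or `"ca"`
#'   (bead on the CA position, the ELNEDYN convention).
#'
#' @details Side-chain bead positions are mass-weighted centers of the
#'   mapped heavy-atom groups. A residue missing some atoms of a group
#'   still gets the bead from the available atoms, with a warning; a
#'   residue type absent from the mapping table is an error.
#'
#' @return object of class `cg_model`: list with `beads` (data.frame:
#'   `index`, `res_uid`, `chain`, `res_ord`, `resno`, `resid`, `kind`
#'   (BB/SC), `sc_rank` (0 for BB), `x`, `y`, `z` nm, `atoms`), `bb_mode`
#'   and `version`.
#' @export
map_structure <- function(structure, bb_mode = c("com", "ca")) {
  bb_mode <- match.arg(bb_mode)
  mapping <- martini_mapping()
  res <- structure$residues
  at <- structure$atoms
  rows <- list()
  idx <- 0L
  missing_atoms <- 0L

  com <- function(sub) {
    m <- .ATOMIC_MASS[sub$element]
    m[is.na(m)] <- 12
    c(sum(sub$x * m), sum(sub$y * m), sum(sub$z * m)) / sum(m)
  }

  for (k in seq_len(nrow(res))) {
    u <- res$res_uid[k]
    rtype <- res$resid[k]
    if (!rtype %in% names(mapping)) {
      stop("residue type ", rtype, " (", res$chain[k], ":", res$resno[k],
           ") absent from the MARTINI mapping table")
    }
    ra <- at[at$res_uid == u, ]
    bb_names <- if (bb_mode == "ca") "CA" else c("N", "CA", "C", "O")
    sub <- ra[ra$name %in% bb_names, ]
    if (nrow(sub) == 0) stop("residue ", res$chain[k], ":", res$resno[k],
                             " has no backbone atoms to map")
    idx <- idx + 1L
    p <- com(sub)
    rows[[idx]] <- data.frame(
      index = idx, res_uid = u, chain = res$chain[k],
      res_ord = res$res_ord[k], resno = res$resno[k], resid = rtype,
      kind = "BB", sc_rank = 0L, x = p[1], y = p[2], z = p[3],
      atoms = paste(sub$name, collapse = " "), stringsAsFactors = FALSE
    )
    sc <- mapping[[rtype]]
    for (r in seq_along(sc)) {
      sub <- ra[ra$name %in% sc[[r]], ]
      if (nrow(sub) == 0) {
        warning("residue ", res$chain[k], ":", res$resno[k], " has no atoms",
                " for bead ", names(sc)[r], "; bead skipped")
        next
      }
      if (nrow(sub) < length(sc[[r]])) missing_atoms <- missing_atoms + 1L
      idx <- idx + 1L
      p <- com(sub)
      rows[[idx]] <- data.frame(
        index = idx, res_uid = u, chain = res$chain[k],
        res_ord = res$res_ord[k], resno = res$resno[k], resid = rtype,
        kind = "SC", sc_rank = r, x = p[1], y = p[2], z = p[3],
        atoms = paste(sub$name, collapse = " "), stringsAsFactors = FALSE
      )
    }
  }
  if (missing_atoms > 0) {
    warning(missing_atoms, " side-chain bead(s) built from incomplete atom",
            " groups")
  }
  cg_model(do.call(rbind, rows), bb_mode = bb_mode,
           version = attr(mapping, "version"))
}

#' Low-level coarse-grained model constructor
#'
#' Assembles a `cg_model` from a bead table directly; used for toy bead
#' clouds in tests and examples. [map_structure()] is the standard route.
#'
#' @param beads data.frame with at least `res_uid`, `chain`, `res_ord`,
#'   `kind` (`"BB"`/`"SC"`), `sc_rank`, `x`, `y`, `z` (nm). `index` is
#'   (re)assigned from row order; missing `resno`/`resid`/`atoms` columns
#'   are filled with placeholders.
#' @param bb_mode,version metadata tags.
#' @return a `cg_model` object.
#' @export
cg_model <- function(beads, bb_mode = "com", version = "custom") {
  need <- c("res_uid", "chain", "res_ord", "kind", "sc_rank",
            "x", "y", "z")
  miss <- setdiff(need, names(beads))
  if (length(miss) > 0) stop("bead table lacks: ", paste(miss, collapse = ", "))
  if (!all(beads$kind %in% c("BB", "SC"))) stop("bead kind must be BB or SC")
  bb_per_res <- tapply(beads$kind == "BB", beads$res_uid, sum)
  if (any(bb_per_res != 1)) stop("every residue needs exactly one BB bead")
  beads$index <- seq_len(nrow(beads))
  if (is.null(beads$resno)) beads$resno <- beads$res_uid
  if (is.null(beads$resid)) beads$resid <- "UNK"
  if (is.null(beads$atoms)) beads$atoms <- ""
  out <- list(beads = beads, bb_mode = bb_mode, version = version)
  class(out) <- "cg_model"
  out
}

#' @export
print.cg_model <- function(x, ...) {
  cat("cg_model:", nrow(x$beads), "beads (",
      sum(x$beads$kind == "BB"), "BB /", sum(x$beads$kind == "SC"),
      "SC ), bb_mode =", x$bb_mode, ", mapping =", x$version, "\n")
  invisible(x)
}

#' Distance between two beads (nm)
#'
#' Euclidean distance between mapped bead positions in the reference
#' (input) structure.
#'
#' @param model a `cg_model`.
#' @param i,j bead indices.
#' @return distance in nm.
#' @export
bead_distance <- function(model, i, j) {
  b <- model$beads
  if (any(!c(i, j) %in% b$index)) stop("invalid bead index")
  pi_ <- unlist(b[b$index == i, c("x", "y", "z")])
  pj <- unlist(b[b$index == j, c("x", "y", "z")])
  vnorm(pi_ - pj)
}

#' Export a coarse-grained model as a PDB file
#'
#' One ATOM record per bead (bead kind/rank in the atom-name field), with
#' optional CONECT records tracing a network's springs, for visualizing
#' networks on the bead cloud.
#'
#' @param model a `cg_model`.
#' @param path output path.
#' @param network optional `elastic_network` whose springs become CONECT
#'   records.
#' @export
write_cg_pdb <- function(model, path, network = NULL) {
  b <- model$beads
  nm <- ifelse(b$kind == "BB", "BB", paste0("SC", b$sc_rank))
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(b[, c("x", "y", "z")]) * 10)),
    resno = b$resno,
    resid = ifelse(b$resid == "UNK", "BEA", b$resid),
    eleno = b$index,
    elety = nm,
    chain = ifelse(b$chain == " ", "", b$chain)
  )
  if (!is.null(network) && nrow(network$springs) > 0) {
    con <- sprintf("CONECT%5d%5d", network$springs$i, network$springs$j)
    txt <- readLines(path, warn = FALSE)
    end <- which(txt == "END")
    if (length(end) > 0) {
      txt <- append(txt, con, after = end[length(end)] - 1)
    } else {
      txt <- c(txt, con)
    }
    writeLines(txt, path)
  }
  invisible(path)
}
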