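# Backbone-backbone hydrogen-bond detection: amide-H reconstruction plus a
# DSSP-style electrostatic energy criterion (geometric criterion available
# as an option). Springs attach to backbone beads, so only main-chain
# N-H...O=C bonds are considered.

#' Place missing backbone amide hydrogens
#'
#' For each residue after the first in a chain that lacks an `H` atom, the
#' amide hydrogen is reconstructed 1.0 A from N, in the C(i-1)-N-CA plane,
#' opposite the bisector of the two bonds at N. Prolines get no amide H;
#' the first residue of a chain is never assigned one (no preceding
#' carbonyl). Residues that already carry an H are left untouched.
#'
#' @param structure a [structure3d] object.
#' @return the structure with hydrogens added.
#' @export
place_amide_hydrogens <- function(structure) {
  res <- structure$residues
  new_rows <- list()
  for (k in seq_len(nrow(res))) {
    u <- res$res_uid[k]
    if (res$resid[k] == "PRO") next
    if (res$res_ord[k] == 1) next
    if (!is.null(residue_atom(structure, u, "H"))) next
    prev <- res$res_uid[res$chain == res$chain[k] &
                          res$res_ord == res$res_ord[k] - 1]
    if (length(prev) != 1) next
    c_prev <- residue_atom(structure, prev, "C")
    n <- residue_atom(structure, u, "N")
    ca <- residue_atom(structure, u, "CA")
    if (is.null(c_prev) || is.null(n) || is.null(ca)) next
    h <- amide_h_position(c_prev, n, ca, bond = 0.10)  # nm
    tmpl <- structure$atoms[structure$atoms$res_uid == u, ][1, ]
    tmpl$name <- "H"
    tmpl$element <- "H"
    tmpl$x <- h[1]; tmpl$y <- h[2]; tmpl$z <- h[3]
    new_rows[[length(new_rows) + 1]] <- tmpl
  }
  if (length(new_rows) == 0) return(structure)
  atoms <- rbind(structure$atoms, do.call(rbind, new_rows))
  # keep residue-grouped order; renumber serials
  atoms <- atoms[order(atoms$res_uid), ]
  atoms$serial <- seq_len(nrow(atoms))
  structure3d(atoms[, setdiff(names(atoms), "res_uid")],
              source_id = structure$source_id)
}

#' DSSP-style electrostatic hydrogen-bond energy
#'
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol with
#' distances in Angstrom, between the donor's N-H and the acceptor's C=O.
#' A large positive sentinel is returned when any distance falls below
#' 0.5 A (clashing placement).
#'
#' @param structure a [structure3d] with hydrogens present.
#' @param donor,acceptor residue `res_uid`s; the donor must have N and H,
#'   the acceptor C and O.
#' @return energy in kcal/mol.
#' @export
kabsch_sander_energy <- function(structure, donor, acceptor) {
  n <- residue_atom(structure, donor, "N")
  h <- residue_atom(structure, donor, "H")
  c_ <- residue_atom(structure, acceptor, "C")
  o <- residue_atom(structure, acceptor, "O")
  if (is.null(n) || is.null(h)) stop("donor residue lacks N or H")
  if (is.null(c_) || is.null(o)) stop("acceptor residue lacks C or O")
  r <- c(on = vnorm(o - n), ch = vnorm(c_ - h),
         oh = vnorm(o - h), cn = vnorm(c_ - n)) * 10  # A
  if (any(r < 0.5)) return(1e6)
  0.084 * 332 * (1 / r["on"] + 1 / r["ch"] - 1 / r["oh"] - 1 / r["cn"])[[1]]
}

#' Detect backbone-backbone hydrogen bonds
#'
#' Scans all donor/acceptor residue pairs (excluding self and sequence
#' neighbors i, i+1, whose apparent bonds are artifacts of backbone
#' covalency). Under the default energy criterion a pair is bonded when
#' the [kabsch_sander_energy()] is below the threshold; under the
#' geometric criterion when r(N...O) <= 0.35 nm and the N-H...O angle is
#' >= 120 degrees. Each donor keeps at most its best acceptor (lowest
#' energy / shortest distance), preventing duplicate springs from
#' bifurcated bonds; the result is symmetrized into undirected pairs.
#'
#' @param structure a [structure3d]; hydrogens are placed automatically if
#'   absent.
#' @param criterion `"energy"` (default) or `"geometric"`.
#' @param threshold energy threshold in kcal/mol (default -0.5); for the
#'   geometric criterion, a list with `dist_nm` (default 0.35) and
#'   `angle_deg` (default 120).
#' @return data.frame of class `hbond_list`: columns `donor`, `acceptor`
#'   (res_uid), `energy` (kcal/mol), `dist_no` (nm), `angle` (deg). The
#'   undirected pair set is available via [hbond_pairs()].
#' @export
detect_backbone_hbonds <- function(structure,
                                   criterion = c("energy", "geometric"),
                                   threshold = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "energy") {
    e_cut <- if (is.null(threshold)) -0.5 else threshold
  } else {
    g <- if (is.null(threshold)) list() else threshold
    d_cut <- if (is.null(g$dist_nm)) 0.35 else g$dist_nm
    a_cut <- if (is.null(g$angle_deg)) 120 else g$angle_deg
  }
  structure <- place_amide_hydrogens(structure)
  res <- structure$residues

  get <- function(u, nm) residue_atom(structure, u, nm)
  donors <- res$res_uid[vapply(res$res_uid, function(u) {
    !is.null(get(u, "N")) && !is.null(get(u, "H"))
  }, logical(1))]
  acceptors <- res$res_uid[vapply(res$res_uid, function(u) {
    !is.null(get(u, "C")) && !is.null(get(u, "O"))
  }, logical(1))]

  rows <- list()
  for (d in donors) {
    kd <- match(d, res$res_uid)
    best <- NULL
    for (a in acceptors) {
      if (a == d) next
      ka <- match(a, res$res_uid)
      if (res$chain[kd] == res$chain[ka] &&
          abs(res$res_ord[kd] - res$res_ord[ka]) <= 1) next
      n <- get(d, "N"); h <- get(d, "H")
      o <- get(a, "O")
      r_no <- vnorm(o - n)
      if (r_no > 0.8) next  # beyond any H-bond reach; skip energy eval
      ang <- angle3(n, h, o)
      if (criterion == "energy") {
        e <- kabsch_sander_energy(structure, d, a)
        ok <- e < e_cut
        score <- e
      } else {
        e <- kabsch_sander_energy(structure, d, a)
        ok <- (r_no <= d_cut) && (ang >= a_cut)
        score <- r_no
      }
      if (ok && (is.null(best) || score < best$score)) {
        best <- list(donor = d, acceptor = a, energy = e, dist_no = r_no,
                     angle = ang, score = score)
      }
    }
    if (!is.null(best)) rows[[length(rows) + 1]] <- best
  }

  out <- if (length(rows) == 0) {
    data.frame(donor = integer(0), acceptor = integer(0),
               energy = numeric(0), dist_no = numeric(0),
               angle = numeric(0))
  } else {
    do.call(rbind, lapply(rows, function(b) {
      data.frame(donor = b$donor, acceptor = b$acceptor, energy = b$energy,
                 dist_no = b$dist_no, angle = b$angle)
    }))
  }
  class(out) <- c("hbond_list", "data.frame")
  out
}

#' Undirected residue pairs of a hydrogen-bond list
#'
#' @param hbonds an `hbond_list` from [detect_backbone_hbonds()], a
#'   `stride_record`, or any data.frame with `donor`/`acceptor` columns.
#' @return 2-column matrix of unique unordered `res_uid` pairs (min, max).
#' @export
hbond_pairs <- function(hbonds) {
  hb <- if (inherits(hbonds, "stride_record")) hbonds$hbonds else hbonds
  if (nrow(hb) == 0) return(matrix(integer(0), ncol = 2))
  p <- cbind(pmin(hb$donor, hb$acceptor), pmax(hb$donor, hb$acceptor))
  unique(p)
}

#' Export a hydrogen-bond list as delimited text
#'
#' @param hbonds an `hbond_list`.
#' @param structure the structure the list was computed on (for chain and
#'   residue numbers).
#' @param path output path.
#' @export
write_hbonds <- function(hbonds, structure, path) {
  res <- structure$residues
  kd <- match(hbonds$donor, res$res_uid)
  ka <- match(hbonds$acceptor, res$res_uid)
  d <- data.frame(chain_i = res$chain[kd], res_i = res$resno[kd],
                  chain_j = res$chain[ka], res_j = res$resno[ka],
                  energy = hbonds$energy)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
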