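# Solvent-accessible surface area: Shrake-Rupley test-point engine plus
# normalization to relative (%) accessibility against the packaged
# extended-pentapeptide reference means.

# Chothia-style heavy-atom van der Waals radii (Angstrom). Hydrogens are
# excluded from the area computation by default; a radius is provided for
# the include_hydrogens = TRUE pathway.
.RADII_SETS <- list(
  chothia = c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, H = 1.00, P = 1.90)
)

#' Reference accessible-surface values for the 20 standard residues
#'
#' Mean solvent-accessible surface area (A^2) of each residue type as the
#' central residue of extended G-X1-R-X2-G pentapeptides, used to convert
#' absolute residue SASA into relative accessibility (%). These constants
#' are packaged verbatim and never recomputed silently; see
#' [regenerate_reference_table()] for the diagnostic reproduction.
#'
#' @return named numeric vector, names = 1-letter residue codes.
#' @export
reference_sa <- function() {
  c(A = 103.8, R = 231.1, N = 157.6, D = 156.7, C = 130.8,
    E = 195.0, Q = 195.7, G = 80.8, H = 180.4, I = 168.5,
    L = 171.5, K = 206.4, M = 190.6, F = 198.2, P = 121.6,
    S = 123.5, T = 138.6, W = 229.6, Y = 219.7, V = 144.7)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  theta <- acos(1 - 2 * i / n)
  phi <- pi * (1 + sqrt(5)) * i
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: test points are distributed on each atom's
#' probe-expanded sphere and counted accessible when no neighboring
#' expanded sphere covers them. Areas are reported in A^2 (the field's
#' customary unit for SASA) although coordinates are held in nm.
#'
#' @param structure a [structure3d] object.
#' @param probe_radius solvent probe radius in nm (default 0.14, water).
#' @param n_points test points per atom (default 960; >= 60 required).
#' @param radii_set name of the atomic radii set (currently `"chothia"`).
#' @param include_hydrogens logical; hydrogens are excluded from the area
#'   computation by default (heavy-atom SASA).
#'
#' @return object of class `sasa_result`: list with `atom_area` (A^2 per
#'   atom, NA for excluded atoms), `residue_area` (named by `res_uid`),
#'   `residue_rel` (filled by [relative_sasa()]), and `params`.
#' @export
shrake_rupley <- function(structure, probe_radius = 0.14, n_points = 960,
                          radii_set = "chothia",
                          include_hydrogens = FALSE) {
  if (n_points < 60) stop("n_points must be >= 60")
  radii <- .RADII_SETS[[radii_set]]
  if (is.null(radii)) stop("unknown radii set: ", radii_set)

  at <- structure$atoms
  use <- if (include_hydrogens) rep(TRUE, nrow(at)) else at$element != "H"
  el <- at$element[use]
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown) > 0) {
    idx <- which(use)[el %in% unknown]
    stop("no radius for element(s) ", paste(unknown, collapse = ", "),
         " (atoms ", paste(at$serial[idx], collapse = ", "), ")")
  }

  xyz <- as.matrix(at[use, c("x", "y", "z")]) * 10  # A
  r_exp <- radii[el] + probe_radius * 10
  n_at <- nrow(xyz)
  pts <- sphere_points(n_points)

  # neighbor lists from the pairwise distance matrix (fixture-scale inputs)
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n_at)
  for (i in seq_len(n_at)) {
    nb <- which(d2[i, ] < (r_exp[i] + r_exp)^2 & seq_len(n_at) != i)
    # orient the point grid in a frame derived from the neighbor geometry:
    # the grid then co-rotates with the molecule, making computed areas
    # invariant under rigid-body motion (an isolated atom is spherically
    # symmetric, so the identity frame is exact there)
    Rf <- diag(3)
    if (length(nb) >= 1) {
      ord <- nb[order(d2[i, nb])]
      v1 <- vunit(xyz[ord[1], ] - xyz[i, ])
      v2 <- NULL
      for (j in ord[-1]) {
        w <- xyz[j, ] - xyz[i, ]
        w <- w - sum(w * v1) * v1
        if (vnorm(w) > 1e-6) {
          v2 <- vunit(w)
          break
        }
      }
      if (is.null(v2)) {
        # collinear neighbors: coverage is axially symmetric about v1,
        # so any perpendicular completes the frame without breaking
        # invariance
        a_ref <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        v2 <- vunit(a_ref - sum(a_ref * v1) * v1)
      }
      Rf <- cbind(v1, v2, vcross(v1, v2))
    }
    p <- sweep(pts %*% t(Rf) * r_exp[i], 2, xyz[i, ], "+")
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      covered <- rep(FALSE, n_points)
      for (j in nb) {
        dj <- sweep(p, 2, xyz[j, ], "-")
        covered <- covered | (rowSums(dj * dj) < r_exp[j]^2)
        if (all(covered)) break
      }
      acc <- sum(!covered)
    }
    area[i] <- 4 * pi * r_exp[i]^2 * acc / n_points
  }

  atom_area <- rep(NA_real_, nrow(at))
  atom_area[use] <- area
  residue_area <- vapply(structure$residues$res_uid, function(u) {
    sum(atom_area[at$res_uid == u], na.rm = TRUE)
  }, numeric(1))
  names(residue_area) <- structure$residues$res_uid

  out <- list(
    atom_area = atom_area,
    residue_area = residue_area,
    residue_rel = NULL,
    params = list(probe_radius = probe_radius, n_points = n_points,
                  radii_set = radii_set,
                  include_hydrogens = include_hydrogens),
    residues = structure$residues
  )
  class(out) <- "sasa_result"
  out
}

#' Normalize absolute residue SASA to relative accessibility (%)
#'
#' Relative SA = 100 x absolute SA / reference mean for the residue type.
#' Values above 100% are possible (e.g. chain termini) and are not
#' clamped. Residue types absent from the reference table get `NA` and
#' are excluded from surface-network eligibility (with a warning).
#'
#' @param sasa a `sasa_result` from [shrake_rupley()], or a `stride_record`
#'   from [parse_stride()] (its absolute SA values are normalized the same
#'   way; residue metadata must be attached via `residues`).
#' @param ref named numeric reference table (default [reference_sa()]).
#' @param residues residue table, required only when `sasa` is a
#'   `stride_record`.
#' @return for `sasa_result` input, the same object with `residue_rel`
#'   filled; for `stride_record` input, a named numeric of relative SA (%).
#' @export
relative_sasa <- function(sasa, ref = reference_sa(), residues = NULL) {
  if (inherits(sasa, "stride_record")) {
    if (is.null(residues)) stop("residue table required for stride input")
    abs_sa <- sasa$sa[as.character(residues$res_uid)]
    names(abs_sa) <- residues$res_uid
    res_tab <- residues
  } else {
    abs_sa <- sasa$residue_area
    res_tab <- sasa$residues
  }
  code1 <- AA3TO1[res_tab$resid]
  refv <- ref[code1]
  rel <- 100 * abs_sa / refv
  names(rel) <- res_tab$res_uid
  n_na <- sum(is.na(refv))
  if (n_na > 0) {
    warning(n_na, " residue(s) with no reference SA value; excluded from ",
            "surface-network eligibility")
  }
  if (inherits(sasa, "stride_record")) return(rel)
  sasa$residue_rel <- rel
  sasa
}

#' Regenerate the pentapeptide reference table (diagnostic)
#'
#' Rebuilds, for each requested central residue type, all 400 G-X1-R-X2-G
#' pentapeptides in extended form, computes the central residue's absolute
#' SASA with the local Shrake-Rupley engine and returns the mean. This is
#' a diagnostic companion to the packaged constants in [reference_sa()],
#' never a silent replacement: the packaged table came from a different
#' engine and the regenerated means differ within engine-level bands.
#'
#' @param central character vector of central residue 1-letter codes
#'   (default: all 20).
#' @param phi,psi extended-form torsions, degrees.
#' @param probe_radius,n_points,radii_set SASA engine parameters; the
#'   default point count is reduced relative to [shrake_rupley()] because
#'   8000 structures are averaged.
#' @param x_codes amino-acid codes X1/X2 range over (default all 20; a
#'   subset gives a faster, approximate diagnostic).
#' @return data.frame with `code`, `mean_sa` (A^2), `n_peptides`,
#'   `reference` (the packaged value, NA for non-standard input).
#' @export
regenerate_reference_table <- function(central = names(AA1TO3),
                                       phi = -139, psi = 135,
                                       probe_radius = 0.14, n_points = 240,
                                       radii_set = "chothia",
                                       x_codes = names(AA1TO3)) {
  ref <- reference_sa()
  out <- lapply(central, function(cc) {
    grid <- expand.grid(x1 = x_codes, x2 = x_codes,
                        stringsAsFactors = FALSE)
    vals <- vapply(seq_len(nrow(grid)), function(i) {
      s <- build_extended_pentapeptide(cc, grid$x1[i], grid$x2[i],
                                       phi = phi, psi = psi)
      sr <- shrake_rupley(s, probe_radius = probe_radius,
                          n_points = n_points, radii_set = radii_set)
      unname(sr$residue_area["3"])  # central residue of the 5-mer
    }, numeric(1))
    data.frame(code = cc, mean_sa = mean(vals), n_peptides = nrow(grid),
               reference = unname(ref[cc]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write/read a reference SA table as 2-column delimited text
#'
#' @param ref named numeric vector (code -> A^2).
#' @param path file path.
#' @return `read_reference_sa` returns the named numeric vector.
#' @export
write_reference_sa <- function(ref, path) {
  utils::write.table(data.frame(code = names(ref), area = unname(ref)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_sa
#' @export
read_reference_sa <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(d$area, d$code)
}
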