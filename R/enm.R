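# Desk-scale flexibility analysis: anisotropic-network Hessian over a
# spring network, normal modes, predicted per-bead RMSF, Kabsch-super-
# posed RMSD series and signed delta profiles. Normal-mode RMSF is a
# harmonic proxy for the fluctuations a simulation would produce; it is
# labeled as such in outputs.

KB_KJ <- 0.0083144626  # kJ mol^-1 K^-1

#' Build the anisotropic-network Hessian of a spring network
#'
#' Standard ANM construction: each spring (i, j, k) contributes a 3x3
#' super-element -k * rhat rhat^T on the (i, j) off-diagonal blocks, with
#' diagonal blocks set to minus the sum of the off-diagonals (so rigid
#' translations are exact zero modes). Backbone chain springs between
#' consecutive backbone beads of each chain are added automatically so
#' that networks whose rules leave the chain unconnected still yield a
#' connected Hessian (they stand in for the bonded terms of the parent
#' forcefield).
#'
#' @param model a `cg_model`.
#' @param net an `elastic_network` indexing into `model`'s beads.
#' @param backbone_chain_k force constant of the implicit i,i+1 backbone
#'   chain springs, kJ mol^-1 nm^-2 (default 1250); 0 disables all
#'   stand-in springs. Weaker i,i+2 and i,i+3 springs (k/5 and k/25)
#'   stand in for backbone angle and dihedral stiffness, and every
#'   side-chain bead is anchored to its residue's backbone bead, the
#'   preceding side-chain bead and the flanking backbone beads, so that
#'   pendant beads do not produce spurious floppy modes. Stand-in springs
#'   enter the flexibility proxy only; they are never part of the
#'   exported network.
#' @return a 3N x 3N symmetric matrix (N = bead count), with attributes
#'   `floppy` (indices of beads with no springs at all) and `n_beads`.
#' @export
build_hessian <- function(model, net, backbone_chain_k = 1250) {
  b <- model$beads
  n <- nrow(b)
  xyz <- as.matrix(b[, c("x", "y", "z")])
  sp <- net$springs[, c("i", "j", "k")]
  if (backbone_chain_k > 0) {
    bb <- b[b$kind == "BB", ]
    for (ch in unique(bb$chain)) {
      bc <- bb[bb$chain == ch, ]
      bc <- bc[order(bc$res_ord), ]
      m <- nrow(bc)
      for (off in 1:3) {
        if (m > off) {
          sp <- rbind(sp, data.frame(
            i = bc$index[seq_len(m - off)],
            j = bc$index[seq_len(m - off) + off],
            k = backbone_chain_k / 5^(off - 1)))
        }
      }
    }
    # anchor SC beads (MARTINI BB-SC bonded terms stand-in)
    sc <- b[b$kind == "SC", ]
    for (s in seq_len(nrow(sc))) {
      bb_res <- b$index[b$kind == "BB" & b$res_uid == sc$res_uid[s]]
      anchors <- bb_res
      if (sc$sc_rank[s] > 1) {
        anchors <- c(anchors, b$index[b$res_uid == sc$res_uid[s] &
                                        b$kind == "SC" &
                                        b$sc_rank == sc$sc_rank[s] - 1])
      }
      nb <- b[b$kind == "BB" & b$chain == sc$chain[s] &
                b$res_uid != sc$res_uid[s], ]
      nb <- nb[order(abs(nb$res_ord - sc$res_ord[s])), ]
      flank <- utils::head(nb$index, 2)
      anchors <- unique(c(anchors, flank))
      sp <- rbind(sp, data.frame(i = anchors, j = sc$index[s],
                                 k = backbone_chain_k))
    }
  }
  if (nrow(sp) == 0) stop("no springs to build a Hessian from")

  H <- matrix(0, 3 * n, 3 * n)
  for (s in seq_len(nrow(sp))) {
    i <- sp$i[s]; j <- sp$j[s]
    r <- xyz[j, ] - xyz[i, ]
    rh <- r / vnorm(r)
    blk <- sp$k[s] * (rh %o% rh)
    ii <- (3 * i - 2):(3 * i)
    jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  deg <- integer(n)
  t1 <- table(factor(sp$i, levels = seq_len(n)))
  t2 <- table(factor(sp$j, levels = seq_len(n)))
  deg <- as.integer(t1 + t2)
  attr(H, "floppy") <- which(deg == 0)
  attr(H, "n_beads") <- n
  H
}

# connected components of the spring graph implied by nonzero H blocks
hessian_components <- function(H) {
  n <- attr(H, "n_beads")
  comp <- rep(0L, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      vv <- (3 * v - 2):(3 * v)
      for (w in seq_len(n)) {
        if (comp[w] == 0L) {
          ww <- (3 * w - 2):(3 * w)
          if (any(H[vv, ww] != 0)) {
            comp[w] <- cur
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  comp
}

#' Per-bead RMSF from normal modes of a network Hessian
#'
#' Eigen-decomposes the Hessian, discards the six rigid-body modes
#' (eigenvalues below `tol` times the largest) and accumulates the
#' thermal mean-square fluctuation of each bead as kB*T * sum over modes
#' of |eigenvector components|^2 / eigenvalue. Backbone-bead values are
#' reported per residue.
#'
#' @param hessian matrix from [build_hessian()].
#' @param model the `cg_model` the Hessian was built on.
#' @param temperature Kelvin (default 300).
#' @param tol near-zero mode threshold relative to the largest eigenvalue
#'   (default 1e-8).
#' @return a `flex_profile`: data.frame with `res_uid`, `chain`,
#'   `res_ord`, `value` (RMSF, nm) for the backbone beads, with
#'   attributes `label`, `source = "enm"`, `n_zero_modes`, and `rmsf_all`
#'   (per-bead values).
#' @export
rmsf_from_modes <- function(hessian, model, temperature = 300,
                            tol = 1e-8) {
  eig <- eigen(hessian, symmetric = TRUE)
  lam <- eig$values
  thresh <- tol * max(lam)
  zero <- lam < thresh
  n_zero <- sum(zero)
  if (n_zero > 6) {
    comp <- hessian_components(hessian)
    if (max(comp) > 1) {
      stop("disconnected network: ", max(comp), " components (beads ",
           paste(tapply(seq_along(comp), comp, function(i) {
             paste(i, collapse = ",")
           }), collapse = "; "), ")")
    }
    stop("under-constrained network: ", n_zero, " near-zero modes ",
         "(expected 6 rigid-body modes); add springs or keep the ",
         "backbone chain stand-ins enabled")
  }
  keep <- which(!zero)
  n <- attr(hessian, "n_beads")
  msf <- numeric(n)
  for (m in keep) {
    v2 <- matrix(eig$vectors[, m]^2, nrow = 3)
    msf <- msf + colSums(v2) / lam[m]
  }
  msf <- KB_KJ * temperature * msf
  rmsf <- sqrt(msf)

  b <- model$beads
  bb <- b[b$kind == "BB", ]
  out <- data.frame(res_uid = bb$res_uid, chain = bb$chain,
                    res_ord = bb$res_ord, value = rmsf[bb$index])
  flex_profile(out, label = paste0("ENM RMSF proxy, T=", temperature, "K"),
               source = "enm", n_zero_modes = n_zero, rmsf_all = rmsf)
}

#' Flexibility profile container
#'
#' @param df data.frame with at least `res_uid` and `value` (>= 0).
#' @param label free-text label.
#' @param source `"enm"` or `"external"`.
#' @param ... further attributes to attach.
#' @return the data.frame with class `flex_profile`.
#' @export
flex_profile <- function(df, label = "", source = "external", ...) {
  if (any(df$value < 0)) stop("flexibility values must be non-negative")
  attr(df, "label") <- label
  attr(df, "source") <- source
  extra <- list(...)
  for (nm in names(extra)) attr(df, nm) <- extra[[nm]]
  class(df) <- c("flex_profile", "data.frame")
  df
}

# Kabsch optimal superposition: rotate/translate `mobile` onto `ref`
kabsch_superpose <- function(ref, mobile) {
  cr <- colMeans(ref)
  cm <- colMeans(mobile)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(ref, 2, cr)
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  sweep(P %*% t(R), 2, cr, "+")
}

#' Per-frame RMSD of an ensemble against a reference
#'
#' Each frame is optimally superposed (Kabsch) onto the reference before
#' the root-mean-square deviation is computed.
#'
#' @param reference n x 3 coordinate matrix (nm).
#' @param ensemble list of n x 3 matrices, or a single matrix (one frame).
#' @return numeric vector of RMSD values (nm), one per frame.
#' @export
rmsd_series <- function(reference, ensemble) {
  if (is.matrix(ensemble)) ensemble <- list(ensemble)
  vapply(ensemble, function(fr) {
    if (!all(dim(fr) == dim(reference))) {
      stop("frame/reference atom count mismatch")
    }
    fit <- kabsch_superpose(reference, fr)
    sqrt(mean(rowSums((fit - reference)^2)))
  }, numeric(1))
}

#' Signed difference of two flexibility profiles
#'
#' Element-wise `a - b`; positive values mean `a` is more flexible.
#'
#' @param a,b `flex_profile`s (or data.frames with `value`) of equal
#'   length.
#' @return a `flex_profile` of differences with attributes `mean_delta`
#'   and `max_abs_delta`.
#' @export
delta_profile <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("profiles have different lengths")
  d <- a
  d$value <- a$value - b$value
  attr(d, "label") <- "delta"
  attr(d, "source") <- "delta"
  attr(d, "mean_delta") <- mean(d$value)
  attr(d, "max_abs_delta") <- max(abs(d$value))
  class(d) <- c("flex_profile", "data.frame")
  d
}

#' Write/read a flexibility profile as 2-column delimited text
#'
#' @param profile a `flex_profile`.
#' @param path file path.
#' @return `read_profile` returns a `flex_profile` (`source =
#'   "external"`).
#' @export
write_profile <- function(profile, path) {
  ord <- if (!is.null(profile$res_ord)) profile$res_ord else {
    seq_len(nrow(profile))
  }
  utils::write.table(data.frame(residue = ord, value = profile$value),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  flex_profile(data.frame(res_uid = d$residue, res_ord = d$residue,
                          value = d$value),
               label = basename(path), source = "external")
}
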