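# Shared fixtures and literal-rule oracles. Fixtures are built in code;
# the heavier ones are memoized per test run.

helix10 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_ideal_helix(10)
    cache
  }
})

# helix(10) - loop(4) - helix(10), poly-leucine: the two helices pack,
# several core residues drop below 30% relative accessibility, and the
# loop carries no hydrogen bonds.
helix_loop_helix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      phi <- c(rep(-57, 10), -139, -90, 80, -139, rep(-57, 10))
      psi <- c(rep(-47, 10), 135, 0, 20, 135, rep(-47, 10))
      cache <<- build_peptide(strrep("L", 24), phi, psi)
    }
    cache
  }
})

# random toy CG model: n residues on a loose 3D random walk, one BB bead
# each plus an SC bead for a random subset; single or double chain
random_toy_model <- function(n_res, two_chains = FALSE, sc_frac = 0.5) {
  step <- function() stats::rnorm(3, sd = 0.25)
  pos <- matrix(0, n_res, 3)
  for (i in 2:n_res) pos[i, ] <- pos[i - 1, ] + step()
  chain <- if (two_chains) {
    rep(c("A", "B"), c(ceiling(n_res / 2), floor(n_res / 2)))
  } else rep("A", n_res)
  res_ord <- unlist(lapply(unique(chain), function(ch) {
    seq_len(sum(chain == ch))
  }))
  beads <- data.frame(res_uid = seq_len(n_res), chain = chain,
                      res_ord = res_ord, kind = "BB", sc_rank = 0L,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3])
  has_sc <- stats::runif(n_res) < sc_frac
  if (any(has_sc)) {
    sc <- beads[has_sc, ]
    sc$kind <- "SC"
    sc$sc_rank <- 1L
    sc[, c("x", "y", "z")] <- sc[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(sc), sd = 0.2), ncol = 3)
    beads <- rbind(beads, sc)
  }
  ord <- order(beads$res_uid, beads$kind != "BB", beads$sc_rank)
  cg_model(beads[ord, ])
}

# literal O(n^2) transcription of the surface-spring rule
oracle_sa_pairs <- function(model, rel, params) {
  b <- model$beads
  cand <- b[b$kind == params$mode, ]
  pairs <- matrix(integer(0), ncol = 2)
  for (s in seq_len(nrow(cand))) {
    rs <- rel[as.character(cand$res_uid[s])]
    if (is.na(rs) || rs >= params$sa_c) next
    for (t in seq_len(nrow(cand))) {
      if (t == s) next
      d <- sqrt(sum((cand[s, c("x", "y", "z")] -
                       cand[t, c("x", "y", "z")])^2))
      sep_ok <- cand$chain[s] != cand$chain[t] ||
        abs(cand$res_ord[s] - cand$res_ord[t]) >= params$min_sep_sa
      if (d < params$r_c && sep_ok) {
        pairs <- rbind(pairs, c(min(cand$index[s], cand$index[t]),
                                max(cand$index[s], cand$index[t])))
      }
    }
  }
  unique(pairs)
}

# literal O(n^2) transcription of the ELNEDYN rule
oracle_eln_pairs <- function(model, r_c, min_sep) {
  b <- model$beads
  bb <- b[b$kind == "BB", ]
  pairs <- matrix(integer(0), ncol = 2)
  n <- nrow(bb)
  if (n < 2) return(pairs)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      d <- sqrt(sum((bb[s, c("x", "y", "z")] -
                       bb[t, c("x", "y", "z")])^2))
      sep_ok <- bb$chain[s] != bb$chain[t] ||
        abs(bb$res_ord[s] - bb$res_ord[t]) >= min_sep
      if (d < r_c && sep_ok) {
        pairs <- rbind(pairs, c(bb$index[s], bb$index[t]))
      }
    }
  }
  pairs
}

spring_pairs <- function(springs) {
  if (nrow(springs) == 0) return(matrix(integer(0), ncol = 2))
  m <- unique(cbind(springs$i, springs$j))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

sort_pairs <- function(p) {
  if (nrow(p) == 0) return(matrix(integer(0), ncol = 2))
  p[order(p[, 1], p[, 2]), , drop = FALSE]
}

# independent finite-difference Hessian of the spring energy, used to
# cross-check the analytic ANM construction
spring_energy <- function(xyz, springs) {
  e <- 0
  for (r in seq_len(nrow(springs))) {
    d <- sqrt(sum((xyz[springs$i[r], ] - xyz[springs$j[r], ])^2))
    e <- e + 0.5 * springs$k[r] * (d - springs$b0[r])^2
  }
  e
}

fd_hessian <- function(xyz, springs, h = 1e-5) {
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  grad <- function(x) {
    g <- numeric(3 * n)
    for (p in seq_len(3 * n)) {
      xp <- x; xp[p] <- xp[p] + h
      xm <- x; xm[p] <- xm[p] - h
      mp <- matrix(xp, n, 3, byrow = TRUE)
      mm <- matrix(xm, n, 3, byrow = TRUE)
      g[p] <- (spring_energy(mp, springs) - spring_energy(mm, springs)) /
        (2 * h)
    }
    g
  }
  x0 <- as.vector(t(xyz))
  for (p in seq_len(3 * n)) {
    xp <- x0; xp[p] <- xp[p] + h
    xm <- x0; xm[p] <- xm[p] - h
    H[, p] <- (grad(xp) - grad(xm)) / (2 * h)
  }
  (H + t(H)) / 2
}

# minimal Stride-like report for a structure: given SA values (by residue
# ordinal) and donor->acceptor resno pairs
write_stride_fixture <- function(path, structure, sa, hb_pairs = NULL) {
  res <- structure$residues
  lines <- c("REM  --------------------", "REM  Generated fixture")
  for (k in seq_len(nrow(res))) {
    lines <- c(lines, sprintf(
      "ASG  %3s %s %4d %4d    C          Coil    -139.00    135.00   %7.1f      ~~~~",
      res$resid[k], res$chain[k], res$resno[k], k, sa[k]))
  }
  if (!is.null(hb_pairs)) {
    for (r in seq_len(nrow(hb_pairs))) {
      kd <- hb_pairs[r, 1]
      ka <- hb_pairs[r, 2]
      lines <- c(lines, sprintf(
        "DNR  %3s %s %4d %4d  ->  %3s %s %4d %4d   3.0   113.4    21.2   ~~~~",
        res$resid[kd], res$chain[kd], res$resno[kd], kd,
        res$resid[ka], res$chain[ka], res$resno[ka], ka))
    }
  }
  writeLines(lines, path)
  path
}
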