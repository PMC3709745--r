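# Network Hessian, normal-mode RMSF proxy, RMSD and delta profiles

toy_net <- function(beads, springs) {
  elastic_network(springs, model = cg_model(beads))
}

dimer <- function(sep = 0.4) {
  cg_model(data.frame(res_uid = 1:2, chain = "A", res_ord = 1:2,
                      kind = "BB", sc_rank = 0L, x = c(0, sep), y = 0, z = 0))
}

test_that("a two-bead spring gives a rank-1 Hessian with zero block row sums", {
  m <- dimer()
  net <- elastic_network(data.frame(i = 1L, j = 2L, b0 = 0.4, k = 100,
                                    origin = "sa"), model = m)
  H <- build_hessian(m, net, backbone_chain_k = 0)
  expect_equal(H, t(H))
  expect_equal(sum(eigen(H, symmetric = TRUE)$values > 1e-10), 1)
  # translational invariance: each 3-row block sums to zero over beads
  for (b in 1:2) {
    rows <- (3 * b - 2):(3 * b)
    expect_equal(rowSums(matrix(rowSums(H[rows, , drop = FALSE]), 3)),
                 c(0, 0, 0))
  }
})

test_that("the analytic Hessian matches a finite-difference Hessian at equilibrium", {
  set.seed(5)
  m <- random_toy_model(8, sc_frac = 0)
  xyz <- as.matrix(m$beads[, c("x", "y", "z")])
  # dense random network at rest length (so the ANM form is exact)
  pairs <- t(combn(8, 2))
  keep <- sample(nrow(pairs), 16)
  springs <- data.frame(
    i = pairs[keep, 1], j = pairs[keep, 2],
    b0 = sqrt(rowSums((xyz[pairs[keep, 1], ] - xyz[pairs[keep, 2], ])^2)),
    k = round(runif(16, 100, 1000)), origin = "sa")
  net <- elastic_network(springs, model = m)
  H <- build_hessian(m, net, backbone_chain_k = 0)
  Hfd <- fd_hessian(xyz, springs)
  expect_equal(H, Hfd, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("RMSF scales as 1/sqrt(2) when all force constants double", {
  s <- helix_loop_helix()
  net <- build_sahbnet(s)
  p1 <- rmsf_from_modes(build_hessian(net$model, net), net$model)
  net2 <- net
  net2$springs$k <- net2$springs$k * 2
  p2 <- rmsf_from_modes(build_hessian(net$model, net2,
                                      backbone_chain_k = 2500), net$model)
  expect_equal(p2$value, p1$value / sqrt(2), tolerance = 1e-8)
})

test_that("connected 3D networks have exactly 6 near-zero modes; a collinear dimer has 5", {
  eln <- build_elnedyn(helix10())
  H <- build_hessian(eln$model, eln)
  lam <- eigen(H, symmetric = TRUE)$values
  expect_equal(sum(lam < 1e-8 * max(lam)), 6)
  pr <- rmsf_from_modes(H, eln$model)
  expect_equal(attr(pr, "n_zero_modes"), 6)
  expect_true(all(pr$value >= 0))

  m <- dimer()
  net <- elastic_network(data.frame(i = 1L, j = 2L, b0 = 0.4, k = 100,
                                    origin = "sa"), model = m)
  H2 <- build_hessian(m, net, backbone_chain_k = 0)
  lam2 <- eigen(H2, symmetric = TRUE)$values
  expect_equal(sum(lam2 < 1e-8 * max(lam2)), 5)
})

test_that("disconnected networks are refused with component diagnostics", {
  beads <- data.frame(res_uid = 1:4, chain = c("A", "A", "B", "B"),
                      res_ord = c(1, 2, 1, 2), kind = "BB", sc_rank = 0L,
                      x = c(0, 0.4, 5, 5.4), y = c(0, 0.2, 0, 0.2),
                      z = c(0, 0.1, 0, 0.1))
  m <- cg_model(beads)
  sp <- data.frame(i = c(1L, 3L), j = c(2L, 4L), b0 = 0, k = 100,
                   origin = "sa")
  sp$b0 <- c(bead_distance(m, 1, 2), bead_distance(m, 3, 4))
  net <- elastic_network(sp, model = m)
  H <- build_hessian(m, net, backbone_chain_k = 0)
  expect_error(rmsf_from_modes(H, m), "disconnected")
})

test_that("sparse chain ends fluctuate more than the braced middle", {
  set.seed(2)
  n <- 11
  x <- 0.38 * (0:(n - 1))
  beads <- data.frame(res_uid = 1:n, chain = "A", res_ord = 1:n,
                      kind = "BB", sc_rank = 0L, x = x,
                      y = 0.05 * sin(1:n), z = 0.05 * cos(1:n))
  m <- cg_model(beads)
  # dense bracing among middle beads 4..8 only
  mid <- t(combn(4:8, 2))
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  sp <- data.frame(i = mid[, 1], j = mid[, 2],
                   b0 = sqrt(rowSums((xyz[mid[, 1], ] - xyz[mid[, 2], ])^2)),
                   k = 1000, origin = "sa")
  net <- elastic_network(sp, model = m)
  pr <- rmsf_from_modes(build_hessian(m, net), m)
  expect_gt(pr$value[1], max(pr$value[5:7]))
  expect_gt(pr$value[n], max(pr$value[5:7]))
})

test_that("adding a spring never increases any bead's RMSF", {
  set.seed(9)
  for (rep in 1:3) {
    m <- random_toy_model(7, sc_frac = 0)
    xyz <- as.matrix(m$beads[, c("x", "y", "z")])
    pairs <- t(combn(7, 2))
    base_idx <- sample(nrow(pairs), 14)
    mk_net <- function(idx) {
      elastic_network(data.frame(
        i = pairs[idx, 1], j = pairs[idx, 2],
        b0 = sqrt(rowSums((xyz[pairs[idx, 1], ] - xyz[pairs[idx, 2], ])^2)),
        k = 500, origin = "sa"), model = m)
    }
    extra <- setdiff(seq_len(nrow(pairs)), base_idx)[1]
    p_base <- try(rmsf_from_modes(build_hessian(m, mk_net(base_idx)), m),
                  silent = TRUE)
    p_more <- try(rmsf_from_modes(build_hessian(m, mk_net(c(base_idx, extra))),
                                  m), silent = TRUE)
    if (inherits(p_base, "try-error") || inherits(p_more, "try-error")) next
    expect_true(all(attr(p_more, "rmsf_all") <=
                      attr(p_base, "rmsf_all") + 1e-10))
  }
})

test_that("ELNEDYN flattens the profile while SAHBNET keeps loops mobile", {
  s <- helix_loop_helix()
  sahb <- build_sahbnet(s)
  eln <- build_elnedyn(s)
  p_sahb <- rmsf_from_modes(build_hessian(sahb$model, sahb), sahb$model)
  p_eln <- rmsf_from_modes(build_hessian(eln$model, eln), eln$model)
  loop <- 11:14
  # loop beads retain higher fluctuation under SAHBNET
  expect_true(all(p_sahb$value[loop] > p_eln$value[loop]))
  # the dense uniform ELNEDYN profile is flatter overall
  expect_lt(stats::sd(p_eln$value), stats::sd(p_sahb$value))
  expect_lt(diff(range(p_eln$value)), diff(range(p_sahb$value)))
})

test_that("RMSD is zero for identical or rigidly moved frames and matches an independent superposition", {
  ca <- atom_coords(helix10(), "CA")
  expect_equal(rmsd_series(ca, ca), 0)
  R <- sahbnet:::rotation_matrix(c(1, 0.5, -0.2), 0.9)
  moved <- sweep(ca %*% t(R), 2, c(1, -2, 0.5), "+")
  expect_equal(rmsd_series(ca, moved), 0, tolerance = 1e-6)

  # one displaced atom: compare against bio3d's fitted RMSD (A <-> nm)
  pert <- ca
  pert[4, ] <- pert[4, ] + c(0.2, -0.1, 0.15)
  ours <- rmsd_series(ca, pert)
  ref <- bio3d::rmsd(as.vector(t(ca * 10)), as.vector(t(pert * 10)),
                     fit = TRUE) / 10
  expect_equal(ours, ref, tolerance = 1e-3)  # bio3d rounds to 0.001 A
  expect_error(rmsd_series(ca, ca[-1, ]), "mismatch")
})

test_that("delta profiles are antisymmetric signed differences", {
  a <- flex_profile(data.frame(res_uid = 1:5, value = c(1, 2, 3, 4, 5)))
  b <- flex_profile(data.frame(res_uid = 1:5, value = c(1, 2, 3, 4, 5)))
  expect_true(all(delta_profile(a, b)$value == 0))

  b$value <- b$value + 0.25
  d_ab <- delta_profile(a, b)
  d_ba <- delta_profile(b, a)
  expect_equal(d_ab$value, -d_ba$value)
  expect_equal(d_ab$value, rep(-0.25, 5))
  expect_equal(attr(d_ba, "mean_delta"), 0.25)
  expect_error(delta_profile(a, flex_profile(data.frame(res_uid = 1:3,
                                                        value = 1:3))),
               "length")
})

test_that("profiles round trip through 2-column text", {
  s <- helix_loop_helix()
  net <- build_sahbnet(s)
  pr <- rmsf_from_modes(build_hessian(net$model, net), net$model)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_profile(pr, tf)
  back <- read_profile(tf)
  expect_equal(back$value, pr$value, tolerance = 1e-12)
})
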