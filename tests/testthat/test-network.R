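# Spring-network construction, statistics, comparison and sweeps

test_that("hydrogen-bond springs join BB beads, one per undirected pair", {
  h <- helix10()
  m <- map_structure(h)
  hb <- detect_backbone_hbonds(h)
  sp <- build_hbond_springs(m, hb, k = 1000)
  expect_equal(nrow(sp), 6)
  expect_true(all(sp$origin == "hbond"))
  bb_idx <- m$beads$index[m$beads$kind == "BB"]
  expect_true(all(c(sp$i, sp$j) %in% bb_idx))
  expect_true(all(sp$k == 1000))

  # empty list and duplicate directed pairs
  expect_equal(nrow(build_hbond_springs(m, data.frame(donor = integer(0),
                                                      acceptor = integer(0)))), 0)
  dup <- data.frame(donor = c(1, 5), acceptor = c(5, 1))
  expect_equal(nrow(build_hbond_springs(m, dup)), 1)
})

test_that("surface springs obey the buried / distance / separation rule", {
  # toy: buried residue 1, partners at 0.5 / 0.85 / 1.2 nm, separations >= 5
  beads <- data.frame(res_uid = 1:4, chain = "A",
                      res_ord = c(1, 6, 11, 16), kind = "BB", sc_rank = 0L,
                      x = c(0, 0.5, 0.85, 1.2), y = 0, z = 0)
  m <- cg_model(beads)
  rel <- c(`1` = 10, `2` = 90, `3` = 90, `4` = 90)
  p <- network_params(sa_c = 30, r_c = 0.9)
  sp <- build_sa_springs(m, rel, p)
  expect_equal(nrow(sp), 2)
  expect_equal(sort_pairs(spring_pairs(sp)), cbind(c(1, 1), c(2, 3)),
               ignore_attr = TRUE)
  expect_equal(sort(sp$b0), c(0.5, 0.85))

  # separation filter: ordinal difference 5 passes, 4 is blocked
  beads2 <- beads[1:2, ]
  beads2$res_ord <- c(1, 6)
  expect_equal(nrow(build_sa_springs(cg_model(beads2), rel[1:2], p)), 1)
  beads2$res_ord <- c(1, 5)
  expect_equal(nrow(build_sa_springs(cg_model(beads2), rel[1:2], p)), 0)

  # nothing buried -> empty network
  rel_hi <- rel; rel_hi[] <- 80
  expect_equal(nrow(build_sa_springs(m, rel_hi, p)), 0)
})

test_that("partners need not be buried and inter-chain pairs skip the separation filter", {
  beads <- data.frame(res_uid = 1:2, chain = c("A", "B"),
                      res_ord = c(1, 1), kind = "BB", sc_rank = 0L,
                      x = c(0, 0.5), y = 0, z = 0)
  m <- cg_model(beads)
  sp <- build_sa_springs(m, c(`1` = 5, `2` = 95), network_params())
  expect_equal(nrow(sp), 1)
})

test_that("SC-mode surface springs link side-chain beads only", {
  set.seed(11)
  m <- random_toy_model(12, sc_frac = 0.7)
  rel <- stats::setNames(runif(12, 0, 60), 1:12)
  p <- network_params(sa_c = 30, r_c = 0.6, mode = "SC")
  sp <- build_sa_springs(m, rel, p)
  sc_idx <- m$beads$index[m$beads$kind == "SC"]
  if (nrow(sp) > 0) expect_true(all(c(sp$i, sp$j) %in% sc_idx))
  expect_equal(sort_pairs(spring_pairs(sp)),
               sort_pairs(oracle_sa_pairs(m, rel, p)), ignore_attr = TRUE)
})

test_that("ELNEDYN springs follow the distance + separation rule", {
  # 2 residues: separation filter blocks everything
  two <- cg_model(data.frame(res_uid = 1:2, chain = "A", res_ord = 1:2,
                             kind = "BB", sc_rank = 0L,
                             x = c(0, 0.4), y = 0, z = 0))
  expect_equal(nrow(build_elnedyn_springs(two)), 0)

  # collinear 5-bead chain at 0.38 nm: |i-j|>=3 pairs are >= 1.14 nm away
  five <- cg_model(data.frame(res_uid = 1:5, chain = "A", res_ord = 1:5,
                              kind = "BB", sc_rank = 0L,
                              x = 0.38 * (0:4), y = 0, z = 0))
  expect_equal(nrow(build_elnedyn_springs(five, r_c = 0.9, min_sep = 3)), 0)

  # helix: equals brute-force enumeration over all pairs
  m <- map_structure(helix10(), bb_mode = "ca")
  sp <- build_elnedyn_springs(m, r_c = 0.9, min_sep = 3)
  expect_equal(sort_pairs(spring_pairs(sp)),
               sort_pairs(oracle_eln_pairs(m, 0.9, 3)), ignore_attr = TRUE)
  expect_gt(nrow(sp), 0)
})

test_that("spring sets equal the literal rule enumeration on random toy structures", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    m <- random_toy_model(n, two_chains = rep %% 3 == 0)
    rel <- stats::setNames(runif(n, 0, 100), seq_len(n))
    p <- network_params(sa_c = runif(1, 10, 60), r_c = runif(1, 0.5, 1.2))
    got <- sort_pairs(spring_pairs(build_sa_springs(m, rel, p)))
    expect_equal(got, sort_pairs(oracle_sa_pairs(m, rel, p)),
                 ignore_attr = TRUE)
    r_c <- runif(1, 0.5, 1.2)
    got_e <- sort_pairs(spring_pairs(build_elnedyn_springs(m, r_c = r_c)))
    expect_equal(got_e, sort_pairs(oracle_eln_pairs(m, r_c, 3)),
                 ignore_attr = TRUE)
  }
})

test_that("rest lengths reproduce bead distances to 1e-6 nm", {
  s <- helix_loop_helix()
  net <- build_sahbnet(s)
  for (r in seq_len(nrow(net$springs))) {
    expect_equal(net$springs$b0[r],
                 bead_distance(net$model, net$springs$i[r],
                               net$springs$j[r]),
                 tolerance = 1e-6)
  }
})

test_that("merged SAHBNET keeps hydrogen-bond priority and counts add up", {
  s <- helix_loop_helix()
  net <- build_sahbnet(s)
  st <- network_stats(net)
  expect_equal(st$n_springs, st$n_hbond + st$n_sa)
  expect_gt(st$n_hbond, 0)
  expect_gt(st$n_sa, 0)
  expect_equal(anyDuplicated(net$springs[, c("i", "j")]), 0L)

  # SA_c = 0: no residue can be buried -> pure hydrogen-bond network
  net0 <- build_sahbnet(s, network_params(sa_c = 0))
  expect_equal(network_stats(net0)$n_sa, 0)
  expect_equal(network_stats(net0)$n_hbond, st$n_hbond)
})

test_that("spring sets nest as SA_c or R_c grows and ignore K_SPRING", {
  s <- helix_loop_helix()
  key <- function(net) paste(net$springs$i, net$springs$j)
  n20 <- build_sahbnet(s, network_params(sa_c = 20))
  n40 <- build_sahbnet(s, network_params(sa_c = 40))
  expect_true(all(key(n20) %in% key(n40)))
  expect_gt(nrow(n40$springs), nrow(n20$springs))

  r05 <- build_sahbnet(s, network_params(r_c = 0.5))
  r09 <- build_sahbnet(s, network_params(r_c = 0.9))
  expect_true(all(key(r05) %in% key(r09)))

  k1 <- build_sahbnet(s, network_params(k_spring = 100))
  k2 <- build_sahbnet(s, network_params(k_spring = 10000))
  expect_identical(key(k1), key(k2))
  expect_true(all(k1$springs$k == 100) && all(k2$springs$k == 10000))
})

test_that("network statistics satisfy the accounting identities", {
  empty <- elastic_network(data.frame(i = integer(0), j = integer(0),
                                      b0 = numeric(0), k = numeric(0),
                                      origin = character(0)))
  st0 <- network_stats(empty)
  expect_equal(st0$n_springs, 0)
  expect_equal(st0$n_hbond + st0$n_sa + st0$n_elnedyn, 0)

  net <- build_sahbnet(helix10())
  st <- network_stats(net)
  expect_equal(st$n_springs, 6)
  expect_equal(st$n_hbond, 6)
  expect_equal(st$n_sa, 0)
  expect_equal(sum(st$degree), 2 * st$n_springs)
})

test_that("network comparison reports overlap and Jaccard correctly", {
  h <- helix_loop_helix()
  net <- build_sahbnet(h)
  expect_equal(compare_networks(net, net)$jaccard, 1.0)

  m <- net$model
  mk <- function(df) elastic_network(df, model = m)
  sp <- net$springs
  a <- mk(sp[1:2, ])
  b <- mk(sp[3:4, ])
  expect_equal(compare_networks(a, b)$jaccard, 0.0)
  sub <- mk(sp[1:2, ])
  sup <- mk(sp[1:4, ])
  cmp <- compare_networks(sub, sup)
  expect_equal(cmp$jaccard, 0.5)
  expect_equal(cmp$n_shared, 2)
  expect_equal(nrow(cmp$only_b), 2)

  # mismatched bead sets error
  m2 <- m; m2$beads <- m$beads[-nrow(m$beads), ]
  expect_error(compare_networks(net, elastic_network(sp[1:2, ], model = m2)),
               "different bead sets")
})

test_that("parameter sweeps tabulate one row per combination with monotone counts", {
  s <- helix_loop_helix()
  one <- sweep_parameters(s, sa_c = 30, r_c = 0.9, k = 1000)
  expect_equal(nrow(one), 1)
  direct <- network_stats(build_sahbnet(s))
  expect_equal(one$n_springs, direct$n_springs)

  sw <- sweep_parameters(s, sa_c = c(10, 30, 50), r_c = c(0.5, 0.9),
                         k = c(500, 1000))
  expect_equal(nrow(sw), 12)
  for (rc in c(0.5, 0.9)) {
    counts <- sw$n_springs[sw$r_c == rc & sw$k_spring == 1000]
    expect_true(all(diff(counts) >= 0))
  }
  expect_error(sweep_parameters(s, sa_c = numeric(0)), "empty")
})

test_that("two chains within reach get inter-chain springs", {
  a <- build_peptide("AAAA", -139, 135, chain = "A")
  b <- build_peptide("AAAA", -139, 135, chain = "B")
  b$atoms$y <- b$atoms$y + 0.45
  s <- structure3d(rbind(a$atoms[, 1:11], b$atoms[, 1:11]))
  m <- map_structure(s, bb_mode = "ca")
  rel <- stats::setNames(c(10, rep(90, 7)), 1:8)
  sp <- build_sa_springs(m, rel, network_params(r_c = 0.7))
  ch <- m$beads$chain[match(c(sp$i, sp$j), m$beads$index)]
  expect_gt(nrow(sp), 0)
  expect_equal(sort(unique(ch)), c("A", "B"))
  expect_equal(sort_pairs(spring_pairs(sp)),
               sort_pairs(oracle_sa_pairs(m, rel, network_params(r_c = 0.7))),
               ignore_attr = TRUE)
})

test_that("networks export as edge lists", {
  net <- build_sahbnet(helix10())
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tf)
  d <- read.table(tf, header = TRUE)
  expect_equal(nrow(d), 6)
  expect_named(d, c("bead_i", "bead_j", "b0_nm", "k", "origin"))
})
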