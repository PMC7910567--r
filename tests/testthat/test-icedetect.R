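test_that("rational switching function: clamps, limits, asymptote", {
  p <- switching_params(r0 = 0.35, d0 = 0.1, n = 6, m = 12, r_cut = 10)
  expect_equal(rational_switch(0.05, p), 1)      # r <= d0
  expect_equal(rational_switch(p$d0, p), 1)
  expect_equal(rational_switch(p$d0 + p$r0, p), 0.5)   # x = 1 -> n/m

  r <- seq(0, 5, by = 0.01)
  w <- rational_switch(r, p)
  expect_true(all(diff(w) <= 1e-12))             # non-increasing
  expect_true(all(w >= 0 & w <= 1))
  # the rational tail decays as x^(n - m): 1/(1 + x^6) for the defaults
  expect_lte(rational_switch(p$d0 + 3 * p$r0, p), 1.4e-3)
  expect_lte(rational_switch(p$d0 + 10 * p$r0, p), 1e-6)

  expect_error(switching_params(n = 12, m = 6), "m > n")
  expect_error(switching_params(r0 = -1), "r0")
  expect_error(rational_switch(-0.1, p), ">= 0")
})

test_that("q6 vector: single-neighbour closed form and rotational symmetry", {
  # one neighbour along +z: only m = 0 survives, value Y_{6,0}(0)
  cfg <- configuration(rbind(c(1, 1, 1), c(1, 1, 1.27)), c("O", "O"),
                       c("water_O", "water_O"), c(10, 10, 10))
  q <- q6_vector(cfg, 1)
  expect_equal(Re(q["m0"]), sqrt(13 / (4 * pi)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lte(max(abs(q[names(q) != "m0"])), 1e-12)

  # rigid rotation about z leaves every |q6,m| unchanged
  set.seed(3)
  nb <- matrix(rnorm(15), ncol = 3)
  nb <- nb / sqrt(rowSums(nb^2)) * 0.28
  base <- rbind(c(5, 5, 5), sweep(nb, 2, c(5, 5, 5), "+"))
  cfg1 <- configuration(base, rep("O", 6), rep("water_O", 6), c(10, 10, 10))
  th <- 0.83
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- sweep(sweep(base, 2, c(5, 5, 5)) %*% t(Rz), 2, c(5, 5, 5), "+")
  cfg2 <- configuration(rot, rep("O", 6), rep("water_O", 6), c(10, 10, 10))
  expect_equal(abs(q6_vector(cfg1, 1)), abs(q6_vector(cfg2, 1)),
               tolerance = 1e-10)

  # isolated molecule raises a no-neighbours error
  iso <- configuration(rbind(c(1, 1, 1), c(9, 9, 9)), c("O", "O"),
                       c("water_O", "water_O"), c(20, 20, 20))
  expect_error(q6_vector(iso, 1), "no neighbours")
  expect_error(s6(iso, 1), "no neighbours")
})

test_that("q6 and s6 match the brute-force double-loop oracle", {
  p <- switching_params()
  ice <- build_ice_ih(2, 2, 2)
  mid <- which(ice$role == "water_O")[17]
  expect_equal(q6_vector(cfg <- ice, mid), o_q6(ice, mid, p),
               tolerance = 1e-10, ignore_attr = TRUE)

  for (seed in 1:3) {
    cfg <- random_water_config(40, box = c(2, 2, 2), seed = seed)
    got <- icebindr:::s6_all(cfg, p, TRUE)$s6
    want <- o_s6_all(cfg, p, TRUE)
    expect_equal(got, want, tolerance = 1e-10)
    # raw (unnormalized) mode agrees too
    expect_equal(icebindr:::s6_all(cfg, p, FALSE)$s6,
                 o_s6_all(cfg, p, FALSE), tolerance = 1e-10)
  }
})

test_that("s6: unit value for translationally identical environments, bounds,
           rigid-motion invariance", {
  # simple-cubic lattice: every environment identical including orientation
  g <- seq(0.15, 2.85, by = 0.3)
  pts <- as.matrix(expand.grid(g, g, g))
  sc <- configuration(pts, rep("O", nrow(pts)), rep("water_O", nrow(pts)),
                      c(3, 3, 3))
  s <- icebindr:::s6_all(sc, switching_params())$s6
  expect_equal(s, rep(1, length(s)), tolerance = 1e-10)

  # bounds with normalize on
  cfg <- random_water_config(120, seed = 4)
  s2 <- icebindr:::s6_all(cfg, switching_params())$s6
  expect_true(all(is.na(s2) | (s2 >= -1 - 1e-12 & s2 <= 1 + 1e-12)))

  # global rotation + translation invariance: a compact cluster far from
  # the box boundary (minimum imaging itself is not rotation invariant),
  # with pair distances clear of the neighbour-list cutoff
  rc <- switching_params()$r_cut
  for (seed in 5:30) {
    set.seed(seed)
    pos <- matrix(runif(180, -1.2, 1.2), ncol = 3)
    d <- as.numeric(dist(pos))
    if (min(abs(d - rc)) > 1e-3) break
  }
  box <- c(12, 12, 12)
  role <- rep("water_O", nrow(pos)); spec <- rep("O", nrow(pos))
  th <- 0.61; ph <- 1.2
  R1 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  pos2 <- sweep(pos %*% t(R2 %*% R1), 2, c(6.1, 5.9, 6.2), "+")
  cfg3b <- configuration(pos2, spec, role, box)
  cfg3a <- configuration(sweep(pos, 2, c(6, 6, 6), "+"), spec, role, box)
  sa <- icebindr:::s6_all(cfg3a, switching_params())$s6
  sb <- icebindr:::s6_all(cfg3b, switching_params())$s6
  expect_equal(sa, sb, tolerance = 1e-8)
})

test_that("ice classification: thresholds, monotonicity, edge cases", {
  liq <- build_liquid_slab(c(3, 3, 3), 30, seed = 6)
  lab <- classify_ice(liq)
  expect_lt(mean(lab$ice), 0.01)

  # box must exceed twice the neighbour cutoff for an undistorted bulk
  # crystal environment under minimum imaging
  ice <- build_ice_ih(3, 4, 4)
  expect_true(all(classify_ice(ice)$ice))
  # s6 <= 1 with normalize on, so an impossible threshold yields no ice
  expect_equal(sum(classify_ice(ice, threshold = 1.01)$ice), 0L)

  # raising the threshold never increases the ice count
  cfg <- make_composite(seed = 3)$config
  counts <- vapply(c(0.2, 0.45, 0.6, 0.9),
                   function(th) sum(classify_ice(cfg, threshold = th)$ice),
                   integer(1))
  expect_true(all(diff(counts) <= 0))

  expect_error(classify_ice(configuration(rbind(c(1, 1, 1)), "C", "generic",
                                          c(3, 3, 3))), "no water")
})

test_that("largest ice cluster: fixtures and oracle partition equality", {
  # no ice
  liq <- build_liquid_slab(c(2.2, 2.2, 2.2), 20, seed = 8)
  lab <- largest_ice_cluster(liq, classify_ice(liq))
  if (sum(lab$ice) == 0) expect_equal(lab$largest_cluster_size, 0L)

  # two separated blocks of 10 and 20 all-ice molecules
  set.seed(9)
  blk <- function(n, orig) {
    g <- as.matrix(expand.grid(0:4, 0:1, 0:1))[seq_len(n), ] * 0.3
    sweep(g, 2, orig, "+")
  }
  pts <- rbind(blk(10, c(0.5, 0.5, 0.5)), blk(20, c(0.5, 0.5, 3.0)))
  cfg <- configuration(pts, rep("O", 30), rep("water_O", 30), c(8, 8, 8))
  lab2 <- classify_ice(cfg, threshold = -2)      # flag everything ice
  lab2 <- largest_ice_cluster(cfg, lab2, link_cutoff = 0.35)
  expect_equal(lab2$largest_cluster_size, 20L)

  # partition equality against the label-propagation oracle
  for (seed in 1:4) {
    cfg <- random_water_config(60, box = c(2.5, 2.5, 2.5), seed = seed)
    lab <- classify_ice(cfg, threshold = -2)
    lab <- largest_ice_cluster(cfg, lab, link_cutoff = 0.35)
    ice_idx <- lab$water_idx[lab$ice]
    want <- o_clusters(cfg, ice_idx, 0.35)
    got <- lab$cluster[lab$ice]
    # same partition (ids may differ): compare co-membership
    expect_identical(outer(got, got, "=="), outer(want, want, "=="))
    expect_equal(lab$largest_cluster_size, max(tabulate(want)))
  }
})

test_that("rdf: analytic fixtures", {
  # two atoms at exactly 0.3 nm occupy the single bin containing 0.3
  cfg <- configuration(rbind(c(1, 1, 1), c(1, 1, 1.3)), c("O", "O"),
                       c("water_O", "water_O"), c(4, 4, 4))
  g <- rdf(cfg, r_max = 1.0, bin_width = 0.02)
  occ <- which(g$g > 0)
  expect_length(occ, 1L)
  expect_true(g$r[occ] > 0.28 && g$r[occ] < 0.32)

  expect_error(rdf(cfg, r_max = 3), "half the smallest")
  expect_error(rdf(cfg, "amine_N", "water_O"), "non-empty")
})

test_that("solvation shell: counts, strict cutoff, ice/liquid split", {
  # 5 waters at 0.30-0.40 nm from one methylene, plus one at exactly 0.45
  set.seed(10)
  ctr <- c(2, 2, 2)
  dirs <- matrix(rnorm(18), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rr <- c(0.30, 0.325, 0.35, 0.375, 0.40, 0.45)
  wpos <- sweep(dirs * rr, 2, ctr, "+")
  pos <- rbind(ctr, wpos)
  cfg <- configuration(pos, c("C", rep("O", 6)),
                       c("methylene_C", rep("water_O", 6)), c(4, 4, 4))
  lab <- classify_ice(cfg, threshold = 2)    # nothing is ice
  lab$ice[] <- FALSE
  rep1 <- solvation_shell(cfg, lab, cutoff = 0.45)
  expect_equal(rep1$n_total, 5L)             # the 0.45 water is excluded
  expect_equal(rep1$n_ice, 0L)
  expect_equal(rep1$n_liquid, 5L)

  # flip three shell waters to ice: split must track the flags
  lab$ice[1:3] <- TRUE
  rep2 <- solvation_shell(cfg, lab, cutoff = 0.45)
  expect_equal(rep2$n_ice, 3L)
  expect_equal(rep2$n_ice + rep2$n_liquid, rep2$n_total)

  # far-away methylene sees nothing
  cfg2 <- configuration(rbind(c(0.2, 0.2, 0.2), c(3, 3, 3)), c("C", "O"),
                        c("methylene_C", "water_O"), c(4, 4, 4))
  lab2 <- classify_ice(cfg2, threshold = 2)
  rep3 <- solvation_shell(cfg2, lab2)
  expect_equal(rep3$n_total, 0L)

  expect_error(solvation_shell(cfg2, lab2, cutoff = 0.45) -> x, NA)
  cfg3 <- configuration(rbind(c(1, 1, 1)), "O", "water_O", c(3, 3, 3))
  expect_error(solvation_shell(cfg3, classify_ice(cfg3, threshold = 2)),
               "methylene")
})
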