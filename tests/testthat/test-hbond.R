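# 3-atom donor/hydrogen/acceptor fixture with prescribed DA distance and
# DHA angle (degrees); |HA| solved from the law of cosines so both are exact
dha_fixture <- function(da, angle_deg) {
  D <- c(2, 2, 2)
  H <- D + c(0.1, 0, 0)
  th <- angle_deg * pi / 180
  h <- 0.1 * cos(th) + sqrt(0.01 * cos(th)^2 - 0.01 + da^2)
  A <- H + h * c(-cos(th), sin(th), 0)
  configuration(rbind(D, H, A), c("O", "H", "O"),
                c("water_O", "water_H", "water_O"), c(6, 6, 6),
                bonds = rbind(c(1L, 2L)))
}

test_that("hydrogen-bond criterion: distance and angle gates", {
  crit <- hbond_criterion()
  don <- data.frame(donor = 1L, hydrogen = 2L)

  hb <- detect_hbonds(dha_fixture(0.28, 180), don, 3L, crit)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 0.28, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)

  expect_equal(nrow(detect_hbonds(dha_fixture(0.32, 180), don, 3L, crit)), 0L)
  expect_equal(nrow(detect_hbonds(dha_fixture(0.28, 150), don, 3L, crit)), 0L)
  # just inside / outside the folded angle window
  expect_equal(nrow(detect_hbonds(dha_fixture(0.28, 160.01), don, 3L, crit)),
               1L)
  expect_equal(nrow(detect_hbonds(dha_fixture(0.28, 159.99), don, 3L, crit)),
               0L)

  expect_error(hbond_criterion(min_angle = 200), "180")
  expect_error(hbond_criterion(max_da_distance = 0), "> 0")
})

test_that("detect_hbonds equals the triple-loop oracle; mirror symmetry", {
  crit <- hbond_criterion()
  for (seed in 1:5) {
    cfg <- random_water_config(40, box = c(1.6, 1.6, 1.6), seed = seed,
                               with_h = TRUE)
    don <- icebindr:::default_donors(cfg)
    acc <- icebindr:::default_acceptors(cfg)
    got <- detect_hbonds(cfg, don, acc, crit)
    want <- o_hbonds(cfg, don, acc, crit)
    expect_equal(lapply(got[, c("donor", "hydrogen", "acceptor")], as.integer),
                 list(donor = as.integer(want[, 1]),
                      hydrogen = as.integer(want[, 2]),
                      acceptor = as.integer(want[, 3])), ignore_attr = TRUE)
    # no duplicate (hydrogen, acceptor) pairs
    expect_false(any(duplicated(got[, c("hydrogen", "acceptor")])))

    # mirroring the configuration (x -> box - x) leaves the set unchanged
    m <- cfg
    m$positions[, 1] <- cfg$box[1] - m$positions[, 1]
    mc <- configuration(m$positions, m$species, m$role, m$box,
                        bonds = m$bonds)
    got_m <- detect_hbonds(mc, don, acc, crit)
    expect_identical(got[, 1:3], got_m[, 1:3])
  }
})

test_that("polymer-ice bonds: constructed fixture and restriction property", {
  # static slab with a 20-hydroxyl polymer; 4 hydroxyls in ideal geometry
  ice <- build_ice_ih(3, 3, 4)
  zoff <- 1
  box <- c(ice$box[1], ice$box[2], ice$box[3] + 4)
  pos <- ice$positions; pos[, 3] <- pos[, 3] + zoff
  cfg0 <- configuration(pos, ice$species, ice$role, box, "xy",
                        bonds = ice$bonds)
  lab0 <- largest_ice_cluster(cfg0, classify_ice(cfg0))
  top <- icebindr:::largest_cluster_atoms(lab0)
  topz <- cfg0$positions[top, 3]
  sel <- top[order(topz, decreasing = TRUE)]
  sites <- sel[!duplicated(round(cfg0$positions[sel, 1:2] / 0.4))][1:4]

  poly <- build_polymer(rep("VA", 20), "extended", seed = 2)
  np <- nrow(pos)
  ppos <- poly$config$positions
  ppos <- sweep(ppos, 2, colMeans(ppos))
  ppos <- sweep(ppos, 2, c(box[1] / 2, box[2] / 2,
                           max(cfg0$positions[, 3]) + 1.2), "+")
  topo <- icebindr:::shift_topology(poly$topology, np)
  ohO <- icebindr:::topology_atoms(topo, "hydroxyl_O")
  ohH <- icebindr:::topology_atoms(topo, "hydroxyl_H")
  for (k in 1:4) {
    ppos[ohO[k] - np, ] <- cfg0$positions[sites[k], ] + c(0, 0, 0.28)
    ppos[ohH[k] - np, ] <- cfg0$positions[sites[k], ] + c(0, 0, 0.18)
  }
  ppos[, 3] <- pmin(ppos[, 3], box[3] - 1e-6)
  all_cfg <- configuration(rbind(cfg0$positions, ppos),
                           c(cfg0$species, poly$config$species),
                           c(cfg0$role, poly$config$role), box, "xy",
                           bonds = rbind(cfg0$bonds, poly$config$bonds + np))
  lab <- largest_ice_cluster(all_cfg, classify_ice(all_cfg))
  hb <- polymer_ice_bonds(all_cfg, lab, topo)
  bonded <- attr(hb, "hydroxyl_atoms")
  expect_setequal(bonded, ohO[1:4])

  # restriction: polymer-ice bonds are a subset of all detected bonds
  allhb <- detect_hbonds(all_cfg)
  key <- function(df) paste(df$donor, df$hydrogen, df$acceptor)
  expect_true(all(key(hb) %in% key(allhb)))

  # polymer far from ice: empty set
  far <- ppos; far[, 3] <- pmin(far[, 3] + 2.5, box[3])
  cfg_far <- configuration(rbind(cfg0$positions, far),
                           c(cfg0$species, poly$config$species),
                           c(cfg0$role, poly$config$role), box, "xy",
                           bonds = rbind(cfg0$bonds, poly$config$bonds + np))
  lab_far <- largest_ice_cluster(cfg_far, classify_ice(cfg_far))
  expect_equal(nrow(polymer_ice_bonds(cfg_far, lab_far, topo)), 0L)
})

test_that("bound-fraction series and binding time on a scripted movie", {
  poly <- build_polymer(rep("VA", 10), "coil", seed = 4)
  sc <- growth_script(n_frames = 10, dt_ps = 1000, schedule = 24,
                      binding_frame = 4, stall_frames = 99, seed = 3)
  tr <- build_growth_trajectory(sc, poly)
  topo <- attr(tr, "topology")
  bs <- bound_fraction_series(tr, topo)
  expect_true(all(bs$frac_OH[1:3] == 0))
  expect_true(all(bs$frac_OH[4:10] >= 0.20))
  expect_equal(attr(bs, "t0"), 3000)            # frame 4 at dt 1000

  # polymer never near ice: all-zero series, t0 = none
  sc2 <- growth_script(n_frames = 4, dt_ps = 1000, schedule = 24, seed = 3)
  tr2 <- build_growth_trajectory(sc2, poly)
  bs2 <- bound_fraction_series(tr2, attr(tr2, "topology"))
  expect_true(all(bs2$frac_OH == 0))
  expect_true(is.na(attr(bs2, "t0")))
})

test_that("binding_time scans a series correctly", {
  mk <- function(t, f) structure(data.frame(time = t, frac_OH = f),
                                 class = c("binding_series", "data.frame"))
  expect_equal(binding_time(mk(c(0, 10, 20, 30), c(0, 0.1, 0.25, 0.1))), 20)
  expect_true(is.na(binding_time(mk(c(0, 10), c(0.1, 0.15)))))
  expect_equal(binding_time(mk(c(5, 10), c(0, 0.5)), threshold = 0), 5)
  expect_error(binding_time(mk(numeric(0), numeric(0))), "non-empty")
})

test_that("moving average: identity, constancy, shrinking edges", {
  expect_equal(moving_average(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_equal(moving_average(rep(2.5, 7), 5), rep(2.5, 7))
  expect_equal(moving_average(c(0, 1, 0, 1, 0), 3),
               c(0.5, 1 / 3, 2 / 3, 1 / 3, 0.5))
  expect_error(moving_average(1:5, 2), "odd")
})

test_that("hydrogen-bond count distribution normalizes", {
  poly <- build_polymer(rep("VA", 10), "coil", seed = 4)
  sc <- growth_script(n_frames = 8, dt_ps = 1000, schedule = 24,
                      binding_frame = 3, stall_frames = 99, seed = 3)
  tr <- build_growth_trajectory(sc, poly)
  d <- hbond_count_distribution(tr, attr(tr, "topology"), "hydroxyl")
  expect_equal(sum(d$prob), 1)
  expect_true(0L %in% d$count)               # the two unbound frames
  expect_true(any(d$count >= 3L))            # the bound frames

  # never-bound movie: point mass at zero
  sc2 <- growth_script(n_frames = 3, dt_ps = 1000, schedule = 0, seed = 5)
  tr2 <- build_growth_trajectory(sc2, poly)
  d2 <- hbond_count_distribution(tr2, attr(tr2, "topology"), "hydroxyl")
  expect_equal(d2, data.frame(count = 0L, prob = 1))
})
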