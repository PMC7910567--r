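test_that("ice Ih generator: cell counts, box, replication linearity", {
  c111 <- build_ice_ih(1, 1, 1)
  expect_equal(sum(c111$role == "water_O"), 4L)

  c222 <- build_ice_ih(2, 2, 2)
  expect_equal(sum(c222$role == "water_O"), 32L)
  expect_equal(c222$box, 2 * c111$box)

  # molecule count scales linearly in each cell-count argument
  for (dims in list(c(3, 1, 1), c(1, 4, 1), c(1, 1, 5), c(2, 3, 4))) {
    cfg <- build_ice_ih(dims[1], dims[2], dims[3])
    expect_equal(sum(cfg$role == "water_O"), 4L * prod(dims))
  }
})

test_that("ice Ih generator: density, coordination, errors, reproducibility", {
  ice <- build_ice_ih(3, 3, 4)
  wo <- which(ice$role == "water_O")
  vol_cm3 <- prod(ice$box) * 1e-21
  dens <- length(wo) * 18.01528 / 6.02214e23 / vol_cm3
  expect_lt(abs(dens - 0.92) / 0.92, 0.05)

  # every oxygen 4-coordinated at the Ih bond length
  p <- icebindr:::pairs_within(ice, 0.30, subset = wo)
  nb <- tabulate(c(match(p$i, wo), match(p$j, wo)), length(wo))
  expect_true(all(nb == 4L))
  expect_true(all(p$d > 0.27 & p$d < 0.28))

  expect_error(build_ice_ih(2, 2, 2, a_lattice = -1), "positive")
  expect_error(build_ice_ih(0, 1, 1), ">= 1")

  expect_identical(build_ice_ih(2, 2, 2, seed = 9)$positions,
                   build_ice_ih(2, 2, 2, seed = 9)$positions)
  expect_false(identical(build_ice_ih(2, 2, 2, seed = 1)$positions,
                         build_ice_ih(2, 2, 2, seed = 2)$positions))
})

test_that("liquid slab generator: counts, min distance, reproducibility", {
  expect_equal(nrow(build_liquid_slab(c(3, 3, 3), 0)$positions), 0L)

  liq <- build_liquid_slab(c(3, 3, 3), 33, seed = 1)
  expect_equal(sum(liq$role == "water_O"), 891L)   # round(33 * 27)

  wo <- which(liq$role == "water_O")
  p <- icebindr:::pairs_within(liq, 0.24, subset = wo)
  expect_true(all(p$d >= 0.24 - 1e-12))

  expect_error(build_liquid_slab(c(2, 2, 2), 80, min_dist = 0.24),
               "infeasible")

  expect_identical(build_liquid_slab(c(2, 2, 2), 30, seed = 3)$positions,
                   build_liquid_slab(c(2, 2, 2), 30, seed = 3)$positions)
})

test_that("liquid slab is structureless beyond the exclusion distance", {
  liq <- build_liquid_slab(c(5.5, 5.5, 5.5), 30, seed = 7)
  g <- rdf(liq, "water_O", "water_O", r_max = 2.0, bin_width = 0.1)
  far <- g$g[g$r > 0.3]
  expect_true(all(abs(far - 1) < 0.15))       # Monte-Carlo tolerance
  expect_true(all(g$g[g$r < 0.2] == 0))       # below min_dist
})

test_that("polymer generator: composition, Rg restraint, errors", {
  res <- build_polymer(rep("VA", 20), "coil", seed = 1)
  expect_equal(length(icebindr:::topology_atoms(res$topology, "hydroxyl_O")),
               20L)
  expect_equal(length(icebindr:::topology_atoms(res$topology, "methylene_C")),
               20L)

  co <- build_polymer(c(rep("VA", 5), rep("VAm", 5)), "coil", seed = 2)
  expect_equal(length(icebindr:::topology_atoms(co$topology, "hydroxyl_O")), 5L)
  expect_equal(length(icebindr:::topology_atoms(co$topology, "amine_N")), 5L)
  expect_equal(length(icebindr:::topology_atoms(co$topology, "amine_H")), 15L)

  cp <- build_polymer(rep("VA", 10), "compact", target_Rg = 0.5, seed = 3)
  rg <- radius_of_gyration(cp$config)
  expect_gte(rg, 0.49); expect_lte(rg, 0.51)

  expect_error(build_polymer(rep("VA", 20), "coil", target_Rg = 0.01),
               "steric")
  expect_error(build_polymer("VA", "coil"), "polymerisation")
  expect_error(build_polymer(c("VA", "XX"), "coil"), "VA")
})

test_that("radius of gyration: closed forms and pair-sum oracle", {
  one <- configuration(rbind(c(1, 2, 3)), "C", "generic", c(5, 5, 5))
  expect_equal(radius_of_gyration(one), 0)

  two <- configuration(rbind(c(0, 0, 0), c(1, 0, 0)), c("C", "C"),
                       c("generic", "generic"), c(5, 5, 5))
  expect_equal(radius_of_gyration(two), 0.5)

  res <- build_polymer(rep("VA", 20), "coil", seed = 5)
  masses <- icebindr:::atom_masses(res$config)
  expect_equal(radius_of_gyration(res$config),
               o_rg(res$config$positions, masses), tolerance = 1e-12)

  expect_error(radius_of_gyration(one, integer(0)), "non-empty")
})

test_that("growth trajectories: frozen, scripted, conserved, truncated", {
  # all-zero schedule: frames identical
  sc0 <- growth_script(n_frames = 3, schedule = 0, seed = 2)
  tr0 <- build_growth_trajectory(sc0)
  expect_identical(tr0$frames[[1]]$positions, tr0$frames[[3]]$positions)

  # total atom count conserved across frames
  sc <- growth_script(n_frames = 6, schedule = 24, seed = 2)
  tr <- build_growth_trajectory(sc)
  expect_length(unique(vapply(tr$frames, icebindr:::n_atoms, integer(1))), 1L)
  expect_false(attr(tr, "truncated"))

  # reproducible
  tr2 <- build_growth_trajectory(sc)
  expect_identical(tr$frames[[4]]$positions, tr2$frames[[4]]$positions)

  # schedule exceeding capacity truncates with a warning flag
  sc_big <- growth_script(n_frames = 5, schedule = 400, max_layers = 8,
                          seed = 2)
  expect_warning(tr_big <- build_growth_trajectory(sc_big), "truncat")
  expect_true(attr(tr_big, "truncated"))

  expect_error(growth_script(n_frames = 5, schedule = -1), "non-negative")
  expect_error(growth_script(n_frames = 5, binding_frame = 7), "binding")
})

test_that("structure IO round-trips positions, roles, box", {
  ice <- build_ice_ih(2, 2, 2)

  f_gro <- tempfile(fileext = ".gro")
  write_structure(ice, f_gro, "GRO")
  rt <- read_structure(f_gro)
  expect_lte(max(abs(rt$positions - ice$positions)), 5e-4)
  expect_identical(rt$role, ice$role)
  expect_equal(rt$box, ice$box, tolerance = 1e-5)

  f_xyz <- tempfile(fileext = ".xyz")
  write_structure(ice, f_xyz, "XYZ")
  rt2 <- read_structure(f_xyz)
  expect_lte(max(abs(rt2$positions - ice$positions)), 1e-7)
  expect_identical(rt2$species, ice$species)
  expect_identical(rt2$role, ice$role)

  f_pdb <- tempfile(fileext = ".pdb")
  write_structure(ice, f_pdb, "PDB")
  rt3 <- read_structure(f_pdb)
  expect_lte(max(abs(rt3$positions - ice$positions)), 1e-4)
  expect_identical(rt3$role, ice$role)

  # polymer roles survive a round trip too
  poly <- build_polymer(c(rep("VA", 3), rep("VAm", 3)), "extended", seed = 1)
  f2 <- tempfile(fileext = ".gro")
  write_structure(poly$config, f2, "GRO")
  rtp <- read_structure(f2)
  expect_identical(rtp$role, poly$config$role)
})

test_that("structure IO rejects malformed files informatively", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK hi", "ATOM      1  OW  SOL     1       0.000   0.000   0.000  1.00  0.00           O",
               "END"), f)
  expect_error(read_structure(f), "CRYST1")

  f2 <- tempfile(fileext = ".gro")
  writeLines(character(0), f2)
  expect_error(read_structure(f2), "empty")

  f3 <- tempfile(fileext = ".gro")
  ice <- build_ice_ih(1, 1, 1)
  write_structure(ice, f3, "GRO")
  lines <- readLines(f3)
  lines[3] <- sub("SOL", "ZZZ", sub(" OW", " QQ", lines[3]))
  writeLines(lines, f3)
  expect_error(read_structure(f3), "unknown role")

  f4 <- tempfile(fileext = ".xyz")
  writeLines(c("3", "no lattice here", "O 0 0 0 water_O"), f4)
  expect_error(read_structure(f4), "Lattice|expected")
})

test_that("trajectory IO round-trips frames and times", {
  sc <- growth_script(n_frames = 3, schedule = 24, seed = 4)
  tr <- build_growth_trajectory(sc)
  f <- tempfile(fileext = ".xyz")
  write_trajectory(tr, f, "XYZ")
  rt <- read_trajectory(f)
  expect_length(rt, 3L)
  expect_equal(frame_times <- vapply(rt$frames, function(x) x$time, numeric(1)),
               c(0, 2000, 4000))
  expect_lte(max(abs(rt$frames[[2]]$positions - tr$frames[[2]]$positions)),
             1e-7)
})
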