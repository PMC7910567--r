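# icebindr

Quantitative analysis of ice growth and polymer–ice interaction in molecular
configurations, with generators for fully synthetic test systems.

Flexible polymers such as poly(vinyl alcohol) (PVA) inhibit ice
recrystallisation: once a chain hydrogen-bonds to an advancing ice front it
can pin the front, unless the crystal overgrows and engulfs it. Molecular
simulation studies of this process need a common computational layer — which
water molecules are ice, how big is the growing crystal, when did the polymer
bind, how much volume and contact area does it occupy at the interface, what
does its conformational free-energy landscape look like. `icebindr`
implements that layer as a self-contained R package, exercised end-to-end on
synthetically generated ice/water/polymer configurations, for researchers in
molecular simulation and cryoprotectant design.

## What it computes

**Ice detection (Steinhardt order parameter).** Each water oxygen *i* gets a
6th-order Steinhardt vector

    q6m(i) = Σ_j σ(|rij|) Y6m(r̂ij) / Σ_j σ(|rij|),   m = −6…6,

with a rational switching function σ defining a fuzzy coordination shell, and
the neighbour-correlation order parameter

    s6(i) = Σ_j σ(|rij|) Σ_m q6m*(i)·q6m(j) / Σ_j σ(|rij|)

(unit-normalized q6 vectors by default). Molecules with `s6 > 0.45` are
ice-like; the largest connected cluster of them is the growing crystal.

**Hydrogen bonds and binding time.** Geometric criterion: donor–acceptor
distance < 0.3 nm and folded donor–hydrogen–acceptor angle ≥ 160°. The
binding time t0 is the first frame where ≥ 20 % of the polymer's hydroxyls
are hydrogen-bonded to the largest ice cluster.

**Interface geometry.** Alpha-shape occupied volume (Delaunay simplices with
circumradius ≤ 0.17 nm), xy-projected ice contact area, minimum
periodic-image distance rMI, ice-front position and advancement, and surface
coverage in polymers/nm².

**Growth metrics.** Ice-count curves, molecule growth in a fixed window
after t0, growth rates, and an `active` / `overgrown` / `unbound` fate
classification.

**Well-tempered metadynamics.** Parsing of deposited-Gaussians ("hills")
logs, bias reconstruction `V(s,t) = Σ_{kτ<t} W(kτ) exp(−(s−s(kτ))²/2σ²)`,
the free-energy profile `ΔG(s) = −γ/(γ−1)·V(s, t_end)` over the radius of
gyration (bias factor γ = 100 by default), and minima/barrier scans.

**Synthetic systems.** Hexagonal-ice Ih slabs with the primary prismatic
face in the xy-plane (growth along ±z), disordered liquid layers, PVA /
PVAm / block-copolymer chains with labelled hydroxyl, amine and methylene
groups and controllable radius of gyration, and scripted frame-by-frame
growth movies with programmable binding time, stall and engulfment. GRO,
PDB and extended-XYZ readers/writers round-trip all of it.

## Worked example

A 14-frame growth movie: a PVA decamer binds the upper prismatic front at
frame 4, stalls the front for 2 frames, then is engulfed.

```r
library(icebindr)

poly   <- build_polymer(rep("VA", 10), "coil", seed = 4)
script <- growth_script(n_frames = 14, dt_ps = 1000, schedule = 24,
                        binding_frame = 4, stall_frames = 2, engulf = TRUE,
                        seed = 3)
traj <- build_growth_trajectory(script, poly)
topo <- attr(traj, "topology")

series <- bound_fraction_series(traj, topo)
head(series, 6)
#>   time frac_OH frac_NH3 n_bonds_OH n_bonds_NH3
#> 1    0     0.0       NA          0           0
#> 2 1000     0.0       NA          0           0
#> 3 2000     0.0       NA          0           0
#> 4 3000     0.3       NA          3           0
#> 5 4000     0.3       NA          3           0
#> 6 5000     0.3       NA          3           0
attr(series, "t0")
#> [1] 3000
```

30 % of the hydroxyls bond at frame 4 (t = 3000 ps), so t0 lands on the
programmed binding frame. The ice count plateaus during the stall:

```r
curve <- growth_curve(traj)
head(curve, 6)
#>   time n_ice
#> 1    0    96
#> 2 1000   120
#> 3 2000   144
#> 4 3000   168
#> 5 4000   168
#> 6 5000   168
growth_in_window(curve, t0 = 3000, window_ns = 4)
#> [1] 48
classify_overgrowth(traj, topo, t0 = 3000)
#> [1] overgrown
```

48 molecules grow in the 4 ns after binding (two paused frames, then two
24-molecule layers as the front overruns the chain), and the fate
classifier reports the scripted engulfment. Interface geometry on an
embedded frame:

```r
cfg <- traj$frames[[10]]
lab <- largest_ice_cluster(cfg, classify_ice(cfg))
lab
#> <ice_labels> 487 waters | 288 ice (s6 > 0.45) | largest cluster 264
contact_area(cfg, topo, lab)$area        # nm^2, xy-projected
#> [1] 0.1961...
min_image_distance(cfg, topo)            # nm
#> [1] 0.59...
```

## Command-line interface

```sh
exec/icebindr synth ice --cells 3,3,4 --out ice.gro
exec/icebindr classify --in ice.gro --out-csv s6.csv --out-json summary.json
exec/icebindr fes --hills HILLS --out fes.dat --minima minima.json
```

## Documentation

The methods vignette (`vignettes/ice-polymer-analysis.Rmd`) describes the
model and its assumptions, every tunable parameter with units and defaults,
what the synthetic generators do and do not emulate, and the package's
numerical conventions and limitations.
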