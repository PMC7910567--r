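#' Scripted ice-growth movie parameters
#'
#' Declares a deterministic, frame-by-frame synthetic stand-in for an
#' ice-growth production run: a central hexagonal-ice slab (prismatic face in
#' xy) flanked by static disordered liquid bands, a per-frame
#' layer-conversion schedule that turns liquid molecules into lattice
#' molecules at the advancing +/-z fronts, and an optional programmed
#' polymer-binding event with stall and engulfment.
#'
#' Frame `binding_frame` (1-based) places the polymer's hydroxyls in ideal
#' hydrogen-bond geometry on the upper front; conversion then pauses for
#' `stall_frames` frames. With `engulf = TRUE` conversion subsequently
#' resumes and the polymer is embedded in the crystal interior; otherwise the
#' polymer detaches and growth resumes.
#'
#' @param n_frames number of frames (>= 2).
#' @param dt_ps frame spacing in ps.
#' @param schedule molecules converted per frame transition: a scalar or a
#'   vector of length `n_frames` (entry f applies between frames f-1 and f;
#'   the first entry is ignored). Must be non-negative.
#' @param cells_x,cells_y lateral generator-cell counts of the slab.
#' @param initial_layers occupied lattice layers at frame 1.
#' @param binding_frame programmed binding frame (1-based, < n_frames), or
#'   `NA` for an unbound run.
#' @param stall_frames conversion pause after binding.
#' @param engulf logical; resume growth and embed the polymer after the stall.
#' @param max_layers optional hard cap on total lattice layers; a schedule
#'   exceeding capacity is truncated with a warning flag.
#' @param liquid_density liquid number density (nm^-3).
#' @param gap depletion gap between lattice and liquid molecules (nm).
#' @param seed integer RNG seed.
#' @param a_lattice,c_lattice lattice constants (nm).
#' @return An object of class `growth_script`.
#' @export
growth_script <- function(n_frames, dt_ps = 2000, schedule = 4,
                          cells_x = 2, cells_y = 3, initial_layers = 6,
                          binding_frame = NA_integer_, stall_frames = 0,
                          engulf = FALSE, max_layers = NULL,
                          liquid_density = 30, gap = 0.8, seed = 1L,
                          a_lattice = 0.45, c_lattice = 0.732) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (length(schedule) == 1L) schedule <- rep(schedule, n_frames)
  if (length(schedule) != n_frames)
    stop("schedule must be scalar or length n_frames")
  if (any(schedule < 0)) stop("schedule must be non-negative")
  schedule[1] <- 0
  if (!is.na(binding_frame) && binding_frame >= n_frames)
    stop("programmed binding frame must be < n_frames")
  structure(list(n_frames = as.integer(n_frames), dt_ps = dt_ps,
                 schedule = as.integer(round(schedule)),
                 cells_x = as.integer(cells_x), cells_y = as.integer(cells_y),
                 initial_layers = as.integer(initial_layers),
                 binding_frame = as.integer(binding_frame),
                 stall_frames = as.integer(stall_frames),
                 engulf = isTRUE(engulf),
                 max_layers = if (is.null(max_layers)) NULL else as.integer(max_layers),
                 liquid_density = liquid_density, gap = gap,
                 seed = as.integer(seed),
                 a_lattice = a_lattice, c_lattice = c_lattice),
            class = "growth_script")
}

# shift all atom indices of a polymer topology by a fixed offset
shift_topology <- function(topo, offset) {
  topo$monomers <- lapply(topo$monomers, lapply, function(v) v + offset)
  topo$bonds <- topo$bonds + as.integer(offset)
  topo$atom_offset <- topo$atom_offset + as.integer(offset)
  topo
}

# effective per-frame conversion counts after the stall window
effective_schedule <- function(script) {
  eff <- script$schedule
  b <- script$binding_frame
  if (!is.na(b) && script$stall_frames > 0) {
    pause <- seq(b + 1L, min(script$n_frames, b + script$stall_frames))
    eff[pause] <- 0L
  }
  eff
}

#' Build a scripted ice-growth trajectory
#'
#' Realizes a [growth_script()] as an `ice_trajectory`: every frame converts
#' the scheduled number of liquid molecules onto the next lattice sites at
#' the growth fronts (alternating above/below the slab), conserving the
#' total atom count. See [growth_script()] for the binding/stall/engulf
#' programme. A depletion gap separates lattice and liquid molecules so that
#' scripted ice counts are exactly recoverable by the s6 classifier.
#'
#' @param script a `growth_script`.
#' @param polymer optional result of [build_polymer()] (list with `config`
#'   and `topology`).
#' @return An `ice_trajectory` with attributes `topology` (index-shifted
#'   polymer topology or `NULL`), `script`, `n_initial_ice`, and `truncated`.
#' @export
build_growth_trajectory <- function(script, polymer = NULL) {
  stopifnot(inherits(script, "growth_script"))
  a <- script$a_lattice; cc <- script$c_lattice
  cell_z <- sqrt(3) / 2 * a
  per_layer <- 4L * script$cells_x * script$cells_y
  eff <- effective_schedule(script)
  n_conv_req <- sum(eff)

  n_layers_needed <- script$initial_layers +
    2L * as.integer(ceiling(n_conv_req / per_layer / 2 + 1))
  truncated <- FALSE
  if (!is.null(script$max_layers) && n_layers_needed > script$max_layers) {
    n_layers_needed <- script$max_layers
    capacity <- per_layer * (n_layers_needed - script$initial_layers)
    if (n_conv_req > capacity) {
      truncated <- TRUE
      warning("conversion schedule exhausts available liquid/lattice; truncated")
      cs <- pmin(cumsum(eff), capacity)
      eff <- as.integer(diff(c(0L, cs)))
      n_conv_req <- sum(eff)
    }
  }
  nz <- n_layers_needed
  lat <- build_ice_ih(script$cells_x, script$cells_y, nz,
                      a_lattice = a, c_lattice = cc, seed = script$seed)
  n_sites <- n_atoms(lat) %/% 3L
  siteO <- lat$positions[3L * (seq_len(n_sites) - 1L) + 1L, , drop = FALSE]
  layer <- as.integer(floor(siteO[, 3] / cell_z + 1e-9))
  lay_lo <- (nz - script$initial_layers) %/% 2L
  lay_hi <- lay_lo + script$initial_layers - 1L
  initial_sites <- which(layer >= lay_lo & layer <= lay_hi)
  free <- which(layer < lay_lo | layer > lay_hi)
  # conversion order: layers alternately above/below, nearest first;
  # within a layer, row-major in (y, x)
  ldist <- ifelse(layer[free] > lay_hi, layer[free] - lay_hi, lay_lo - layer[free])
  side <- ifelse(layer[free] > lay_hi, 0L, 1L)  # upper side first on ties
  ord <- order(ldist, side, round(siteO[free, 2] / a * 4),
               round(siteO[free, 1] / cc * 8))
  site_order <- free[ord]
  if (n_conv_req > length(site_order)) {
    truncated <- TRUE
    warning("conversion schedule exhausts available lattice sites; truncated")
    cs <- pmin(cumsum(eff), length(site_order))
    eff <- as.integer(diff(c(0L, cs)))
    n_conv_req <- sum(eff)
  }

  box_xy <- lat$box[1:2]
  z_lat_top <- nz * cell_z
  n_liquid <- n_conv_req + max(30L, as.integer(0.3 * n_conv_req))
  t_liq <- (n_liquid / 2) / (script$liquid_density * prod(box_xy))
  gap <- script$gap
  z_off <- t_liq + gap + 0.5   # shift so bottom liquid band starts above 0
  parking <- NA_real_
  p_ext <- 0
  if (!is.null(polymer)) {
    pc <- polymer$config$positions
    p_ext <- max(apply(pc, 2, function(v) diff(range(v)))) / 2
  }
  box_z <- z_off + z_lat_top + gap + t_liq + 1.2 + 2 * p_ext + 1.0

  # liquid bands (static), half above and half below the full lattice extent
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(script$seed + 7L)
  box <- c(box_xy, box_z)
  n_lo <- n_liquid %/% 2L
  n_hi <- n_liquid - n_lo
  liqO <- rbind(
    .rsa_insert_cpp(n_lo, box, FALSE, 0.24,
                    c(0.35, z_off - gap), 20000L),
    .rsa_insert_cpp(n_hi, box, FALSE, 0.24,
                    c(z_off + z_lat_top + gap, z_off + z_lat_top + gap + t_liq),
                    20000L))
  # water atom block: initial slab molecules first, then liquid molecules
  n_wmol <- length(initial_sites) + n_liquid
  wpos <- matrix(0, 3L * n_wmol, 3)
  site_atoms <- function(s) lat$positions[3L * (s - 1L) + 1:3, , drop = FALSE]
  for (k in seq_along(initial_sites)) {
    wpos[3L * (k - 1L) + 1:3, ] <- site_atoms(initial_sites[k])
  }
  doh <- 0.09572
  u1 <- random_unit(n_liquid)
  for (k in seq_len(n_liquid)) {
    i <- length(initial_sites) + k
    u2 <- perp_at_angle(u1[k, ], 104.52)
    wpos[3L * (i - 1L) + 1, ] <- liqO[k, ]
    wpos[3L * (i - 1L) + 2, ] <- liqO[k, ] + doh * u1[k, ]
    wpos[3L * (i - 1L) + 3, ] <- liqO[k, ] + doh * u2
  }
  wpos[seq_len(3L * length(initial_sites)), 3] <-
    wpos[seq_len(3L * length(initial_sites)), 3] + z_off
  wspecies <- rep(c("O", "H", "H"), n_wmol)
  wrole <- rep(c("water_O", "water_H", "water_H"), n_wmol)
  wbonds <- cbind(rep(3L * (seq_len(n_wmol) - 1L) + 1L, each = 2),
                  3L * rep(seq_len(n_wmol) - 1L, each = 2) + c(2L, 3L))

  n_watoms <- 3L * n_wmol
  topo <- NULL
  ppos0 <- NULL
  if (!is.null(polymer)) {
    topo <- shift_topology(polymer$topology, n_watoms)
    ppos0 <- polymer$config$positions
    pspecies <- polymer$config$species
    prole <- polymer$config$role
    pbonds <- polymer$config$bonds + n_watoms
    parking <- z_off + z_lat_top + gap + t_liq + 1.0 + p_ext
  }

  cum <- cumsum(eff)
  b <- script$binding_frame
  # z of the upper front (top of highest occupied layer) per frame
  front_top_layer <- function(nconv) {
    conv <- if (nconv > 0) site_order[seq_len(nconv)] else integer(0)
    max(layer[c(initial_sites, conv)])
  }

  # pre-compute binding placement against the front at the binding frame
  bind_override <- NULL
  bound_com_z <- NA_real_
  if (!is.null(polymer) && !is.na(b)) {
    nconv_b <- cum[b]
    occ <- c(initial_sites, if (nconv_b > 0) site_order[seq_len(nconv_b)])
    # bind only to front molecules that the s6 classifier itself places in
    # the largest cluster (outermost-layer lattice molecules straddle the
    # 0.45 threshold)
    wpos_b <- wpos
    if (nconv_b > 0) {
      for (q in seq_len(nconv_b)) {
        sa <- site_atoms(site_order[q]); sa[, 3] <- sa[, 3] + z_off
        wpos_b[3L * (length(initial_sites) + q - 1L) + 1:3, ] <- sa
      }
    }
    cfg_b <- configuration(wpos_b, wspecies, wrole, box, "xy", bonds = wbonds)
    lab_b <- largest_ice_cluster(cfg_b, classify_ice(cfg_b))
    in_cluster <- largest_cluster_atoms(lab_b)          # water O atom rows
    mol_in_cluster <- (in_cluster - 1L) %/% 3L + 1L
    site_of_mol <- c(initial_sites, site_order)[mol_in_cluster]
    zocc <- siteO[site_of_mol, 3] + z_off
    top <- site_of_mol[order(zocc, decreasing = TRUE)]
    oh_O <- topology_atoms(topo, "hydroxyl_O")
    oh_H <- topology_atoms(topo, "hydroxyl_H")
    n_bind <- max(1L, as.integer(ceiling(0.25 * length(oh_O))))
    sel_sites <- integer(0)
    for (s in top) {
      if (length(sel_sites) >= n_bind) break
      sxy <- siteO[s, 1:2]
      okd <- TRUE
      for (t in sel_sites) {
        d <- min_image(c(siteO[t, 1:2], 0), c(sxy, 0), c(box_xy, 1), "xyz")
        if (sqrt(sum(d^2)) < 0.35) { okd <- FALSE; break }
      }
      if (okd) sel_sites <- c(sel_sites, s)
    }
    n_bind <- length(sel_sites)
    sel_oh <- seq_len(n_bind)
    bind_override <- list(
      O = oh_O[sel_oh], H = oh_H[sel_oh],
      O_pos = cbind(siteO[sel_sites, 1:2, drop = FALSE],
                    siteO[sel_sites, 3] + z_off + 0.28),
      H_pos = cbind(siteO[sel_sites, 1:2, drop = FALSE],
                    siteO[sel_sites, 3] + z_off + 0.18))
    bound_com_z <- max(siteO[sel_sites, 3]) + z_off + 0.45 + p_ext
  }

  frames <- vector("list", script$n_frames)
  times <- (seq_len(script$n_frames) - 1) * script$dt_ps
  slab_center_z <- z_off + (lay_lo + script$initial_layers / 2) * cell_z
  for (f in seq_len(script$n_frames)) {
    pos <- wpos
    nconv <- cum[f]
    if (nconv > 0) {
      for (q in seq_len(nconv)) {
        mol <- length(initial_sites) + q       # consume liquid molecule q
        sa <- site_atoms(site_order[q])
        sa[, 3] <- sa[, 3] + z_off
        pos[3L * (mol - 1L) + 1:3, ] <- sa
      }
    }
    if (!is.null(polymer)) {
      pp <- ppos0
      com <- colMeans(pp)
      # parked before binding; bound through the stall window; afterwards
      # embedded (engulf) or detached back to parking (no engulf)
      phase <- if (is.na(b) || f < b) "parked"
               else if (f <= b + script$stall_frames) "bound"
               else if (script$engulf) "embedded"
               else "parked"
      target <- switch(phase,
        parked = c(box_xy / 2, parking),
        bound = c(box_xy / 2, bound_com_z),
        embedded = c(box_xy / 2, slab_center_z))
      pp <- sweep(pp, 2, com) ; pp <- sweep(pp, 2, target, "+")
      if (phase == "bound" && !is.null(bind_override)) {
        pp[bind_override$O - n_watoms, ] <- bind_override$O_pos
        pp[bind_override$H - n_watoms, ] <- bind_override$H_pos
      }
      pos <- rbind(pos, pp)
      species <- c(wspecies, pspecies)
      role <- c(wrole, prole)
      bonds <- rbind(wbonds, pbonds)
    } else {
      species <- wspecies; role <- wrole; bonds <- wbonds
    }
    pos[, 3] <- pmin(pmax(pos[, 3], 0), box_z)
    frames[[f]] <- configuration(pos, species, role, box, "xy",
                                 time = times[f], bonds = bonds)
  }
  traj <- trajectory(frames, dt_ps = script$dt_ps)
  attr(traj, "topology") <- topo
  attr(traj, "script") <- script
  attr(traj, "effective_schedule") <- eff
  attr(traj, "n_initial_ice") <- length(initial_sites)
  attr(traj, "truncated") <- truncated
  traj
}
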