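# Independent brute-force reference implementations. These deliberately use
# different code paths from the package internals: generic associated
# Legendre recurrences instead of closed-form order-6 polynomials, explicit
# double loops instead of vectorized pair lists, label propagation instead
# of union-find.

# minimum-image displacement, scalar path
o_mi <- function(a, b, box, pbc) {
  d <- b - a
  nper <- if (identical(pbc, "xy")) 2 else 3
  for (k in seq_len(nper)) d[k] <- d[k] - box[k] * round(d[k] / box[k])
  d
}

# associated Legendre P_l^m (Condon-Shortley) by recurrence
o_alp <- function(l, m, x) {
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, 1 - x^2))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  pll <- pmmp1
  for (ll in (m + 2):l) {
    pll <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pll
}

# Y_{6,m} for a single unit vector, m = -6..6
o_y6 <- function(u) {
  theta <- acos(max(-1, min(1, u[3])))
  phi <- atan2(u[2], u[1])
  out <- complex(13)
  for (m in 0:6) {
    K <- sqrt((13 / (4 * pi)) * factorial(6 - m) / factorial(6 + m))
    y <- K * o_alp(6, m, cos(theta)) * exp(1i * m * phi)
    out[7 + m] <- y
    if (m > 0) out[7 - m] <- (-1)^m * Conj(y)
  }
  out
}

o_switch <- function(r, p) {
  if (r >= p$r_cut) return(0)
  x <- (r - p$d0) / p$r0
  if (x <= 0) return(1)
  if (abs(x - 1) < 1e-9) return(p$n / p$m)
  (1 - x^p$n) / (1 - x^p$m)
}

# q6 vector of water-oxygen atom `i` by direct double loop
o_q6 <- function(config, i, params) {
  wo <- which(config$role == "water_O")
  acc <- complex(13)
  wsum <- 0
  for (j in wo) {
    if (j == i) next
    d <- o_mi(config$positions[i, ], config$positions[j, ], config$box,
              config$pbc_mode)
    r <- sqrt(sum(d^2))
    if (r >= params$r_cut || r < 1e-12) next
    w <- o_switch(r, params)
    acc <- acc + w * o_y6(d / r)
    wsum <- wsum + w
  }
  if (wsum <= 0) return(NULL)
  acc / wsum
}

# s6 values for all waters by direct double loop
o_s6_all <- function(config, params, normalize = TRUE) {
  wo <- which(config$role == "water_O")
  Q <- lapply(wo, function(i) o_q6(config, i, params))
  if (normalize) {
    Q <- lapply(Q, function(q) {
      if (is.null(q)) return(NULL)
      nq <- sqrt(Re(sum(q * Conj(q))))
      if (nq > 0) q / nq else q
    })
  }
  s <- rep(NA_real_, length(wo))
  for (a in seq_along(wo)) {
    if (is.null(Q[[a]])) next
    num <- 0; den <- 0
    for (b in seq_along(wo)) {
      if (a == b || is.null(Q[[b]])) next
      d <- o_mi(config$positions[wo[a], ], config$positions[wo[b], ],
                config$box, config$pbc_mode)
      r <- sqrt(sum(d^2))
      if (r >= params$r_cut || r < 1e-12) next
      w <- o_switch(r, params)
      num <- num + w * Re(sum(Conj(Q[[a]]) * Q[[b]]))
      den <- den + w
    }
    if (den > 0) s[a] <- num / den
  }
  s
}

# connected components by label propagation (O(N^2) per sweep)
o_clusters <- function(config, ice_atom_idx, link_cutoff) {
  n <- length(ice_atom_idx)
  if (!n) return(integer(0))
  lab <- seq_len(n)
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a >= b) next
    d <- o_mi(config$positions[ice_atom_idx[a], ],
              config$positions[ice_atom_idx[b], ], config$box,
              config$pbc_mode)
    if (sqrt(sum(d^2)) < link_cutoff) adj[a, b] <- adj[b, a] <- TRUE
  }
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) {
      nb <- which(adj[a, ])
      if (length(nb)) {
        m <- min(lab[a], lab[nb])
        if (any(c(lab[a], lab[nb]) != m)) {
          lab[a] <- m
          lab[nb] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# hydrogen-bond triplets by triple loop
o_hbonds <- function(config, donors, acceptors, criterion) {
  res <- list()
  for (r in seq_len(nrow(donors))) {
    D <- donors$donor[r]; H <- donors$hydrogen[r]
    for (A in acceptors) {
      if (A == D) next
      da <- o_mi(config$positions[D, ], config$positions[A, ], config$box,
                 config$pbc_mode)
      dd <- sqrt(sum(da^2))
      if (dd >= criterion$max_da_distance) next
      hd <- o_mi(config$positions[H, ], config$positions[D, ], config$box,
                 config$pbc_mode)
      ha <- o_mi(config$positions[H, ], config$positions[A, ], config$box,
                 config$pbc_mode)
      cosang <- sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang >= criterion$min_angle)
        res[[length(res) + 1]] <- c(D, H, A)
    }
  }
  if (!length(res)) return(matrix(integer(0), 0, 3))
  m <- do.call(rbind, res)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# radius of gyration via the pair-sum identity
# Rg^2 = sum_{i<j} m_i m_j r_ij^2 / M^2
o_rg <- function(pos, masses) {
  M <- sum(masses)
  acc <- 0
  for (i in seq_len(nrow(pos) - 1)) for (j in (i + 1):nrow(pos)) {
    acc <- acc + masses[i] * masses[j] * sum((pos[i, ] - pos[j, ])^2)
  }
  sqrt(acc / M^2)
}

# rMI by exhaustive image enumeration
o_rmi <- function(pos, box, pbc) {
  sh <- if (identical(pbc, "xy")) {
    expand.grid(-1:1, -1:1, 0)
  } else expand.grid(-1:1, -1:1, -1:1)
  sh <- as.matrix(sh[rowSums(abs(sh)) > 0, ])
  best <- Inf
  for (k in seq_len(nrow(sh))) {
    off <- sh[k, ] * box
    for (i in seq_len(nrow(pos))) for (j in seq_len(nrow(pos))) {
      best <- min(best, sum((pos[i, ] - pos[j, ] - off)^2))
    }
  }
  sqrt(best)
}

# metadynamics bias by direct double loop
o_bias <- function(log, s, t = Inf) {
  out <- numeric(length(s))
  for (q in seq_along(s)) {
    acc <- 0
    for (k in seq_len(nrow(log))) {
      if (log$time[k] < t)
        acc <- acc + log$height[k] *
          exp(-(s[q] - log$center[k])^2 / (2 * log$sigma[k]^2))
    }
    out[q] <- acc
  }
  out
}

# ---- fixture builders ------------------------------------------------------

# random disordered water box (oxygens only, optional hydrogens)
random_water_config <- function(n, box = c(3, 3, 3), seed = 1,
                                with_h = FALSE, pbc = "xyz") {
  set.seed(seed)
  pos <- matrix(runif(3 * n), ncol = 3) %*% diag(box)
  if (!with_h) {
    return(configuration(pos, rep("O", n), rep("water_O", n), box, pbc))
  }
  allpos <- matrix(0, 3 * n, 3)
  role <- character(3 * n); species <- character(3 * n)
  bonds <- matrix(0L, 2 * n, 2)
  for (i in seq_len(n)) {
    o <- 3 * (i - 1) + 1
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    allpos[o, ] <- pos[i, ]
    allpos[o + 1, ] <- pos[i, ] + 0.096 * u
    allpos[o + 2, ] <- pos[i, ] + 0.096 * (cos(1.82) * u + sin(1.82) * v)
    species[o] <- "O"; species[o + 1:2] <- "H"
    role[o] <- "water_O"; role[o + 1:2] <- "water_H"
    bonds[2 * i - 1, ] <- c(o, o + 1)
    bonds[2 * i, ] <- c(o, o + 2)
  }
  configuration(allpos, species, role, box, pbc, bonds = bonds)
}

# ice slab embedded in liquid bands with a depletion gap (slab geometry)
make_composite <- function(cells_x = 2, cells_y = 3, layers = 6,
                           liquid_per_side = 120, gap = 0.8, seed = 1) {
  ice <- build_ice_ih(cells_x, cells_y, layers, seed = seed)
  t_liq <- liquid_per_side / (30 * ice$box[1] * ice$box[2])
  z_off <- t_liq + gap + 0.3
  box <- c(ice$box[1], ice$box[2], z_off + ice$box[3] + gap + t_liq + 0.3)
  pos <- ice$positions
  pos[, 3] <- pos[, 3] + z_off
  liq_lo <- build_liquid_slab(box, liquid_per_side /
                                (box[1] * box[2] * (z_off - gap - 0.2)),
                              seed = seed + 1, pbc_mode = "xyz",
                              zrange = c(0.2, z_off - gap))
  liq_hi <- build_liquid_slab(box, liquid_per_side /
                                (box[1] * box[2] * (t_liq + 0.05)),
                              seed = seed + 2, pbc_mode = "xyz",
                              zrange = c(z_off + ice$box[3] + gap,
                                         z_off + ice$box[3] + gap + t_liq + 0.05))
  allpos <- rbind(pos, liq_lo$positions, liq_hi$positions)
  species <- c(ice$species, liq_lo$species, liq_hi$species)
  role <- c(ice$role, liq_lo$role, liq_hi$role)
  bonds <- rbind(ice$bonds,
                 liq_lo$bonds + nrow(pos),
                 liq_hi$bonds + nrow(pos) + nrow(liq_lo$positions))
  cfg <- configuration(allpos, species, role, box, "xy", bonds = bonds)
  n_ice_mol <- nrow(pos) / 3
  lat_z <- pos[seq(1, nrow(pos), by = 3), 3]
  cell_z <- sqrt(3) / 2 * 0.45
  interior <- which(lat_z > z_off + cell_z & lat_z < z_off + ice$box[3] - cell_z)
  list(config = cfg, n_ice_mol = n_ice_mol,
       ice_mol = seq_len(n_ice_mol),
       interior_mol = interior,
       liquid_mol = n_ice_mol + seq_len((nrow(liq_lo$positions) +
                                           nrow(liq_hi$positions)) / 3))
}
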