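#' Hexagonal ice Ih slab generator
#'
#' Builds the oxygen sublattice of hexagonal ice Ih oriented with a primary
#' prismatic plane parallel to xy, so that the crystal growth normal is the z
#' axis. The hexagonal c axis runs along x. The generator cell is one
#' half-height orthorhombic slice of the conventional orthorhombic Ih cell:
#' dimensions `c_lattice` x `a_lattice` x `sqrt(3)/2 * a_lattice`, holding 4
#' water molecules; alternate z layers carry the centering shift `a/2` along
#' y, which reproduces the Ih stacking exactly inside the box. (The periodic
#' wrap across z is only seamless for even `cells_z`; irrelevant for slab
#' geometries.)
#'
#' Hydrogens are placed on the O-O connecting lines at a fixed O-H length
#' with a randomized two-of-four assignment per oxygen; the proton network is
#' therefore not Bernal-Fowler ice-rule exact. Ice/liquid classification uses
#' oxygens only and is unaffected.
#'
#' @param cells_x,cells_y,cells_z number of generator cells (each >= 1).
#' @param a_lattice,c_lattice hexagonal lattice constants in nm
#'   (defaults 0.45 and 0.732, giving a mass density near 0.93 g/cm3).
#' @param seed integer seed for the proton assignment.
#' @return An `ice_config` with `4 * cells_x * cells_y * cells_z` water
#'   molecules (O then 2 H per molecule, contiguous) and pbc `"xyz"`.
#' @export
build_ice_ih <- function(cells_x, cells_y, cells_z,
                         a_lattice = 0.45, c_lattice = 0.732, seed = 1L) {
  if (cells_x < 1 || cells_y < 1 || cells_z < 1)
    stop("cell counts must be >= 1")
  if (a_lattice <= 0 || c_lattice <= 0)
    stop("lattice constants must be positive")
  a <- a_lattice; cc <- c_lattice
  cell <- c(cc, a, sqrt(3) / 2 * a)
  # 4-molecule basis of the half-height slice (x = c axis)
  base <- rbind(
    c(0,        0,     sqrt(3) / 3 * a),
    c(3 / 8 * cc, 0,   sqrt(3) / 3 * a),
    c(1 / 2 * cc, a / 2, sqrt(3) / 6 * a),
    c(7 / 8 * cc, a / 2, sqrt(3) / 6 * a))
  nmol <- 4L * cells_x * cells_y * cells_z
  O <- matrix(0, nmol, 3)
  k <- 0L
  for (iz in seq_len(cells_z) - 1L) {
    yshift <- if (iz %% 2L == 1L) a / 2 else 0
    for (iy in seq_len(cells_y) - 1L) {
      for (ix in seq_len(cells_x) - 1L) {
        off <- c(ix * cell[1], iy * cell[2] + yshift, iz * cell[3])
        O[k + 1:4, ] <- sweep(base, 2, off, "+")
        k <- k + 4L
      }
    }
  }
  box <- c(cells_x, cells_y, cells_z) * cell
  O[, 2] <- O[, 2] %% box[2]
  cfg_O <- list(positions = O, box = box, pbc_mode = "xyz")

  # proton placement: 2 of up to 4 nearest O neighbours, O-H = 0.1 nm
  doh <- 0.10
  bond_cut <- 1.15 * 3 / 8 * cc  # covers both bond types, excludes 2nd shell
  p <- .pairs_within_cpp(O, box, TRUE, bond_cut)
  nb <- vector("list", nmol)
  dir <- vector("list", nmol)
  if (length(p$i)) {
    for (q in seq_along(p$i)) {
      i <- p$i[q]; j <- p$j[q]
      u <- c(p$dx[q], p$dy[q], p$dz[q]) / p$d[q]
      nb[[i]] <- c(nb[[i]], j); dir[[i]] <- c(dir[[i]], list(u))
      nb[[j]] <- c(nb[[j]], i); dir[[j]] <- c(dir[[j]], list(-u))
    }
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  pos <- matrix(0, 3L * nmol, 3)
  species <- character(3L * nmol)
  role <- character(3L * nmol)
  bonds <- matrix(0L, 2L * nmol, 2)
  for (i in seq_len(nmol)) {
    oi <- 3L * (i - 1L) + 1L
    pos[oi, ] <- O[i, ]
    species[oi] <- "O"; role[oi] <- "water_O"
    ndir <- dir[[i]]
    if (length(ndir) >= 2L) {
      pick <- sample(length(ndir), 2L)
      u1 <- ndir[[pick[1]]]; u2 <- ndir[[pick[2]]]
    } else {
      u1 <- random_unit(1)[1, ]
      u2 <- perp_at_angle(u1, 104.52)
    }
    pos[oi + 1L, ] <- O[i, ] + doh * u1
    pos[oi + 2L, ] <- O[i, ] + doh * u2
    species[oi + 1:2] <- "H"; role[oi + 1:2] <- "water_H"
    bonds[2L * i - 1L, ] <- c(oi, oi + 1L)
    bonds[2L * i, ] <- c(oi, oi + 2L)
  }
  configuration(pos, species, role, box, "xyz", bonds = bonds)
}

random_unit <- function(n) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# unit vector at `angle_deg` from unit vector u, random azimuth
perp_at_angle <- function(u, angle_deg) {
  w <- random_unit(1)[1, ]
  w <- w - sum(w * u) * u
  w <- w / sqrt(sum(w^2))
  th <- angle_deg * pi / 180
  cos(th) * u + sin(th) * w
}

#' Disordered liquid water slab generator
#'
#' Places water oxygens by random sequential insertion with a hard
#' minimum-distance constraint under the box periodicity, then attaches two
#' hydrogens per oxygen with the rigid water geometry at a random
#' orientation. Beyond `min_dist` the pair correlation is that of an ideal
#' gas (g(r) ~ 1).
#'
#' @param box box lengths (nm).
#' @param number_density oxygen number density in nm^-3.
#' @param min_dist minimum O-O distance in nm (default 0.24).
#' @param seed integer RNG seed.
#' @param pbc_mode `"xyz"` (default) or `"xy"`.
#' @param zrange optional `c(zmin, zmax)` restricting insertion to a slab of
#'   the box (density then refers to that sub-volume).
#' @return An `ice_config`; `round(number_density * volume)` molecules.
#' @export
build_liquid_slab <- function(box, number_density, min_dist = 0.24, seed = 1L,
                              pbc_mode = "xyz", zrange = NULL) {
  box <- as.numeric(box)
  if (number_density < 0) stop("number density must be >= 0")
  if (number_density * min_dist^3 > 0.6)
    stop("density infeasible: number_density * min_dist^3 exceeds the ",
         "random-insertion jamming guard (0.6)")
  if (is.null(zrange)) zrange <- c(0, box[3])
  vol <- box[1] * box[2] * (zrange[2] - zrange[1])
  n <- round(number_density * vol)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  if (n == 0) {
    return(configuration(matrix(numeric(0), 0, 3), character(0), character(0),
                         box, pbc_mode))
  }
  O <- .rsa_insert_cpp(as.integer(n), box, identical(pbc_mode, "xyz"),
                       min_dist, zrange, 20000L)
  doh <- 0.09572
  pos <- matrix(0, 3L * n, 3)
  species <- character(3L * n)
  role <- character(3L * n)
  bonds <- matrix(0L, 2L * n, 2)
  u1 <- random_unit(n)
  for (i in seq_len(n)) {
    oi <- 3L * (i - 1L) + 1L
    pos[oi, ] <- O[i, ]
    u2 <- perp_at_angle(u1[i, ], 104.52)
    pos[oi + 1L, ] <- O[i, ] + doh * u1[i, ]
    pos[oi + 2L, ] <- O[i, ] + doh * u2
    species[oi] <- "O"; species[oi + 1:2] <- "H"
    role[oi] <- "water_O"; role[oi + 1:2] <- "water_H"
    bonds[2L * i - 1L, ] <- c(oi, oi + 1L)
    bonds[2L * i, ] <- c(oi, oi + 2L)
  }
  if (identical(pbc_mode, "xy")) pos[, 3] <- pmin(pmax(pos[, 3], 0), box[3])
  configuration(pos, species, role, box, pbc_mode, bonds = bonds)
}
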