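#' @useDynLib icebindr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# canonical per-atom role tags
ROLE_LEVELS <- c("water_O", "water_H", "hydroxyl_O", "hydroxyl_H",
                 "amine_N", "amine_H", "methylene_C", "backbone_C", "generic")

# atomic masses, amu
ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)

#' Molecular configuration
#'
#' A static snapshot of a molecular system: Cartesian positions in nm, one
#' chemical species and one role tag per atom, an orthorhombic box, and the
#' periodic-boundary mode (`"xyz"` for bulk, `"xy"` for slab geometries where
#' z is non-periodic). An optional bond list carries covalent topology
#' (water O-H bonds, polymer bonds) where analyses need it.
#'
#' @param positions numeric N x 3 matrix of coordinates (nm).
#' @param species character vector of element symbols (H, C, N, O, ...).
#' @param role character vector of role tags; one of
#'   `water_O, water_H, hydroxyl_O, hydroxyl_H, amine_N, amine_H,
#'   methylene_C, backbone_C, generic`.
#' @param box numeric length-3 vector of box edge lengths (nm), all `> 0`.
#' @param pbc_mode `"xyz"` or `"xy"`.
#' @param time frame time in ps, or `NA`.
#' @param bonds optional integer 2-column matrix of 1-based atom index pairs.
#' @return An object of class `ice_config`.
#' @export
configuration <- function(positions, species, role, box,
                          pbc_mode = c("xyz", "xy"), time = NA_real_,
                          bonds = NULL) {
  pbc_mode <- match.arg(pbc_mode)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (length(species) != n || length(role) != n)
    stop("species and role must have one entry per atom")
  bad <- setdiff(unique(role), ROLE_LEVELS)
  if (length(bad))
    stop("unknown role name(s): ", paste(bad, collapse = ", "))
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be 3 positive lengths (nm)")
  if (pbc_mode == "xy") {
    z <- positions[, 3]
    if (n > 0 && (min(z) < -1e-9 || max(z) > box[3] + 1e-9))
      stop("under pbc_mode = 'xy', z coordinates must lie inside the box")
  }
  if (!is.null(bonds)) {
    bonds <- as.matrix(bonds)
    storage.mode(bonds) <- "integer"
    if (ncol(bonds) != 2L || any(bonds < 1L) || any(bonds > n))
      stop("bonds must be a 2-column matrix of valid atom indices")
  }
  # every hydroxyl_H must be bonded to exactly one hydroxyl_O
  if (any(role == "hydroxyl_H")) {
    if (is.null(bonds))
      stop("configurations with hydroxyl_H atoms must carry a bond list")
    hh <- which(role == "hydroxyl_H")
    for (h in hh) {
      partners <- c(bonds[bonds[, 1] == h, 2], bonds[bonds[, 2] == h, 1])
      if (sum(role[partners] == "hydroxyl_O") != 1L)
        stop("hydroxyl_H atom ", h, " must be bonded to exactly one hydroxyl_O")
    }
  }
  structure(list(positions = positions, species = as.character(species),
                 role = as.character(role), box = box, pbc_mode = pbc_mode,
                 time = as.numeric(time), bonds = bonds),
            class = "ice_config")
}

#' @export
print.ice_config <- function(x, ...) {
  cat(sprintf("<ice_config> %d atoms | box %.3f x %.3f x %.3f nm | pbc %s%s\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3], x$pbc_mode,
              if (is.finite(x$time)) sprintf(" | t = %g ps", x$time) else ""))
  tab <- table(factor(x$role, levels = ROLE_LEVELS))
  tab <- tab[tab > 0]
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

n_atoms <- function(config) nrow(config$positions)

water_oxygens <- function(config) which(config$role == "water_O")

atom_masses <- function(config) {
  m <- ATOMIC_MASSES[config$species]
  m[is.na(m)] <- 12.011  # unknown species treated as carbon-mass
  unname(m)
}

#' Minimum-image displacement vectors
#'
#' Displacements `to - from` wrapped by the minimum-image convention on the
#' periodic axes of the configuration.
#'
#' @param from,to numeric vectors (length 3) or N x 3 matrices.
#' @param box box lengths (nm).
#' @param pbc_mode `"xyz"` or `"xy"`.
#' @return matrix of displacements with the same number of rows as the inputs.
#' @export
min_image <- function(from, to, box, pbc_mode = "xyz") {
  from <- matrix(as.numeric(from), ncol = 3)
  to <- matrix(as.numeric(to), ncol = 3)
  if (nrow(from) == 1L && nrow(to) > 1L) from <- from[rep(1L, nrow(to)), , drop = FALSE]
  if (nrow(to) == 1L && nrow(from) > 1L) to <- to[rep(1L, nrow(from)), , drop = FALSE]
  d <- to - from
  nper <- if (identical(pbc_mode, "xy")) 2L else 3L
  for (k in seq_len(nper)) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# pair list (i < j) within cutoff; thin wrapper over the C++ kernel
pairs_within <- function(config, cutoff, subset = NULL) {
  pos <- config$positions
  if (!is.null(subset)) pos <- pos[subset, , drop = FALSE]
  p <- .pairs_within_cpp(pos, config$box, identical(config$pbc_mode, "xyz"),
                         cutoff)
  if (!is.null(subset)) {
    p$i <- subset[p$i]
    p$j <- subset[p$j]
  }
  p
}

cross_pairs_within <- function(config, idx_a, idx_b, cutoff) {
  .cross_pairs_within_cpp(config$positions[idx_a, , drop = FALSE],
                          config$positions[idx_b, , drop = FALSE],
                          config$box, identical(config$pbc_mode, "xyz"),
                          cutoff)
}

#' Trajectory of configurations
#'
#' An ordered list of [configuration()] frames sharing atom count, ordering
#' and box topology, with strictly increasing frame times.
#'
#' @param frames list of `ice_config` objects.
#' @param dt_ps frame spacing in ps (optional; inferred from frame times).
#' @return An object of class `ice_trajectory`.
#' @export
trajectory <- function(frames, dt_ps = NULL) {
  if (!length(frames)) stop("trajectory needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "ice_config")))
    stop("all frames must be ice_config objects")
  n0 <- n_atoms(frames[[1]])
  if (!all(vapply(frames, n_atoms, integer(1)) == n0))
    stop("all frames must share the same atom count")
  for (f in frames) {
    if (!identical(f$role, frames[[1]]$role))
      stop("all frames must share atom ordering and roles")
    if (!identical(f$pbc_mode, frames[[1]]$pbc_mode))
      stop("all frames must share the pbc mode")
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(is.na(times))) {
    if (is.null(dt_ps)) dt_ps <- 1
    times <- (seq_along(frames) - 1) * dt_ps
    for (k in seq_along(frames)) frames[[k]]$time <- times[k]
  }
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (is.null(dt_ps)) dt_ps <- if (length(times) > 1) times[2] - times[1] else 1
  structure(list(frames = frames, dt_ps = dt_ps), class = "ice_trajectory")
}

#' @export
print.ice_trajectory <- function(x, ...) {
  cat(sprintf("<ice_trajectory> %d frames x %d atoms | dt = %g ps\n",
              length(x$frames), n_atoms(x$frames[[1]]), x$dt_ps))
  invisible(x)
}

#' @export
length.ice_trajectory <- function(x) length(x$frames)

frame_times <- function(traj) vapply(traj$frames, function(f) f$time, numeric(1))
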