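# Alpha shapes via Delaunay filtering: keep simplices whose circumradius is
# at most the alpha radius. Tessellation topology is computed on
# deterministically jittered coordinates (1e-9 nm, fixed internal seed) to
# break cospherical degeneracies; all metric quantities (volumes, areas,
# circumradii) are evaluated on the original coordinates.

alpha_jitter <- function(pts, magnitude = 1e-9) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(20141017L)
  pts + matrix(runif(length(pts), -magnitude, magnitude), nrow(pts))
}

tet_volume <- function(pts, tets) {
  a <- pts[tets[, 1], , drop = FALSE]
  v1 <- pts[tets[, 2], , drop = FALSE] - a
  v2 <- pts[tets[, 3], , drop = FALSE] - a
  v3 <- pts[tets[, 4], , drop = FALSE] - a
  cx <- v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]
  cy <- v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]
  cz <- v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]
  abs(v1[, 1] * cx + v1[, 2] * cy + v1[, 3] * cz) / 6
}

tet_circumradius <- function(pts, tets) {
  n <- nrow(tets)
  out <- numeric(n)
  for (k in seq_len(n)) {
    a <- pts[tets[k, 1], ]
    M <- rbind(pts[tets[k, 2], ] - a, pts[tets[k, 3], ] - a,
               pts[tets[k, 4], ] - a)
    rhs <- rowSums(M^2) / 2
    cc <- tryCatch(solve(M, rhs), error = function(e) NULL)
    out[k] <- if (is.null(cc)) Inf else sqrt(sum(cc^2))
  }
  out
}

tri_area2d <- function(pts, tris) {
  a <- pts[tris[, 1], , drop = FALSE]
  b <- pts[tris[, 2], , drop = FALSE]
  c2 <- pts[tris[, 3], , drop = FALSE]
  abs((b[, 1] - a[, 1]) * (c2[, 2] - a[, 2]) -
        (b[, 2] - a[, 2]) * (c2[, 1] - a[, 1])) / 2
}

tri_circumradius2d <- function(pts, tris) {
  n <- nrow(tris)
  out <- numeric(n)
  for (k in seq_len(n)) {
    a <- pts[tris[k, 1], ]
    M <- rbind(pts[tris[k, 2], ] - a, pts[tris[k, 3], ] - a)
    rhs <- rowSums(M^2) / 2
    cc <- tryCatch(solve(M, rhs), error = function(e) NULL)
    out[k] <- if (is.null(cc)) Inf else sqrt(sum(cc^2))
  }
  out
}

#' Alpha-shape occupied volume
#'
#' Delaunay tetrahedralization of the (unwrapped) points filtered to
#' simplices with circumradius at most `alpha`; the occupied volume is the
#' sum of the retained tetrahedra. As `alpha` grows the result converges to
#' the convex-hull volume.
#'
#' @param points numeric N x 3 matrix (nm), N >= 4, not all coplanar.
#' @param alpha alpha radius in nm (default 0.17).
#' @return An object of class `alpha_shape` with fields `volume` (in cubic
#'   Angstrom), `alpha`, `n_vertices`, `n_simplices`.
#' @export
alpha_shape_volume <- function(points, alpha = 0.17) {
  points <- as.matrix(points)
  if (nrow(points) < 4)
    stop("degenerate input: alpha-shape volume needs at least 4 points")
  if (qr(sweep(points, 2, colMeans(points)))$rank < 3)
    stop("degenerate input: points are coplanar")
  tets <- .delaunay3d_cpp(alpha_jitter(points))
  rr <- tet_circumradius(points, tets)
  keep <- rr <= alpha
  vol_nm3 <- if (any(keep)) sum(tet_volume(points, tets[keep, , drop = FALSE])) else 0
  verts <- if (any(keep)) length(unique(as.vector(tets[keep, ]))) else 0L
  structure(list(volume = vol_nm3 * 1000,   # nm^3 -> A^3
                 area = NA_real_, alpha = alpha,
                 n_vertices = verts, n_simplices = sum(keep)),
            class = "alpha_shape")
}

#' @export
print.alpha_shape <- function(x, ...) {
  cat(sprintf("<alpha_shape> alpha = %g nm | volume = %.2f A^3%s | %d vertices\n",
              x$alpha, x$volume,
              if (is.finite(x$area)) sprintf(" | area = %.4f nm^2", x$area) else "",
              x$n_vertices))
  invisible(x)
}

# 2-D alpha-shape area of projected points
alpha_area_2d <- function(xy, alpha) {
  if (nrow(xy) < 3)
    stop("degenerate input: alpha-shape area needs at least 3 projected points")
  xy3 <- cbind(xy, 0)
  tris <- .delaunay2d_cpp(alpha_jitter(xy3)[, 1:2, drop = FALSE])
  rr <- tri_circumradius2d(xy, tris)
  keep <- rr <= alpha
  if (any(keep)) sum(tri_area2d(xy, tris[keep, , drop = FALSE])) else 0
}

#' Polymer-ice projected contact area
#'
#' Projects the polymer atoms bound at the ice surface onto the xy plane and
#' measures the 2-D alpha-shape area. By default "bound" means every polymer
#' heavy atom within `contact_cutoff` of a largest-cluster water oxygen; with
#' `bound_only = TRUE` the stricter selection of atoms appearing in the
#' supplied hydrogen-bond set is used.
#'
#' @param config an `ice_config`.
#' @param topology a `polymer_topology`.
#' @param labels an `ice_labels` with clusters filled.
#' @param alpha alpha radius (nm).
#' @param bound_only use the hydrogen-bond selection instead of the distance
#'   selection.
#' @param hbonds an `hbond_set` (required when `bound_only = TRUE`).
#' @param contact_cutoff distance selection cutoff (nm), default 0.35.
#' @return An `alpha_shape` with the `area` field set (nm^2).
#' @export
contact_area <- function(config, topology, labels, alpha = 0.17,
                         bound_only = FALSE, hbonds = NULL,
                         contact_cutoff = 0.35) {
  heavy <- topology_atoms(topology, "heavy")
  if (!length(heavy)) stop("polymer has no heavy atoms")
  if (bound_only) {
    if (is.null(hbonds)) stop("bound_only = TRUE requires an hbond_set")
    poly_all <- topology_atoms(topology, "all")
    sel <- intersect(unique(c(hbonds$donor, hbonds$acceptor)), poly_all)
  } else {
    ice_O <- largest_cluster_atoms(labels)
    if (!length(ice_O)) stop("no ice cluster to measure contact against")
    p <- cross_pairs_within(config, heavy, ice_O, contact_cutoff)
    sel <- heavy[unique(p$i[p$d < contact_cutoff])]
  }
  if (length(sel) < 3)
    stop("degenerate input: fewer than 3 bound atoms to project")
  xy <- config$positions[sel, 1:2, drop = FALSE]
  area <- alpha_area_2d(xy, alpha)
  structure(list(volume = NA_real_, area = area, alpha = alpha,
                 n_vertices = length(sel), n_simplices = NA_integer_),
            class = "alpha_shape")
}

#' Minimum periodic-image distance of a polymer
#'
#' Minimum distance between any polymer atom and any atom of a periodic
#' image of the polymer: the minimum over nonzero lattice shifts (the 8
#' in-plane neighbour images under pbc `"xy"`, all 26 under `"xyz"`) of the
#' distance between the atom set and its shifted copy.
#'
#' @param config an `ice_config`.
#' @param topology a `polymer_topology`, or `NULL` to use every non-water
#'   atom.
#' @param box optional box override (nm).
#' @return rMI in nm.
#' @export
min_image_distance <- function(config, topology = NULL, box = NULL) {
  if (is.null(box)) box <- config$box
  idx <- if (is.null(topology)) {
    which(!(config$role %in% c("water_O", "water_H")))
  } else topology_atoms(topology, "all")
  if (!length(idx)) stop("no polymer atoms found")
  P <- config$positions[idx, , drop = FALSE]
  shifts <- if (identical(config$pbc_mode, "xy")) {
    as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = 0))
  } else {
    as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  }
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  if (!nrow(shifts)) stop("no periodic directions")
  best <- Inf
  for (k in seq_len(nrow(shifts))) {
    Q <- sweep(P, 2, shifts[k, ] * box, "+")
    for (i in seq_len(nrow(P))) {
      d2 <- rowSums(sweep(Q, 2, P[i, ])^2)
      best <- min(best, min(d2))
    }
  }
  sqrt(best)
}

#' Ice-front profile along z
#'
#' Bins the box along z and computes the fraction of water molecules in each
#' bin that belong to the largest ice cluster. The upper and lower front
#' positions are the outermost z where the linearly interpolated fraction
#' crosses 0.5 (box edges when the profile never drops below 0.5).
#'
#' @param config an `ice_config`.
#' @param labels an `ice_labels` with clusters filled.
#' @param bin_width z bin width (nm), default 0.05.
#' @return An object of class `front_profile`: list with `z` (bin centres),
#'   `fraction`, `upper`, `lower` (nm).
#' @export
front_profile <- function(config, labels, bin_width = 0.05) {
  ice_O <- largest_cluster_atoms(labels)
  if (!length(ice_O)) stop("no ice cluster: front undefined")
  wo <- labels$water_idx
  edges <- seq(0, config$box[3], by = bin_width)
  if (edges[length(edges)] < config$box[3]) edges <- c(edges, config$box[3])
  zb_all <- findInterval(config$positions[wo, 3], edges,
                         rightmost.closed = TRUE)
  zb_ice <- findInterval(config$positions[ice_O, 3], edges,
                         rightmost.closed = TRUE)
  nb <- length(edges) - 1
  tot <- tabulate(zb_all, nbins = nb)
  ice <- tabulate(zb_ice, nbins = nb)
  frac <- ifelse(tot > 0, ice / pmax(tot, 1), NA_real_)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  # fronts from the water-containing bins only; the 0.5 crossing is
  # interpolated in z between consecutive non-empty bins, and sits at the
  # box edge when the profile never drops below 0.5 on that side
  ne <- which(tot > 0)
  occ <- ne[frac[ne] >= 0.5]
  if (!length(occ)) stop("no z bin reaches ice fraction 0.5")
  hi <- max(occ); lo <- min(occ)
  above <- ne[ne > hi]
  upper <- if (!length(above)) config$box[3] else {
    j <- above[1]
    mids[hi] + (frac[hi] - 0.5) / (frac[hi] - frac[j]) * (mids[j] - mids[hi])
  }
  below <- rev(ne[ne < lo])
  lower <- if (!length(below)) 0 else {
    j <- below[1]
    mids[lo] - (frac[lo] - 0.5) / (frac[lo] - frac[j]) * (mids[lo] - mids[j])
  }
  structure(list(z = mids, fraction = frac, upper = upper, lower = lower,
                 bin_width = bin_width),
            class = "front_profile")
}

#' Front advancement across a trajectory
#'
#' Mean outward displacement of the two fronts relative to frame 1,
#' reported in Angstrom: `((upper_t - upper_0) + (lower_0 - lower_t)) / 2`.
#'
#' @param traj an `ice_trajectory`.
#' @param params,threshold,link_cutoff classification settings.
#' @param bin_width z bin width (nm).
#' @return data.frame with columns `time`, `upper`, `lower` (nm) and
#'   `advancement` (Angstrom).
#' @export
front_advancement <- function(traj, params = switching_params(),
                              threshold = 0.45, link_cutoff = 0.35,
                              bin_width = 0.05) {
  rows <- lapply(traj$frames, function(cfg) {
    labels <- largest_ice_cluster(cfg, classify_ice(cfg, params, threshold),
                                  link_cutoff)
    fp <- front_profile(cfg, labels, bin_width)
    data.frame(time = cfg$time, upper = fp$upper, lower = fp$lower)
  })
  out <- do.call(rbind, rows)
  out$advancement <- ((out$upper - out$upper[1]) +
                        (out$lower[1] - out$lower)) / 2 * 10
  rownames(out) <- NULL
  out
}

#' Polymer surface coverage
#'
#' Number of polymers per unit ice cross-section (one face).
#'
#' @param n_polymers polymer count on the face.
#' @param box box lengths (nm) or an `ice_config`.
#' @return coverage in polymers/nm^2.
#' @export
surface_coverage <- function(n_polymers, box) {
  if (inherits(box, "ice_config")) box <- box$box
  if (box[1] <= 0 || box[2] <= 0) stop("xy box lengths must be positive")
  n_polymers / (box[1] * box[2])
}
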