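#' Switching-function parameters for the Steinhardt coordination shell
#'
#' Rational switching function `(1 - x^n) / (1 - x^m)` with
#' `x = (r - d0) / r0`, clamped to 1 for `r <= d0`, used to weight
#' neighbours in the Steinhardt sums. With the defaults `n = 6, m = 12` this
#' is `1 / (1 + x^6)`. Sums are truncated at `r_cut` (default `d0 + 3 r0`,
#' where the weight has decayed to ~1.4e-3); the truncation radius is part
#' of the operator definition.
#'
#' The defaults (`d0 = 0.45`, `r0 = 0.10`) weight the whole first solvation
#' shell (extent 0.45 nm, the first minimum of the water O-O radial
#' distribution function) with ~1 and decay across the second shell. This
#' window separates hexagonal ice (interior s6 > 0.95) from disordered
#' water (s6 < ~0.35) with a wide margin around the 0.45 classification
#' threshold; narrower first-shell-only windows put substantial
#' liquid-phase weight above the threshold.
#'
#' @param r0 switching range (nm), `> 0`.
#' @param d0 offset (nm).
#' @param n,m integer exponents, `m > n > 0`.
#' @param r_cut neighbour-list truncation radius (nm).
#' @return An object of class `switching_params`.
#' @export
switching_params <- function(r0 = 0.10, d0 = 0.45, n = 6L, m = 12L,
                             r_cut = d0 + 3 * r0) {
  if (r0 <= 0) stop("r0 must be > 0")
  n <- as.integer(n); m <- as.integer(m)
  if (!(m > n && n > 0)) stop("switching exponents must satisfy m > n > 0")
  if (r_cut <= d0) stop("r_cut must exceed d0")
  structure(list(r0 = r0, d0 = d0, n = n, m = m, r_cut = r_cut),
            class = "switching_params")
}

#' Rational switching function
#'
#' @param r distances (nm), `>= 0`.
#' @param params a [switching_params()].
#' @return weights in `[0, 1]`, continuous and non-increasing in `r`.
#' @export
rational_switch <- function(r, params = switching_params()) {
  if (any(r < 0)) stop("distances must be >= 0")
  x <- (r - params$d0) / params$r0
  w <- numeric(length(r))
  lo <- x <= 0
  w[lo] <- 1
  at1 <- !lo & abs(x - 1) < 1e-9
  w[at1] <- params$n / params$m      # analytic limit of 0/0 at x = 1
  rest <- !lo & !at1
  xr <- x[rest]
  w[rest] <- (1 - xr^params$n) / (1 - xr^params$m)
  w
}

# --- spherical harmonics of order 6 ----------------------------------------

# Y_{6,m}(direction), m = 0..6, for unit vectors given as N x 3 matrix;
# Condon-Shortley phase included. m = -6..-1 follow from
# Y_{6,-m} = (-1)^m Conj(Y_{6,m}).
sph_harm6 <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  ct <- z                           # cos(theta)
  st2 <- pmax(0, 1 - ct^2)          # sin^2(theta)
  st <- sqrt(st2)
  # e^{i m phi} built from (x + i y)/sin(theta); safe at the poles where the
  # associated Legendre factor vanishes for m > 0
  eip <- complex(real = x, imaginary = y)
  eip <- ifelse(st > 1e-12, eip / st, 0 + 0i)
  ct2 <- ct * ct
  # associated Legendre P6^m(ct) (with Condon-Shortley (-1)^m)
  P60 <- (231 * ct2^3 - 315 * ct2^2 + 105 * ct2 - 5) / 16
  P61 <- -(21 / 8) * st * ct * (33 * ct2^2 - 30 * ct2 + 5)
  P62 <- (105 / 8) * st2 * (33 * ct2^2 - 18 * ct2 + 1)
  P63 <- -(315 / 2) * st2 * st * ct * (11 * ct2 - 3)
  P64 <- (945 / 2) * st2^2 * (11 * ct2 - 1)
  P65 <- -10395 * st2^2 * st * ct
  P66 <- 10395 * st2^3
  norm <- function(m) sqrt((13 / (4 * pi)) *
                             factorial(6 - m) / factorial(6 + m))
  cbind(m0 = norm(0) * P60 + 0i,
        m1 = norm(1) * P61 * eip,
        m2 = norm(2) * P62 * eip^2,
        m3 = norm(3) * P63 * eip^3,
        m4 = norm(4) * P64 * eip^4,
        m5 = norm(5) * P65 * eip^5,
        m6 = norm(6) * P66 * eip^6)
}

# full 13-component Y_{6,m}, m = -6..6 (columns in that order)
sph_harm6_full <- function(u) {
  Yp <- sph_harm6(u)
  Yn <- sapply(6:1, function(m) (-1)^m * Conj(Yp[, m + 1]))
  if (is.null(dim(Yn))) Yn <- matrix(Yn, nrow = 1)
  out <- cbind(Yn, Yp)
  colnames(out) <- paste0("m", -6:6)
  out
}

# q6 vectors for all water oxygens: N x 13 complex matrix (m = -6..6),
# plus the switching-weight sums. Neighbours are *all* water oxygens within
# r_cut under the configuration's minimum-image convention.
q6_all <- function(config, params = switching_params()) {
  wo <- water_oxygens(config)
  nw <- length(wo)
  Q <- matrix(0 + 0i, nw, 13)
  wsum <- numeric(nw)
  if (nw >= 2) {
    p <- pairs_within(config, params$r_cut, subset = wo)
    if (length(p$i)) {
      ii <- match(p$i, wo); jj <- match(p$j, wo)
      keep <- p$d > 1e-12
      ii <- ii[keep]; jj <- jj[keep]
      u <- cbind(p$dx, p$dy, p$dz)[keep, , drop = FALSE] / p$d[keep]
      w <- rational_switch(p$d[keep], params)
      Y <- sph_harm6_full(u)        # Y(-u) = Y(u) for even order 6
      idx <- c(ii, jj)
      wY <- rbind(Y * w, Y * w)
      for (m in 1:13) {
        re <- rowsum(Re(wY[, m]), idx)
        im <- rowsum(Im(wY[, m]), idx)
        rows <- as.integer(rownames(re))
        Q[rows, m] <- Q[rows, m] + complex(real = re, imaginary = im)
      }
      ws <- rowsum(c(w, w), idx)
      wsum[as.integer(rownames(ws))] <- ws
    }
  }
  ok <- wsum > 0
  Q[ok, ] <- Q[ok, , drop = FALSE] / wsum[ok]
  list(Q = Q, wsum = wsum, water_idx = wo)
}

#' Steinhardt q6 vector of one water molecule
#'
#' The 13 complex components (m = -6..6) of the switching-weighted,
#' neighbour-averaged 6th-order spherical-harmonic expansion of the
#' environment of water oxygen `i`.
#'
#' @param config an `ice_config`.
#' @param i atom index of a water oxygen.
#' @param params a [switching_params()].
#' @return complex vector of length 13, names `m-6 ... m6`.
#' @export
q6_vector <- function(config, i, params = switching_params()) {
  qa <- q6_all(config, params)
  k <- match(i, qa$water_idx)
  if (is.na(k)) stop("atom ", i, " is not a water oxygen")
  if (qa$wsum[k] <= 0)
    stop("no neighbours: molecule ", i, " has zero switching weight")
  setNames(qa$Q[k, ], paste0("m", -6:6))
}

# s6 for all waters; NA where a molecule has no neighbours
s6_all <- function(config, params = switching_params(), normalize = TRUE) {
  qa <- q6_all(config, params)
  wo <- qa$water_idx
  nw <- length(wo)
  Q <- qa$Q
  if (normalize) {
    nrm <- sqrt(Re(rowSums(Q * Conj(Q))))
    pos <- nrm > 0
    Q[pos, ] <- Q[pos, , drop = FALSE] / nrm[pos]
  }
  num <- numeric(nw)
  den <- numeric(nw)
  if (nw >= 2) {
    p <- pairs_within(config, params$r_cut, subset = wo)
    if (length(p$i)) {
      ii <- match(p$i, wo); jj <- match(p$j, wo)
      keep <- p$d > 1e-12
      ii <- ii[keep]; jj <- jj[keep]
      w <- rational_switch(p$d[keep], params)
      dot <- Re(rowSums(Conj(Q[ii, , drop = FALSE]) * Q[jj, , drop = FALSE]))
      idx <- c(ii, jj)
      nn <- rowsum(c(w * dot, w * dot), idx)
      dd <- rowsum(c(w, w), idx)
      num[as.integer(rownames(nn))] <- nn
      den[as.integer(rownames(dd))] <- dd
    }
  }
  s <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), NA_real_)
  list(s6 = s, water_idx = wo, wsum = qa$wsum)
}

#' Steinhardt s6 order parameter of one water molecule
#'
#' Switching-weighted neighbour average of the scalar products between the
#' q6 vector of molecule `i` and those of its neighbours. With
#' `normalize = TRUE` (default) each 13-vector is scaled to unit norm before
#' the product, so identical environments give exactly 1 and
#' `s6` is bounded by `[-1, 1]`.
#'
#' @inheritParams q6_vector
#' @param normalize scale q6 vectors to unit norm before the dot product.
#' @return dimensionless scalar.
#' @export
s6 <- function(config, i, params = switching_params(), normalize = TRUE) {
  sa <- s6_all(config, params, normalize)
  k <- match(i, sa$water_idx)
  if (is.na(k)) stop("atom ", i, " is not a water oxygen")
  if (is.na(sa$s6[k]))
    stop("no neighbours: molecule ", i, " has zero switching weight")
  sa$s6[k]
}

#' Classify water molecules as ice-like or liquid-like
#'
#' A molecule is flagged ice when its s6 value strictly exceeds `threshold`
#' (default 0.45). Molecules with no neighbours inside the switching range
#' are labelled liquid.
#'
#' @param config an `ice_config` containing water molecules.
#' @param params a [switching_params()].
#' @param threshold classification threshold on s6.
#' @param normalize see [s6()].
#' @return An object of class `ice_labels`: per-water s6 values, ice flags,
#'   cluster ids (filled by [largest_ice_cluster()]), the threshold used and
#'   the water atom indices.
#' @export
classify_ice <- function(config, params = switching_params(),
                         threshold = 0.45, normalize = TRUE) {
  wo <- water_oxygens(config)
  if (!length(wo)) stop("configuration contains no water molecules")
  sa <- s6_all(config, params, normalize)
  ice <- !is.na(sa$s6) & sa$s6 > threshold
  structure(list(s6 = sa$s6, ice = ice,
                 cluster = rep(NA_integer_, length(wo)),
                 largest_cluster_size = NA_integer_,
                 threshold = threshold, params = params,
                 normalize = normalize, water_idx = wo),
            class = "ice_labels")
}

#' @export
print.ice_labels <- function(x, ...) {
  cat(sprintf("<ice_labels> %d waters | %d ice (s6 > %g)%s\n",
              length(x$water_idx), sum(x$ice), x$threshold,
              if (!is.na(x$largest_cluster_size))
                sprintf(" | largest cluster %d", x$largest_cluster_size)
              else ""))
  invisible(x)
}

# union-find with path halving
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Largest connected ice cluster
#'
#' Connected components over the ice-flagged molecules, linking two
#' molecules when their O-O minimum-image distance is strictly below
#' `link_cutoff`. Cluster ids are assigned in order of each cluster's lowest
#' member index; ties for the largest cluster resolve to the lowest member
#' index.
#'
#' @param config an `ice_config`.
#' @param labels an `ice_labels` from [classify_ice()].
#' @param link_cutoff O-O connectivity cutoff (nm).
#' @return `labels` with `cluster` and `largest_cluster_size` filled.
#' @export
largest_ice_cluster <- function(config, labels, link_cutoff = 0.35) {
  stopifnot(inherits(labels, "ice_labels"))
  wo <- labels$water_idx
  ice_idx <- wo[labels$ice]
  labels$cluster <- rep(NA_integer_, length(wo))
  if (!length(ice_idx)) {
    labels$largest_cluster_size <- 0L
    return(labels)
  }
  parent <- seq_along(ice_idx)
  if (length(ice_idx) > 1) {
    p <- pairs_within(config, link_cutoff, subset = ice_idx)
    keep <- which(p$d < link_cutoff)   # strict inequality at the cutoff
    for (q in keep) {
      a <- uf_find(parent, match(p$i[q], ice_idx))
      b <- uf_find(parent, match(p$j[q], ice_idx))
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_along(ice_idx), function(i) uf_find(parent, i),
                 integer(1))
  ids <- match(root, sort(unique(root)))   # id by lowest member index
  labels$cluster[match(ice_idx, wo)] <- ids
  sizes <- tabulate(ids)
  labels$largest_cluster_size <- max(sizes)
  attr(labels, "largest_cluster_id") <- which.max(sizes)  # lowest index wins ties
  labels
}

# atom indices (water oxygens) of the largest cluster
largest_cluster_atoms <- function(labels) {
  id <- attr(labels, "largest_cluster_id")
  if (is.null(id) || is.na(labels$largest_cluster_size) ||
      labels$largest_cluster_size == 0L)
    return(integer(0))
  labels$water_idx[!is.na(labels$cluster) & labels$cluster == id]
}

#' Radial distribution function
#'
#' Standard pair-distance histogram between two role sets, normalized by the
#' ideal-gas shell count under the box periodicity.
#'
#' @param config an `ice_config`.
#' @param center_role,other_role role tags (see [configuration()]).
#' @param r_max maximum distance (nm); must not exceed half the smallest box
#'   length.
#' @param bin_width histogram bin width (nm).
#' @return data.frame with columns `r` (bin centres) and `g`.
#' @export
rdf <- function(config, center_role = "water_O", other_role = "water_O",
                r_max = 1.0, bin_width = 0.01) {
  ia <- which(config$role == center_role)
  ib <- which(config$role == other_role)
  if (!length(ia) || !length(ib)) stop("both role sets must be non-empty")
  if (r_max > min(config$box) / 2 + 1e-12)
    stop("r_max exceeds half the smallest box length (minimum image invalid)")
  same <- identical(center_role, other_role)
  if (same) {
    p <- pairs_within(config, r_max, subset = ia)
    d <- p$d
    npairs_per_shell <- function(vshell)
      length(ia) * (length(ia) - 1) / 2 * vshell / prod(config$box)
  } else {
    p <- cross_pairs_within(config, ia, ib, r_max)
    d <- p$d[p$d > 1e-12]
    npairs_per_shell <- function(vshell)
      length(ia) * length(ib) * vshell / prod(config$box)
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  d <- d[d < r_max]
  counts <- tabulate(findInterval(d, edges, left.open = TRUE),
                     nbins = length(edges) - 1)
  vshell <- 4 / 3 * pi * diff(edges^3)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  data.frame(r = mids, g = counts / npairs_per_shell(vshell))
}

#' Solvation-shell composition around methylene groups
#'
#' Counts, for every methylene carbon, the water molecules whose oxygen lies
#' strictly within `cutoff`, split into ice-like and liquid-like according
#' to the supplied labels.
#'
#' @param config an `ice_config` with methylene_C atoms and waters.
#' @param labels an `ice_labels`.
#' @param cutoff first-solvation-shell radius (nm), default 0.45.
#' @return An object of class `solvation_report`: data.frame with one row
#'   per methylene (`atom`, `n_total`, `n_ice`, `n_liquid`).
#' @export
solvation_shell <- function(config, labels, cutoff = 0.45) {
  me <- which(config$role == "methylene_C")
  if (!length(me)) stop("configuration contains no methylene_C atoms")
  wo <- labels$water_idx
  out <- data.frame(atom = me, n_total = 0L, n_ice = 0L, n_liquid = 0L)
  p <- cross_pairs_within(config, me, wo, cutoff)
  keep <- which(p$d < cutoff)    # strict inequality at the shell boundary
  if (length(keep)) {
    for (q in keep) {
      r <- p$i[q]
      out$n_total[r] <- out$n_total[r] + 1L
      if (labels$ice[p$j[q]]) out$n_ice[r] <- out$n_ice[r] + 1L
    }
    out$n_liquid <- out$n_total - out$n_ice
  }
  structure(out, class = c("solvation_report", "data.frame"), cutoff = cutoff)
}
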