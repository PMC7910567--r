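#' Ice-count growth curve
#'
#' Per-frame size of the largest connected ice cluster, with the binding
#' time t0 attached from [bound_fraction_series()] when a polymer topology
#' is supplied.
#'
#' @param traj an `ice_trajectory` (>= 2 frames).
#' @param params a [switching_params()].
#' @param threshold s6 ice threshold.
#' @param link_cutoff cluster connectivity cutoff (nm).
#' @param topology optional `polymer_topology` (to attach t0).
#' @param binding_threshold bound-hydroxyl fraction defining t0.
#' @return An object of class `growth_series`: data.frame with columns
#'   `time` (ps) and `n_ice`; attributes `t0` (ps or NA) and
#'   `binding_series`.
#' @export
growth_curve <- function(traj, params = switching_params(), threshold = 0.45,
                         link_cutoff = 0.35, topology = NULL,
                         binding_threshold = 0.20) {
  if (length(traj) < 2) stop("growth curve needs at least 2 frames")
  n_ice <- vapply(traj$frames, function(cfg) {
    labels <- largest_ice_cluster(cfg, classify_ice(cfg, params, threshold),
                                  link_cutoff)
    labels$largest_cluster_size
  }, integer(1))
  out <- data.frame(time = frame_times(traj), n_ice = n_ice)
  out <- structure(out, class = c("growth_series", "data.frame"))
  bs <- NULL
  t0 <- NA_real_
  if (!is.null(topology)) {
    bs <- bound_fraction_series(traj, topology, params, threshold,
                                link_cutoff,
                                binding_threshold = binding_threshold)
    t0 <- attr(bs, "t0")
  }
  attr(out, "t0") <- t0
  attr(out, "binding_series") <- bs
  out
}

#' Ice growth within a fixed window after binding
#'
#' Number of ice molecules grown within `window_ns` after the binding time:
#' `count(t0 + window) - count(t0)`, with linear interpolation between
#' frames at both endpoints.
#'
#' @param series a `growth_series`.
#' @param t0 binding time in ps; defaults to the series attribute.
#' @param window_ns window length in ns (default 100).
#' @return molecule count delta (numeric).
#' @export
growth_in_window <- function(series, t0 = attr(series, "t0"),
                             window_ns = 100) {
  if (is.null(t0) || is.na(t0)) stop("t0 is not set")
  if (window_ns < 0) stop("window must be >= 0")
  t1 <- t0 + window_ns * 1000
  tmax <- max(series$time)
  if (t0 < min(series$time) - 1e-9 || t1 > tmax + 1e-9)
    stop(sprintf("series does not cover [t0, t0 + %g ns]", window_ns))
  c0 <- approx(series$time, series$n_ice, xout = t0)$y
  c1 <- approx(series$time, series$n_ice, xout = min(t1, tmax))$y
  c1 - c0
}

#' Overgrowth / engulfment classification
#'
#' A polymer is `overgrown` when, in a sustained run of at least `persist`
#' frames, at least `embed_fraction` of its heavy atoms each have
#' `min_waters` or more largest-cluster water oxygens within `shell` nm;
#' `active` when a binding time exists but the polymer is never overgrown;
#' `unbound` otherwise. This numeric rule is this package's own
#' operationalization of engulfment (both knobs exposed).
#'
#' @param traj an `ice_trajectory` containing the polymer.
#' @param topology a `polymer_topology`.
#' @param params a [switching_params()].
#' @param threshold,link_cutoff classification settings.
#' @param embed_fraction fraction of embedded heavy atoms (default 0.9).
#' @param persist sustained frames required (default 5).
#' @param shell neighbour shell radius (nm, default 0.35).
#' @param min_waters cluster waters required per atom (default 4).
#' @param t0 optional binding time (ps); computed from
#'   [bound_fraction_series()] when missing.
#' @return factor level `"overgrown"`, `"active"` or `"unbound"`, with
#'   attribute `embedded_fraction` (per-frame values).
#' @export
classify_overgrowth <- function(traj, topology, params = switching_params(),
                                threshold = 0.45, link_cutoff = 0.35,
                                embed_fraction = 0.9, persist = 5L,
                                shell = 0.35, min_waters = 4L, t0 = NULL) {
  heavy <- topology_atoms(topology, "heavy")
  if (!length(heavy)) stop("polymer has no heavy atoms")
  if (is.null(t0)) {
    bs <- bound_fraction_series(traj, topology, params, threshold,
                                link_cutoff)
    t0 <- attr(bs, "t0")
  }
  emb <- vapply(traj$frames, function(cfg) {
    labels <- largest_ice_cluster(cfg, classify_ice(cfg, params, threshold),
                                  link_cutoff)
    ice_O <- largest_cluster_atoms(labels)
    if (!length(ice_O)) return(0)
    p <- cross_pairs_within(cfg, heavy, ice_O, shell)
    cnt <- tabulate(p$i[p$d < shell], nbins = length(heavy))
    mean(cnt >= min_waters)
  }, numeric(1))
  runs <- rle(emb >= embed_fraction)
  overgrown <- any(runs$values & runs$lengths >= persist)
  status <- if (overgrown) "overgrown" else if (!is.na(t0)) "active" else "unbound"
  structure(factor(status, levels = c("active", "overgrown", "unbound")),
            embedded_fraction = emb, t0 = t0)
}

#' Ice growth rate
#'
#' Centred finite difference of the moving-average-smoothed ice count over
#' time, in molecules per ns; one-sided differences at the edges.
#'
#' @param series a `growth_series`.
#' @param window odd smoothing window in frames (default 5).
#' @return numeric vector of rates (molecules/ns), same length as the series.
#' @export
growth_rate <- function(series, window = 5L) {
  if (nrow(series) < 3) stop("growth rate needs at least 3 frames")
  sm <- moving_average(series$n_ice, window)
  t <- series$time / 1000  # ps -> ns
  n <- length(sm)
  rate <- numeric(n)
  rate[1] <- (sm[2] - sm[1]) / (t[2] - t[1])
  rate[n] <- (sm[n] - sm[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    rate[i] <- (sm[i + 1] - sm[i - 1]) / (t[i + 1] - t[i - 1])
  }
  rate
}
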