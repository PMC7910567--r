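#' Geometric hydrogen-bond criterion
#'
#' A donor-hydrogen-acceptor triplet is a hydrogen bond when the
#' donor-acceptor minimum-image distance is strictly below
#' `max_da_distance` and the folded D-H-A angle is at least `min_angle`
#' degrees. (A printed window "160-200 degrees" folds to `>= 160` because a
#' three-point angle lies in `[0, 180]`.)
#'
#' @param max_da_distance donor-acceptor distance cutoff (nm), default 0.3.
#' @param min_angle minimal folded D-H-A angle (degrees), default 160.
#' @return An object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_da_distance = 0.3, min_angle = 160) {
  if (max_da_distance <= 0) stop("distance cutoff must be > 0")
  if (min_angle <= 0 || min_angle > 180)
    stop("folded angle window must lie in (0, 180]")
  structure(list(max_da_distance = max_da_distance, min_angle = min_angle),
            class = "hbond_criterion")
}

# default donor (D, H) table and acceptor list from roles + bond list.
# Protonated amine N is donor-only; hydroxyl and water O are both donors
# and acceptors.
default_donors <- function(config) {
  b <- config$bonds
  if (is.null(b)) stop("configuration carries no bond list; supply donors")
  r1 <- config$role[b[, 1]]; r2 <- config$role[b[, 2]]
  heavy_first <- r1 %in% c("water_O", "hydroxyl_O", "amine_N") &
    r2 %in% c("water_H", "hydroxyl_H", "amine_H")
  heavy_second <- r2 %in% c("water_O", "hydroxyl_O", "amine_N") &
    r1 %in% c("water_H", "hydroxyl_H", "amine_H")
  data.frame(donor = c(b[heavy_first, 1], b[heavy_second, 2]),
             hydrogen = c(b[heavy_first, 2], b[heavy_second, 1]))
}

default_acceptors <- function(config) {
  which(config$role %in% c("water_O", "hydroxyl_O"))
}

#' Detect hydrogen bonds
#'
#' All (donor, hydrogen, acceptor) triplets satisfying the geometric
#' criterion, with `donor != acceptor`. Duplicate (hydrogen, acceptor)
#' pairs are impossible by construction (one donor per hydrogen).
#'
#' @param config an `ice_config`.
#' @param donors data.frame with columns `donor`, `hydrogen` (atom indices);
#'   default derived from roles and the bond list.
#' @param acceptors integer atom indices; default water + hydroxyl oxygens.
#' @param criterion an [hbond_criterion()].
#' @return An object of class `hbond_set`: data.frame with columns `donor`,
#'   `hydrogen`, `acceptor`, `distance` (nm), `angle` (degrees).
#' @export
detect_hbonds <- function(config, donors = NULL, acceptors = NULL,
                          criterion = hbond_criterion()) {
  if (is.null(donors)) donors <- default_donors(config)
  if (is.null(acceptors)) acceptors <- default_acceptors(config)
  donors <- as.data.frame(donors)
  if (!all(c("donor", "hydrogen") %in% names(donors)))
    stop("donors must have columns 'donor' and 'hydrogen'")
  if (!nrow(donors) || !length(acceptors))
    return(empty_hbond_set(config$time))
  # sanity: every donor row needs a hydrogen
  if (any(is.na(donors$hydrogen)))
    stop("donor atoms without attached hydrogens in topology")
  p <- cross_pairs_within(config, donors$donor, acceptors,
                          criterion$max_da_distance)
  keep <- which(p$d < criterion$max_da_distance &
                  donors$donor[p$i] != acceptors[p$j])
  if (!length(keep)) return(empty_hbond_set(config$time))
  D <- donors$donor[p$i[keep]]
  H <- donors$hydrogen[p$i[keep]]
  A <- acceptors[p$j[keep]]
  hd <- min_image(config$positions[H, , drop = FALSE],
                  config$positions[D, , drop = FALSE],
                  config$box, config$pbc_mode)
  ha <- min_image(config$positions[H, , drop = FALSE],
                  config$positions[A, , drop = FALSE],
                  config$box, config$pbc_mode)
  cosang <- rowSums(hd * ha) /
    pmax(sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)), 1e-300)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ok <- ang >= criterion$min_angle
  out <- data.frame(donor = D[ok], hydrogen = H[ok], acceptor = A[ok],
                    distance = p$d[keep][ok], angle = ang[ok])
  out <- out[order(out$donor, out$hydrogen, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hbond_set", "data.frame"), time = config$time)
}

empty_hbond_set <- function(time = NA_real_) {
  structure(data.frame(donor = integer(0), hydrogen = integer(0),
                       acceptor = integer(0), distance = numeric(0),
                       angle = numeric(0)),
            class = c("hbond_set", "data.frame"), time = time)
}

#' Hydrogen bonds between a polymer and the ice surface
#'
#' Restriction of [detect_hbonds()] to triplets where one partner is a
#' polymer functional group (hydroxyl O-H, donor and acceptor; protonated
#' amine N-H, donor only) and the other a water molecule belonging to the
#' largest connected ice cluster. Both donor directions are considered.
#'
#' @param config an `ice_config`.
#' @param labels an `ice_labels` with cluster fields filled (see
#'   [largest_ice_cluster()]); if clusters are missing they are computed.
#' @param topology a `polymer_topology` (indices valid in `config`).
#' @param criterion an [hbond_criterion()].
#' @return An `hbond_set` with an extra column `group` (`"hydroxyl"` /
#'   `"amine"`) and attribute `hydroxyl_atoms` of the bonded hydroxyl Os.
#' @export
polymer_ice_bonds <- function(config, labels, topology,
                              criterion = hbond_criterion()) {
  if (is.na(labels$largest_cluster_size))
    labels <- largest_ice_cluster(config, labels)
  ice_O <- largest_cluster_atoms(labels)
  oh_O <- topology_atoms(topology, "hydroxyl_O")
  oh_H <- topology_atoms(topology, "hydroxyl_H")
  am_N <- topology_atoms(topology, "amine_N")
  am_H <- topology_atoms(topology, "amine_H")
  if (!length(ice_O) || (!length(oh_O) && !length(am_N)))
    return(empty_hbond_set(config$time))
  ice_H <- integer(0)
  if (!is.null(config$bonds)) {
    b <- config$bonds
    sel <- b[, 1] %in% ice_O & config$role[b[, 2]] == "water_H"
    ice_H <- b[sel, 2]
    ice_HD <- b[sel, 1]
  }
  # polymer donors -> ice acceptors
  pd <- data.frame(
    donor = c(oh_O, rep(am_N, each = 3)[seq_along(am_H)]),
    hydrogen = c(oh_H, am_H))
  b1 <- detect_hbonds(config, pd, ice_O, criterion)
  # ice water donors -> polymer hydroxyl acceptors (amine N accepts nothing)
  b2 <- if (length(ice_H) && length(oh_O)) {
    detect_hbonds(config, data.frame(donor = ice_HD, hydrogen = ice_H),
                  oh_O, criterion)
  } else empty_hbond_set(config$time)
  out <- rbind(as.data.frame(b1), as.data.frame(b2))
  grp <- ifelse(out$donor %in% am_N, "amine",
                ifelse(out$donor %in% oh_O | out$acceptor %in% oh_O,
                       "hydroxyl", "hydroxyl"))
  out$group <- grp
  bonded_oh <- unique(c(out$donor[out$donor %in% oh_O],
                        out$acceptor[out$acceptor %in% oh_O]))
  structure(out, class = c("hbond_set", "data.frame"), time = config$time,
            hydroxyl_atoms = bonded_oh)
}

#' Bound-functional-group fraction over a trajectory
#'
#' For every frame: classify ice, find the largest cluster, detect
#' polymer-ice hydrogen bonds, and report the fraction of distinct hydroxyl
#' groups with at least one bond to the ice cluster (a hydroxyl with two
#' simultaneous bonds counts once). Amine groups are tracked in parallel for
#' copolymers.
#'
#' @param traj an `ice_trajectory`.
#' @param topology a `polymer_topology`.
#' @param params a [switching_params()].
#' @param threshold s6 ice threshold.
#' @param link_cutoff cluster connectivity cutoff (nm).
#' @param criterion an [hbond_criterion()].
#' @param binding_threshold bound-hydroxyl fraction defining the binding
#'   time t0 (default 0.20).
#' @return An object of class `binding_series`: data.frame with columns
#'   `time`, `frac_OH`, `frac_NH3`, `n_bonds_OH`, `n_bonds_NH3`; attribute
#'   `t0` (ps or `NA`).
#' @export
bound_fraction_series <- function(traj, topology,
                                  params = switching_params(),
                                  threshold = 0.45, link_cutoff = 0.35,
                                  criterion = hbond_criterion(),
                                  binding_threshold = 0.20) {
  n_oh <- length(topology_atoms(topology, "hydroxyl_O"))
  n_am <- length(topology_atoms(topology, "amine_N"))
  if (n_oh + n_am == 0)
    stop("topology has neither hydroxyl nor amine groups")
  rows <- lapply(traj$frames, function(cfg) {
    labels <- largest_ice_cluster(
      cfg, classify_ice(cfg, params, threshold), link_cutoff)
    hb <- polymer_ice_bonds(cfg, labels, topology, criterion)
    oh_atoms <- attr(hb, "hydroxyl_atoms")
    am_bonded <- unique(hb$donor[hb$group == "amine"])
    data.frame(time = cfg$time,
               frac_OH = if (n_oh) length(oh_atoms) / n_oh else NA_real_,
               frac_NH3 = if (n_am) length(am_bonded) / n_am else NA_real_,
               n_bonds_OH = sum(hb$group == "hydroxyl"),
               n_bonds_NH3 = sum(hb$group == "amine"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- structure(out, class = c("binding_series", "data.frame"))
  attr(out, "t0") <- binding_time(out, binding_threshold)
  out
}

#' Binding time t0
#'
#' First time at which the instantaneous bound-hydroxyl fraction reaches
#' `threshold` (default 20 percent). No smoothing is applied.
#'
#' @param series a `binding_series`, or a data.frame with columns `time` and
#'   `frac_OH`.
#' @param threshold bound fraction defining binding.
#' @return time (ps), or `NA` if the threshold is never reached.
#' @export
binding_time <- function(series, threshold = 0.20) {
  if (!nrow(series)) stop("series must be non-empty")
  hit <- which(series$frac_OH >= threshold)
  if (!length(hit)) NA_real_ else series$time[hit[1]]
}

#' Centred moving average with shrinking edges
#'
#' Boxcar mean over an odd window; near the edges the window shrinks to the
#' available samples, so the output has the same length as the input.
#'
#' @param x numeric vector.
#' @param window odd integer window length (frames).
#' @return numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  n <- length(x)
  half <- (window - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Distribution of per-frame polymer-ice hydrogen-bond counts
#'
#' Normalized frequency of the number of hydrogen bonds formed per frame
#' between the chosen functional-group family and the largest ice cluster.
#'
#' @param traj an `ice_trajectory`.
#' @param topology a `polymer_topology`.
#' @param group `"hydroxyl"` or `"amine"`.
#' @param ... passed to [bound_fraction_series()].
#' @return data.frame with columns `count` and `prob` (sums to 1).
#' @export
hbond_count_distribution <- function(traj, topology,
                                     group = c("hydroxyl", "amine"), ...) {
  group <- match.arg(group)
  series <- bound_fraction_series(traj, topology, ...)
  counts <- if (group == "hydroxyl") series$n_bonds_OH else series$n_bonds_NH3
  tab <- table(counts)
  data.frame(count = as.integer(names(tab)),
             prob = as.numeric(tab) / length(counts))
}
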