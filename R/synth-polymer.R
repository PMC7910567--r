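#' Vinyl polymer topology
#'
#' Book-keeping for a poly(vinyl alcohol) / poly(vinyl amine) chain: the
#' ordered monomer types, the atom-index map for each monomer (one methylene
#' CH2 carbon, one backbone CH carbon, and either a hydroxyl O-H pair for VA
#' or an N plus three H for protonated VAm), and the covalent bond list.
#'
#' @param monomer_types character vector of `"VA"` / `"VAm"`, length = DP.
#' @param monomers list of per-monomer atom index lists.
#' @param bonds integer 2-column bond matrix.
#' @param atom_offset index of the polymer's first atom in the configuration.
#' @param n_atoms total number of polymer atoms.
#' @return An object of class `polymer_topology`.
#' @export
polymer_topology <- function(monomer_types, monomers, bonds,
                             atom_offset = 1L, n_atoms) {
  dp <- length(monomer_types)
  if (length(monomers) != dp) stop("one atom map per monomer required")
  if (!all(monomer_types %in% c("VA", "VAm")))
    stop("monomer types must be 'VA' or 'VAm'")
  for (k in seq_len(dp)) {
    m <- monomers[[k]]
    if (monomer_types[k] == "VA") {
      if (length(m$hydroxyl_O) != 1L || length(m$hydroxyl_H) != 1L)
        stop("VA monomer ", k, " must own exactly one hydroxyl_O and one hydroxyl_H")
    } else {
      if (length(m$amine_N) != 1L || length(m$amine_H) != 3L)
        stop("VAm monomer ", k, " must own one amine_N and three amine_H")
    }
  }
  structure(list(monomer_types = monomer_types, monomers = monomers,
                 bonds = bonds, atom_offset = as.integer(atom_offset),
                 n_atoms = as.integer(n_atoms), dp = dp),
            class = "polymer_topology")
}

#' @export
print.polymer_topology <- function(x, ...) {
  cat(sprintf("<polymer_topology> DP = %d (%d VA, %d VAm), %d atoms\n",
              x$dp, sum(x$monomer_types == "VA"),
              sum(x$monomer_types == "VAm"), x$n_atoms))
  invisible(x)
}

topology_atoms <- function(topo, what = c("all", "heavy", "hydroxyl_O",
                                          "hydroxyl_H", "amine_N", "amine_H",
                                          "methylene_C", "backbone_C")) {
  what <- match.arg(what)
  get1 <- function(field) unlist(lapply(topo$monomers, `[[`, field))
  out <- switch(what,
    all = sort(unlist(lapply(topo$monomers, unlist))),
    heavy = sort(c(get1("backbone_C"), get1("methylene_C"),
                   get1("hydroxyl_O"), get1("amine_N"))),
    get1(what))
  as.integer(out[!is.na(out)])
}

#' Build a PVA / PVAm / block-copolymer chain
#'
#' Generates a self-avoiding backbone walk (C-C bond 0.154 nm, tetrahedral
#' angles) with two backbone carbons per monomer, decorated with the monomer
#' functional groups: hydroxyl O-H for vinyl alcohol, protonated amine N-H3
#' for vinyl amine. Conformations: `"coil"` samples trans/gauche dihedrals,
#' `"extended"` is all-trans, `"compact"` biases each step toward the current
#' centroid. If `target_Rg` is given, coordinates are affinely rescaled about
#' the mass-weighted centre so the radius of gyration matches exactly
#' (rejected if the required compression drops interatomic distances below a
#' steric floor of 0.05 nm).
#'
#' @param block_layout character vector of monomer types in chain order,
#'   e.g. `rep("VA", 20)` or `c(rep("VA", 5), rep("VAm", 5))`.
#' @param conformation `"coil"`, `"compact"` or `"extended"`.
#' @param target_Rg target radius of gyration in nm, or `NULL`.
#' @param seed integer RNG seed.
#' @param box optional box lengths; default is the chain bounding box plus
#'   2 nm padding.
#' @return list with elements `config` (an `ice_config`) and `topology`
#'   (a `polymer_topology`).
#' @export
build_polymer <- function(block_layout,
                          conformation = c("coil", "compact", "extended"),
                          target_Rg = NULL, seed = 1L, box = NULL) {
  conformation <- match.arg(conformation)
  block_layout <- as.character(block_layout)
  dp <- length(block_layout)
  if (dp < 2) stop("degree of polymerisation must be >= 2")
  if (!all(block_layout %in% c("VA", "VAm")))
    stop("block_layout entries must be 'VA' or 'VAm'")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  nC <- 2L * dp
  bb <- backbone_walk(nC, conformation)

  pos <- list(); species <- list(); role <- list()
  bonds <- list()
  monomers <- vector("list", dp)
  idx <- 0L
  prev_backbone <- NA_integer_
  for (k in seq_len(dp)) {
    cm <- bb[2L * k - 1L, ]   # methylene CH2 carbon
    cb <- bb[2L * k, ]        # substituted CH carbon
    im <- idx + 1L; ib <- idx + 2L
    pos[[length(pos) + 1L]] <- rbind(cm, cb)
    species[[length(species) + 1L]] <- c("C", "C")
    role[[length(role) + 1L]] <- c("methylene_C", "backbone_C")
    bonds[[length(bonds) + 1L]] <- rbind(c(im, ib))
    if (!is.na(prev_backbone))
      bonds[[length(bonds) + 1L]] <- rbind(c(prev_backbone, im))
    prev_backbone <- ib
    # substituent direction: away from the local backbone axis
    axis <- bb[min(2L * k + 1L, nC), ] - bb[max(2L * k - 2L, 1L), ]
    axis <- axis / max(sqrt(sum(axis^2)), 1e-12)
    side <- perp_at_angle(axis, 90) * (if (k %% 2L) 1 else -1)
    idx <- idx + 2L
    if (block_layout[k] == "VA") {
      o <- cb + 0.143 * side
      h <- o + 0.096 * perp_at_angle(side, 70)
      pos[[length(pos) + 1L]] <- rbind(o, h)
      species[[length(species) + 1L]] <- c("O", "H")
      role[[length(role) + 1L]] <- c("hydroxyl_O", "hydroxyl_H")
      bonds[[length(bonds) + 1L]] <- rbind(c(ib, idx + 1L),
                                           c(idx + 1L, idx + 2L))
      monomers[[k]] <- list(methylene_C = im, backbone_C = ib,
                            hydroxyl_O = idx + 1L, hydroxyl_H = idx + 2L)
      idx <- idx + 2L
    } else {
      nn <- cb + 0.147 * side
      hs <- t(vapply(1:3, function(q) nn + 0.101 * perp_at_angle(side, 68),
                     numeric(3)))
      pos[[length(pos) + 1L]] <- rbind(nn, hs)
      species[[length(species) + 1L]] <- c("N", "H", "H", "H")
      role[[length(role) + 1L]] <- c("amine_N", rep("amine_H", 3))
      bonds[[length(bonds) + 1L]] <- rbind(c(ib, idx + 1L),
                                           c(idx + 1L, idx + 2L),
                                           c(idx + 1L, idx + 3L),
                                           c(idx + 1L, idx + 4L))
      monomers[[k]] <- list(methylene_C = im, backbone_C = ib,
                            amine_N = idx + 1L,
                            amine_H = idx + 1L + 1:3)
      idx <- idx + 4L
    }
  }
  pos <- do.call(rbind, pos)
  species <- unlist(species)
  role <- unlist(role)
  bonds <- do.call(rbind, bonds)
  storage.mode(bonds) <- "integer"

  masses <- ATOMIC_MASSES[species]
  if (!is.null(target_Rg)) {
    com <- colSums(pos * masses) / sum(masses)
    rg0 <- sqrt(sum(masses * rowSums(sweep(pos, 2, com)^2)) / sum(masses))
    s <- target_Rg / rg0
    cand <- sweep(sweep(pos, 2, com) * s, 2, com, "+")
    dmin <- min(stats::dist(cand))
    if (dmin < 0.05)
      stop("target_Rg unachievable: required compression drops minimum ",
           sprintf("interatomic distance to %.3f nm (< 0.05 nm steric floor)",
                   dmin))
    pos <- cand
  }

  pad <- 2
  if (is.null(box)) {
    ext <- apply(pos, 2, range)
    box <- ext[2, ] - ext[1, ] + 2 * pad
    pos <- sweep(pos, 2, ext[1, ] - pad)
  }
  cfg <- configuration(pos, species, role, box, "xyz", bonds = bonds)
  topo <- polymer_topology(block_layout, monomers, bonds,
                           atom_offset = 1L, n_atoms = nrow(pos))
  list(config = cfg, topology = topo)
}

# self-avoiding backbone walk with fixed bond length / angle
backbone_walk <- function(n, conformation, bond = 0.154, angle_deg = 111,
                          min_sep = 0.20, max_restart = 200) {
  th <- (180 - angle_deg) * pi / 180
  for (attempt in seq_len(max_restart)) {
    P <- matrix(0, n, 3)
    P[2, ] <- c(bond, 0, 0)
    ok <- TRUE
    for (k in 3:n) {
      prev <- P[k - 1, ] - P[k - 2, ]
      prev <- prev / sqrt(sum(prev^2))
      phis <- switch(conformation,
                     extended = 0,
                     coil = sample(c(0, 2 * pi / 3, -2 * pi / 3), 3),
                     compact = runif(8, -pi, pi))
      placed <- FALSE
      best <- NULL; bestscore <- Inf
      for (phi in phis) {
        step <- rotate_step(prev, th, phi)
        cand <- P[k - 1, ] + bond * step
        d2 <- rowSums(sweep(P[seq_len(k - 3), , drop = FALSE], 2, cand)^2)
        if (length(d2) && min(d2) < min_sep^2) next
        score <- switch(conformation,
                        compact = sum((cand - colMeans(P[seq_len(k - 1), , drop = FALSE]))^2),
                        extended = 0,
                        coil = runif(1))
        if (score < bestscore) { bestscore <- score; best <- cand }
        placed <- TRUE
        if (conformation != "compact") break
      }
      if (!placed) { ok <- FALSE; break }
      P[k, ] <- best
    }
    if (ok) return(P)
  }
  stop("self-avoiding backbone walk failed; chain too long for constraints")
}

# unit step at polar angle `th` from direction `prev`, dihedral phi
rotate_step <- function(prev, th, phi) {
  ref <- if (abs(prev[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * prev) * prev
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(prev[2] * e1[3] - prev[3] * e1[2],
          prev[3] * e1[1] - prev[1] * e1[3],
          prev[1] * e1[2] - prev[2] * e1[1])
  cos(th) * prev + sin(th) * (cos(phi) * e1 + sin(phi) * e2)
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of a set of atoms from their
#' centre of mass.
#'
#' @param config an `ice_config`.
#' @param atom_subset integer atom indices (default: all atoms).
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(config, atom_subset = NULL) {
  if (is.null(atom_subset)) atom_subset <- seq_len(n_atoms(config))
  if (!length(atom_subset)) stop("atom subset must be non-empty")
  pos <- config$positions[atom_subset, , drop = FALSE]
  m <- atom_masses(config)[atom_subset]
  com <- colSums(pos * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(pos, 2, com)^2)) / sum(m))
}
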