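# Structure file IO. Role labels ride on residue/atom-name conventions:
#   water      -> residue SOL, atoms OW / HW1 HW2
#   VA monomer -> residue PVA, atoms C1 (backbone CH), C2 (methylene),
#                 OH / HO (hydroxyl)
#   VAm        -> residue PVM, atoms C1, C2, N1 / HN1 HN2 HN3 (amine)
#   generic    -> residue MOL, atom X1
# Extended XYZ carries species and role verbatim plus the box in a
# Lattice="..." comment, so it is lossless; GRO/PDB round-trip through the
# dialect above.

role_to_names <- function(role) {
  res <- character(length(role))
  atm <- character(length(role))
  res[role %in% c("water_O", "water_H")] <- "SOL"
  res[role %in% c("hydroxyl_O", "hydroxyl_H")] <- "PVA"
  res[role %in% c("amine_N", "amine_H")] <- "PVM"
  res[role %in% c("methylene_C", "backbone_C")] <- "PVA"
  res[role == "generic"] <- "MOL"
  atm[role == "water_O"] <- "OW"
  atm[role == "water_H"] <- "HW"
  atm[role == "hydroxyl_O"] <- "OH"
  atm[role == "hydroxyl_H"] <- "HO"
  atm[role == "amine_N"] <- "N1"
  atm[role == "amine_H"] <- "HN"
  atm[role == "methylene_C"] <- "C2"
  atm[role == "backbone_C"] <- "C1"
  atm[role == "generic"] <- "X1"
  list(res = res, atm = atm)
}

names_to_role <- function(resname, atomname) {
  key <- toupper(sub("[0-9]+$", "", trimws(atomname)))
  role <- rep(NA_character_, length(key))
  role[key == "OW"] <- "water_O"
  role[key == "HW"] <- "water_H"
  role[key == "OH"] <- "hydroxyl_O"
  role[key == "HO"] <- "hydroxyl_H"
  role[key == "N"] <- "amine_N"
  role[key == "HN"] <- "amine_H"
  role[key == "C" & sub("[A-Z]+", "", trimws(atomname)) == "2"] <- "methylene_C"
  role[key == "C" & sub("[A-Z]+", "", trimws(atomname)) == "1"] <- "backbone_C"
  role[key == "X"] <- "generic"
  if (any(is.na(role))) {
    off <- unique(trimws(atomname[is.na(role)]))
    stop("unknown role for atom name(s): ", paste(off, collapse = ", "))
  }
  role
}

role_to_species <- function(role) {
  c(water_O = "O", water_H = "H", hydroxyl_O = "O", hydroxyl_H = "H",
    amine_N = "N", amine_H = "H", methylene_C = "C", backbone_C = "C",
    generic = "C")[role]
}

# reconstruct covalent O-H / N-H bonds by proximity when a file cannot
# carry an explicit bond list
infer_bonds <- function(pos, role, box, pbc_mode) {
  heavy <- which(role %in% c("water_O", "hydroxyl_O", "amine_N"))
  hyd <- which(role %in% c("water_H", "hydroxyl_H", "amine_H"))
  if (!length(heavy) || !length(hyd)) return(NULL)
  p <- .cross_pairs_within_cpp(pos[hyd, , drop = FALSE],
                               pos[heavy, , drop = FALSE],
                               box, identical(pbc_mode, "xyz"), 0.125)
  if (!length(p$i)) return(NULL)
  # each hydrogen bonds to its nearest heavy atom
  ord <- order(p$d)
  sel <- ord[!duplicated(p$i[ord])]
  cbind(heavy[p$j[sel]], hyd[p$i[sel]])
}

#' Read a molecular structure file
#'
#' @param path file path.
#' @param format `"GRO"`, `"PDB"` or `"XYZ"`; default guessed from the file
#'   extension.
#' @return An `ice_config`.
#' @export
read_structure <- function(path, format = c("auto", "GRO", "PDB", "XYZ")) {
  format <- match.arg(toupper(format[1]), c("AUTO", "GRO", "PDB", "XYZ"))
  if (format == "AUTO")
    format <- toupper(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines))))
    stop("empty structure file: ", path)
  switch(format,
         GRO = parse_gro(lines, path),
         PDB = parse_pdb(lines, path),
         XYZ = parse_xyz(lines, path),
         stop("unknown structure format: ", format))
}

#' Write a molecular structure file
#'
#' @param config an `ice_config`.
#' @param path output path.
#' @param format `"GRO"`, `"PDB"` or `"XYZ"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(config, path, format = c("GRO", "PDB", "XYZ")) {
  format <- match.arg(toupper(format[1]), c("GRO", "PDB", "XYZ"))
  lines <- switch(format,
                  GRO = format_gro(config),
                  PDB = format_pdb(config),
                  XYZ = format_xyz(config))
  writeLines(lines, path)
  invisible(path)
}

residue_numbers <- function(role) {
  # new residue at each water oxygen / monomer backbone start
  starts <- role %in% c("water_O") |
    (role == "methylene_C") | (role == "generic")
  cumsum(ifelse(starts, 1L, 0L)) + ifelse(cumsum(starts) == 0, 1L, 0L)
}

format_gro <- function(config) {
  n <- n_atoms(config)
  nm <- role_to_names(config$role)
  resnum <- residue_numbers(config$role)
  title <- sprintf("icebindr t= %.4f pbc= %s",
                   ifelse(is.finite(config$time), config$time, 0),
                   config$pbc_mode)
  # GRO atom names carry a within-residue hydrogen index (HW1/HW2, HN1..)
  atm <- nm$atm
  hsel <- atm %in% c("HW", "HN")
  if (any(hsel)) {
    idx <- stats::ave(seq_len(n), resnum, atm, FUN = seq_along)
    atm[hsel] <- paste0(atm[hsel], idx[hsel])
  }
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  resnum %% 100000L, nm$res, atm, seq_len(n) %% 100000L,
                  config$positions[, 1], config$positions[, 2],
                  config$positions[, 3])
  c(title, sprintf("%5d", n), body,
    sprintf("%10.5f%10.5f%10.5f", config$box[1], config$box[2], config$box[3]))
}

parse_gro <- function(lines, path) {
  if (length(lines) < 3) stop("malformed GRO file (", path, "): too short")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO file (", path, "): bad atom count, line 2")
  if (length(lines) < 2 + n + 1)
    stop("malformed GRO file (", path, "): expected ", n, " atom records")
  tm <- regmatches(lines[1], regexec("t= *([0-9.eE+-]+)", lines[1]))[[1]]
  time <- if (length(tm) == 2) as.numeric(tm[2]) else NA_real_
  pm <- regmatches(lines[1], regexec("pbc= *(xyz|xy)", lines[1]))[[1]]
  pbc <- if (length(pm) == 2) pm[2] else "xyz"
  rec <- lines[2 + seq_len(n)]
  resname <- trimws(substr(rec, 6, 10))
  atomname <- trimws(substr(rec, 11, 15))
  xyz <- matrix(NA_real_, n, 3)
  for (k in 1:3) {
    fld <- substr(rec, 21 + 8 * (k - 1), 28 + 8 * (k - 1))
    xyz[, k] <- suppressWarnings(as.numeric(fld))
  }
  bad <- which(!stats::complete.cases(xyz))
  if (length(bad))
    stop("malformed GRO file (", path, "): bad coordinates at line ",
         2 + bad[1])
  boxline <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]),
                                                  "\\s+")[[1]]))
  if (length(boxline) < 3 || any(is.na(boxline[1:3])))
    stop("malformed GRO file (", path, "): bad box line ", 3 + n)
  role <- names_to_role(resname, atomname)
  pos <- xyz
  if (identical(pbc, "xy")) pos[, 3] <- pmin(pmax(pos[, 3], 0), boxline[3])
  configuration(pos, role_to_species(role), role, boxline[1:3], pbc,
                time = time,
                bonds = infer_bonds(pos, role, boxline[1:3], pbc))
}

format_pdb <- function(config) {
  n <- n_atoms(config)
  nm <- role_to_names(config$role)
  resnum <- residue_numbers(config$role)
  atm <- nm$atm
  hsel <- atm %in% c("HW", "HN")
  if (any(hsel)) {
    idx <- stats::ave(seq_len(n), resnum, atm, FUN = seq_along)
    atm[hsel] <- paste0(atm[hsel], idx[hsel])
  }
  # PDB is in Angstrom
  c(sprintf("REMARK   icebindr t= %.4f pbc= %s",
            ifelse(is.finite(config$time), config$time, 0), config$pbc_mode),
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            config$box[1] * 10, config$box[2] * 10, config$box[3] * 10,
            90, 90, 90),
    sprintf("ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            seq_len(n) %% 100000L, atm, nm$res, resnum %% 10000L,
            config$positions[, 1] * 10, config$positions[, 2] * 10,
            config$positions[, 3] * 10, config$species),
    "END")
}

parse_pdb <- function(lines, path) {
  cryst <- grep("^CRYST1", lines)
  if (!length(cryst))
    stop("malformed PDB file (", path, "): missing CRYST1 record")
  cl <- lines[cryst[1]]
  box <- c(as.numeric(substr(cl, 7, 15)), as.numeric(substr(cl, 16, 24)),
           as.numeric(substr(cl, 25, 33))) / 10
  if (any(is.na(box)))
    stop("malformed PDB file (", path, "): bad CRYST1 at line ", cryst[1])
  at <- grep("^(ATOM  |HETATM)", lines)
  if (!length(at)) stop("malformed PDB file (", path, "): no ATOM records")
  rec <- lines[at]
  atomname <- trimws(substr(rec, 13, 16))
  resname <- trimws(substr(rec, 18, 21))
  xyz <- cbind(as.numeric(substr(rec, 31, 38)),
               as.numeric(substr(rec, 39, 46)),
               as.numeric(substr(rec, 47, 54))) / 10
  bad <- which(!stats::complete.cases(xyz))
  if (length(bad))
    stop("malformed PDB file (", path, "): bad coordinates at line ",
         at[bad[1]])
  tm <- regmatches(lines[1], regexec("t= *([0-9.eE+-]+)", lines[1]))[[1]]
  time <- if (length(tm) == 2) as.numeric(tm[2]) else NA_real_
  pm <- regmatches(lines[1], regexec("pbc= *(xyz|xy)", lines[1]))[[1]]
  pbc <- if (length(pm) == 2) pm[2] else "xyz"
  role <- names_to_role(resname, atomname)
  if (identical(pbc, "xy")) xyz[, 3] <- pmin(pmax(xyz[, 3], 0), box[3])
  configuration(xyz, role_to_species(role), role, box, pbc, time = time,
                bonds = infer_bonds(xyz, role, box, pbc))
}

format_xyz <- function(config) {
  n <- n_atoms(config)
  lat <- sprintf('Lattice="%.8f 0 0 0 %.8f 0 0 0 %.8f"',
                 config$box[1], config$box[2], config$box[3])
  comment <- sprintf(
    '%s Properties=species:S:1:pos:R:3:role:S:1 Time=%.6f pbc="%s"',
    lat, ifelse(is.finite(config$time), config$time, 0), config$pbc_mode)
  c(sprintf("%d", n), comment,
    sprintf("%-2s %14.8f %14.8f %14.8f %s", config$species,
            config$positions[, 1], config$positions[, 2],
            config$positions[, 3], config$role))
}

parse_xyz <- function(lines, path, offset = 0L) {
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ file (", path, "): bad atom count, line ",
                     offset + 1)
  if (length(lines) < 2 + n)
    stop("malformed XYZ file (", path, "): expected ", n,
         " atom records from line ", offset + 3)
  lm <- regmatches(lines[2],
                   regexec('Lattice="([0-9.eE+ -]+)"', lines[2]))[[1]]
  if (length(lm) != 2)
    stop("malformed XYZ file (", path, "): missing Lattice, line ",
         offset + 2)
  latv <- as.numeric(strsplit(trimws(lm[2]), "\\s+")[[1]])
  box <- latv[c(1, 5, 9)]
  tm <- regmatches(lines[2], regexec("Time=([0-9.eE+-]+)", lines[2]))[[1]]
  time <- if (length(tm) == 2) as.numeric(tm[2]) else NA_real_
  pm <- regmatches(lines[2], regexec('pbc="(xyz|xy)"', lines[2]))[[1]]
  pbc <- if (length(pm) == 2) pm[2] else "xyz"
  toks <- strsplit(trimws(lines[2 + seq_len(n)]), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 5))
    stop("malformed XYZ file (", path, "): bad atom record at line ",
         offset + 2 + which(nt < 5)[1])
  species <- vapply(toks, `[[`, character(1), 1)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  role <- vapply(toks, `[[`, character(1), 5)
  bad <- which(!stats::complete.cases(xyz))
  if (length(bad))
    stop("malformed XYZ file (", path, "): bad coordinates at line ",
         offset + 2 + bad[1])
  configuration(xyz, species, role, box, pbc, time = time,
                bonds = infer_bonds(xyz, role, box, pbc))
}

#' Read / write multi-frame trajectories
#'
#' Trajectories are stored as concatenated single-frame records (XYZ or GRO).
#'
#' @param path file path.
#' @param format `"XYZ"` or `"GRO"`.
#' @return An `ice_trajectory`.
#' @export
read_trajectory <- function(path, format = c("auto", "XYZ", "GRO")) {
  format <- match.arg(toupper(format[1]), c("AUTO", "XYZ", "GRO"))
  if (format == "AUTO") format <- toupper(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  at <- 0L
  if (format == "XYZ") {
    while (at < length(lines)) {
      n <- suppressWarnings(as.integer(trimws(lines[at + 1])))
      if (is.na(n)) stop("malformed XYZ trajectory (", path, ") at line ", at + 1)
      frames[[length(frames) + 1L]] <-
        parse_xyz(lines[at + seq_len(n + 2)], path, offset = at)
      at <- at + n + 2L
    }
  } else if (format == "GRO") {
    while (at < length(lines)) {
      n <- suppressWarnings(as.integer(trimws(lines[at + 2])))
      if (is.na(n)) stop("malformed GRO trajectory (", path, ") at line ", at + 2)
      frames[[length(frames) + 1L]] <- parse_gro(lines[at + seq_len(n + 3)], path)
      at <- at + n + 3L
    }
  } else stop("unknown trajectory format: ", format)
  trajectory(frames)
}

#' @rdname read_trajectory
#' @param traj an `ice_trajectory`.
#' @export
write_trajectory <- function(traj, path, format = c("XYZ", "GRO")) {
  format <- match.arg(toupper(format[1]), c("XYZ", "GRO"))
  lines <- unlist(lapply(traj$frames, function(f)
    if (format == "XYZ") format_xyz(f) else format_gro(f)))
  writeLines(lines, path)
  invisible(path)
}
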