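#' Parse a deposited-Gaussians ("hills") log
#'
#' Whitespace-separated text with columns `time`, `center`, `sigma`,
#' `height`, `biasf` (the standard metadynamics hills dialect; a header line
#' `#! FIELDS time rg sigma_rg height biasf` names the collective variable).
#' Lines starting with `#` are treated as comments.
#'
#' @param path file path.
#' @return An object of class `hills_log`: data.frame with columns `time`
#'   (ps), `center` (nm), `sigma` (nm), `height` (kJ/mol); attributes
#'   `gamma` (bias factor) and `cv` (collective-variable name).
#' @export
parse_hills <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cv <- "cv"
  hdr <- grep("^#! *FIELDS", lines, value = TRUE)
  if (length(hdr)) {
    toks <- strsplit(trimws(hdr[1]), "\\s+")[[1]]
    if (length(toks) >= 4) cv <- toks[4]
  }
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  rec <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    ln <- body_idx[k]
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[ln]), "\\s+")[[1]]))
    if (length(v) < 5 || any(is.na(v[1:5])))
      stop("malformed hills record at line ", ln, " of ", path,
           ": need numeric columns time center sigma height biasf")
    if (v[3] <= 0)
      stop("non-positive Gaussian width at line ", ln, " of ", path)
    if (v[4] < 0)
      stop("negative Gaussian height at line ", ln, " of ", path)
    rec[[k]] <- v[1:5]
  }
  m <- if (length(rec)) do.call(rbind, rec) else matrix(numeric(0), 0, 5)
  if (nrow(m) > 1 && any(diff(m[, 1]) < 0))
    stop("hill deposition times must be non-decreasing in ", path)
  gamma <- if (nrow(m)) m[1, 5] else NA_real_
  if (nrow(m) && gamma <= 1)
    stop("bias factor must exceed 1 (got ", gamma, ")")
  out <- data.frame(time = m[, 1], center = m[, 2], sigma = m[, 3],
                    height = m[, 4])
  structure(out, class = c("hills_log", "data.frame"), gamma = gamma, cv = cv)
}

#' Construct a hills log in memory
#'
#' @param time,center,sigma,height numeric vectors (ps, nm, nm, kJ/mol).
#' @param gamma bias factor, `> 1`.
#' @param cv collective-variable name.
#' @return A `hills_log`.
#' @export
hills_log <- function(time, center, sigma, height, gamma = 100, cv = "rg") {
  if (any(sigma <= 0)) stop("Gaussian widths must be > 0")
  if (any(height < 0)) stop("Gaussian heights must be >= 0")
  if (length(time) > 1 && any(diff(time) < 0))
    stop("deposition times must be non-decreasing")
  if (gamma <= 1) stop("bias factor must exceed 1")
  structure(data.frame(time = time, center = center, sigma = sigma,
                       height = height),
            class = c("hills_log", "data.frame"), gamma = gamma, cv = cv)
}

#' Write a hills log to the standard text dialect
#'
#' @param log a `hills_log`.
#' @param path output path.
#' @export
write_hills <- function(log, path) {
  cv <- attr(log, "cv")
  gamma <- attr(log, "gamma")
  writeLines(c(sprintf("#! FIELDS time %s sigma_%s height biasf", cv, cv),
               sprintf("%.6f %.8f %.8f %.8f %.4f", log$time, log$center,
                       log$sigma, log$height, gamma)),
             path)
  invisible(path)
}

#' Metadynamics bias potential
#'
#' Sum of the deposited Gaussians with deposition time strictly below `t`:
#' `V(s, t) = sum_k W_k exp(-(s - c_k)^2 / (2 sigma_k^2))`.
#'
#' @param log a `hills_log`.
#' @param s collective-variable values (nm), scalar or vector.
#' @param t evaluation time (ps); `Inf` for the full log.
#' @return bias in kJ/mol, same length as `s`.
#' @export
bias_potential <- function(log, s, t = Inf) {
  if (any(!is.finite(s))) stop("grid points must be finite")
  sel <- log$time < t
  if (!any(sel)) return(numeric(length(s)) + 0)
  cn <- log$center[sel]; sg <- log$sigma[sel]; W <- log$height[sel]
  vapply(s, function(si) sum(W * exp(-(si - cn)^2 / (2 * sg^2))), numeric(1))
}

#' Well-tempered free-energy profile
#'
#' Reconstructs the free-energy profile over the collective variable from a
#' converged well-tempered bias: `dG(s) = -(gamma / (gamma - 1)) V(s,
#' t_end)`, shifted so the minimum over the grid is zero. The optional error
#' band is the block-averaged standard error over `n_blocks` deposition-time
#' segments (a labelled substitute for reweighting-based estimates).
#'
#' @param log a `hills_log` with bias factor `gamma > 1`.
#' @param grid CV grid (nm); default 200 points spanning
#'   `[min(center) - 3 sigma, max(center) + 3 sigma]`.
#' @param n_blocks deposition blocks for the error band (0 disables).
#' @return An object of class `fes_profile`: data.frame with columns `s`,
#'   `dG` (kJ/mol, min 0) and `se`; attribute `gamma`.
#' @export
wt_fes <- function(log, grid = NULL, n_blocks = 4L) {
  gamma <- attr(log, "gamma")
  if (is.null(gamma) || is.na(gamma)) gamma <- 100
  if (gamma <= 1) stop("bias factor must exceed 1")
  if (is.null(grid)) {
    if (!nrow(log)) grid <- seq(0, 1, length.out = 200)
    else {
      sp <- max(log$sigma)
      grid <- seq(min(log$center) - 3 * sp, max(log$center) + 3 * sp,
                  length.out = 200)
    }
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  pref <- gamma / (gamma - 1)
  V <- bias_potential(log, grid, Inf)
  dG <- -pref * V
  dG <- dG - min(dG)
  se <- rep(NA_real_, length(grid))
  if (n_blocks > 1 && nrow(log) >= n_blocks) {
    cuts <- floor(seq(0, nrow(log), length.out = n_blocks + 1))
    prof <- sapply(seq_len(n_blocks), function(b) {
      sub <- log[(cuts[b] + 1):cuts[b + 1], , drop = FALSE]
      attr(sub, "gamma") <- gamma
      v <- bias_potential(sub, grid, Inf) * n_blocks
      g <- -pref * v
      g - min(g)
    })
    se <- apply(prof, 1, sd) / sqrt(n_blocks)
  }
  structure(data.frame(s = grid, dG = dG, se = se),
            class = c("fes_profile", "data.frame"), gamma = gamma,
            cv = attr(log, "cv"))
}

#' Scan a free-energy profile for minima and barriers
#'
#' Local minima are detected by sign changes of the first difference; for
#' every pair of adjacent minima the barrier is the lowest intervening
#' maximum minus the shallower (higher-lying) of the two minima.
#'
#' @param profile an `fes_profile` (>= 3 grid points).
#' @param kT thermal energy in kJ/mol (default 2.494, i.e. ~300 K).
#' @return list with `minima` (data.frame `s`, `dG`) and `barriers`
#'   (data.frame `left_min_s`, `right_min_s`, `barrier`, `barrier_kT`).
#' @export
barrier_scan <- function(profile, kT = 2.494) {
  if (nrow(profile) < 3) stop("profile needs at least 3 grid points")
  g <- profile$dG
  s <- profile$s
  d <- diff(g)
  n <- length(g)
  sgn <- sign(d)
  if (all(sgn == 0)) {
    imin <- integer(0)                       # flat profile: no minima
  } else {
    # forward/backward fill zero slopes so plateau minima are detected
    sL <- sgn
    for (k in seq_along(sL)[-1]) if (sL[k] == 0) sL[k] <- sL[k - 1]
    sR <- sgn
    for (k in rev(seq_along(sR))[-1]) if (sR[k] == 0) sR[k] <- sR[k + 1]
    is_min <- c(FALSE, head(sL, -1) < 0 & tail(sR, -1) > 0, FALSE)[seq_len(n)]
    # collapse plateau runs to their middle grid point
    r <- rle(is_min)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    imin <- as.integer(floor((starts[r$values] + ends[r$values]) / 2)) +
      1L - 1L
    # terminal minima at monotone ends
    if (sR[1] > 0) imin <- unique(c(1L, imin))
    if (sL[n - 1] < 0) imin <- unique(c(imin, n))
    imin <- sort(imin)
  }
  minima <- data.frame(s = s[imin], dG = g[imin])
  barriers <- data.frame(left_min_s = numeric(0), right_min_s = numeric(0),
                         barrier = numeric(0), barrier_kT = numeric(0))
  if (length(imin) >= 2) {
    for (k in seq_len(length(imin) - 1)) {
      i1 <- imin[k]; i2 <- imin[k + 1]
      peak <- max(g[i1:i2])
      shallower <- max(g[i1], g[i2])
      barriers <- rbind(barriers,
                        data.frame(left_min_s = s[i1], right_min_s = s[i2],
                                   barrier = peak - shallower,
                                   barrier_kT = (peak - shallower) / kT))
    }
  }
  list(minima = minima, barriers = barriers)
}
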