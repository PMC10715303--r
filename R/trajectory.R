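# Trajectory metrics: Kabsch superposition, RMSD/RMSF, radius of gyration,
# Shrake-Rupley SASA, hydrogen-bond occupancy.

#' Kabsch superposition
#'
#' Finds the proper rotation + translation of \code{mobile} minimizing the
#' RMSD to \code{reference} over a selection, and applies it to all mobile
#' coordinates.
#'
#' @param mobile,reference n x 3 coordinate matrices (equal atom counts).
#' @param selection integer indices of the atoms used for the fit (default
#'   all); at least 3 non-collinear atoms required.
#' @return list: \code{coords} (transformed mobile, all atoms), \code{rmsd}
#'   (minimized, over the selection), \code{rotation} (3x3, det +1),
#'   \code{translation}.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  sel <- selection %||% seq_len(nrow(mobile))
  if (length(sel) < 3L) {
    stop_setphen("superposition needs >= 3 atoms (got %d)", length(sel),
                 class = "setphen_argument_error")
  }
  A <- mobile[sel, , drop = FALSE]
  B <- reference[sel, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)              # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-12) {
    stop_setphen("degenerate (collinear) selection geometry",
                 class = "setphen_argument_error")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- sweep(sweep(mobile, 2, ca) %*% t(R), 2, cb, "+")
  dev <- moved[sel, , drop = FALSE] - B
  list(coords = moved,
       rmsd = sqrt(mean(rowSums(dev^2))),
       rotation = R,
       translation = cb - as.vector(R %*% ca))
}

#' Per-frame RMSD series against a reference frame
#'
#' Each frame is superposed (Kabsch) onto the reference over the selection
#' before computing the deviation; with the default selection this is the
#' backbone RMSD customarily plotted against simulation time.
#'
#' @param trajectory \code{md_trajectory}.
#' @param reference reference frame index (default 1).
#' @param selection passed to [select_atoms] on the topology.
#' @return data.frame: \code{frame}, \code{time_ps}, \code{rmsd} (Angstrom).
#' @export
rmsd_series <- function(trajectory, reference = 1, selection = "backbone") {
  sel <- select_atoms(trajectory$topology, selection)
  ref <- frame_coords(trajectory, reference)
  vals <- vapply(seq_len(nrow(trajectory$frames)), function(f) {
    superpose(frame_coords(trajectory, f), ref, sel)$rmsd
  }, numeric(1))
  data.frame(frame = seq_along(vals),
             time_ps = (seq_along(vals) - 1) * trajectory$frame_interval,
             rmsd = vals)
}

#' Per-residue RMSF profile
#'
#' Every frame is superposed onto the first frame (over the selection), the
#' average structure is computed, and the RMSF of residue i is the root mean
#' square displacement of its selected-atom centroid from its average
#' position.
#'
#' @param trajectory \code{md_trajectory} with >= 2 frames.
#' @param selection atoms used for both the fit and the per-residue centroid
#'   (default backbone).
#' @return data.frame: \code{residue} (index), \code{resno}, \code{rmsf}
#'   (Angstrom).
#' @export
rmsf_profile <- function(trajectory, selection = "backbone") {
  nf <- nrow(trajectory$frames)
  if (nf < 2L) {
    stop_setphen("RMSF needs >= 2 frames", class = "setphen_argument_error")
  }
  topo <- trajectory$topology
  sel <- select_atoms(topo, selection)
  ref <- frame_coords(trajectory, 1)
  res_of_sel <- topo$atoms$res_index[sel]
  residues <- sort(unique(res_of_sel))
  grp <- match(res_of_sel, residues)
  n_per <- tabulate(grp, nbins = length(residues))
  # accumulate per-residue centroid first and second moments over frames
  # (relative to the reference-frame centroids, to avoid cancellation);
  # RMSF uses the population (divide-by-n) convention
  cent0 <- rowsum(ref[sel, , drop = FALSE], grp) / n_per
  s1 <- matrix(0, length(residues), 3)
  s2 <- matrix(0, length(residues), 3)
  for (f in seq_len(nf)) {
    fit <- superpose(frame_coords(trajectory, f), ref, sel)$coords[sel, , drop = FALSE]
    cent <- rowsum(fit, grp) / n_per - cent0
    s1 <- s1 + cent
    s2 <- s2 + cent^2
  }
  msd <- rowSums(s2 / nf - (s1 / nf)^2)
  msd[msd < 0] <- 0   # numerical guard
  data.frame(residue = residues,
             resno = topo$residues$resno[residues],
             rmsf = sqrt(msd))
}

#' Compare two RMSF profiles
#'
#' The two standard per-variant flexibility scores: the Pearson correlation
#' of the profiles (r-RMSF; 1 = identical shape) and the mean absolute
#' difference (Delta|RMSF|, Angstrom; 0 = identical amplitude).
#'
#' @param wt,var numeric RMSF vectors (equal length >= 2) or data.frames
#'   from [rmsf_profile].
#' @return list: \code{r_rmsf}, \code{mean_abs_diff}. A zero-variance
#'   profile gives \code{r_rmsf = NA} with a warning.
#' @export
rmsf_compare <- function(wt, var) {
  if (is.data.frame(wt)) wt <- wt$rmsf
  if (is.data.frame(var)) var <- var$rmsf
  stopifnot(length(wt) == length(var), length(wt) >= 2L)
  r <- if (stats::sd(wt) == 0 || stats::sd(var) == 0) {
    warning("zero-variance RMSF profile; correlation undefined")
    NA_real_
  } else {
    stats::cor(wt, var)
  }
  list(r_rmsf = r, mean_abs_diff = mean(abs(var - wt)))
}

#' Radius of gyration of one conformation
#'
#' @param coords n x 3 coordinate matrix.
#' @param masses atomic masses (default all 1, i.e. geometric Rg).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1L)
  m <- masses %||% rep(1, nrow(coords))
  if (sum(m) <= 0) {
    stop_setphen("total mass must be positive", class = "setphen_argument_error")
  }
  com <- colSums(coords * m) / sum(m)
  dev <- sweep(coords, 2, com)
  sqrt(sum(m * rowSums(dev^2)) / sum(m))
}

#' Per-frame radius-of-gyration series
#'
#' @param trajectory \code{md_trajectory}.
#' @param selection passed to [select_atoms].
#' @param masses optional per-selected-atom masses.
#' @return data.frame: frame, time_ps, rg.
#' @export
rg_series <- function(trajectory, selection = "all", masses = NULL) {
  sel <- select_atoms(trajectory$topology, selection)
  vals <- vapply(seq_len(nrow(trajectory$frames)), function(f) {
    radius_of_gyration(frame_coords(trajectory, f)[sel, , drop = FALSE], masses)
  }, numeric(1))
  data.frame(frame = seq_along(vals),
             time_ps = (seq_along(vals) - 1) * trajectory$frame_interval,
             rg = vals)
}

# --- SASA (Shrake-Rupley) --------------------------------------------------

#' Default van der Waals radii by element (Angstrom)
#' @export
VDW_RADII <- stats::setNames(
  c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.39, 1.47, 1.75, 1.85,
    1.98, 1.90, 1.40, 1.73, 2.00, 2.27, 2.75, 1.40, 1.40),
  c("H", "C", "N", "O", "S", "P", "ZN", "F", "CL", "BR",
    "I", "SE", "FE", "MG", "CA", "NA", "K", "MN", "CU"))

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals surface by testing, for every
#' atom, a deterministic golden-spiral point set on its expanded sphere
#' (radius + probe) against all neighboring expanded spheres.
#'
#' @param coords n x 3 coordinates, or a \code{pdb_structure}.
#' @param elements character vector of element symbols (taken from the
#'   structure when one is supplied).
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_points sphere test points per atom (default 960).
#' @param radii named radius lookup (default [VDW_RADII]).
#' @return list: \code{total} (Angstrom^2), \code{per_atom}.
#' @export
sasa <- function(coords, elements = NULL, probe = 1.4, n_points = 960,
                 radii = VDW_RADII) {
  if (inherits(coords, "pdb_structure")) {
    elements <- coords$atoms$element
    coords <- structure_coords(coords)
  }
  coords <- as.matrix(coords)
  stopifnot(!is.null(elements), length(elements) == nrow(coords))
  r <- radii[toupper(elements)]
  if (anyNA(r)) {
    stop_setphen("no van der Waals radius for element '%s'",
                 elements[is.na(r)][1], class = "setphen_argument_error")
  }
  r <- unname(r) + probe
  n <- nrow(coords)
  pts <- .sphere_points(n_points)
  per_atom <- numeric(n)
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    surf <- sweep(pts * r[i], 2, coords[i, ], "+")
    if (length(neigh)) {
      acc <- rep(TRUE, n_points)
      eps <- 1e-9
      for (j in neigh) {
        dj <- sweep(surf, 2, coords[j, ])
        pd2 <- rowSums(dj^2)
        # a test point exactly on a neighbor's expanded sphere (duplicate
        # atoms) is assigned to the lower-index atom, so coincident spheres
        # contribute one surface, not zero or two
        buried <- pd2 < r[j]^2 - eps | (abs(pd2 - r[j]^2) <= eps & j < i)
        acc <- acc & !buried
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    per_atom[i] <- frac * 4 * pi * r[i]^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Per-frame SASA series
#'
#' @param trajectory \code{md_trajectory}.
#' @param ... passed to [sasa].
#' @return data.frame: frame, time_ps, sasa (Angstrom^2).
#' @export
sasa_series <- function(trajectory, ...) {
  el <- trajectory$topology$atoms$element
  vals <- vapply(seq_len(nrow(trajectory$frames)), function(f) {
    sasa(frame_coords(trajectory, f), el, ...)$total
  }, numeric(1))
  data.frame(frame = seq_along(vals),
             time_ps = (seq_along(vals) - 1) * trajectory$frame_interval,
             sasa = vals)
}

# --- hydrogen-bond occupancy ----------------------------------------------

# resolve "resno:atomname" (optionally "chain:resno:atomname") to atom index
.resolve_atom <- function(structure, spec) {
  parts <- strsplit(spec, ":")[[1]]
  at <- structure$atoms; res <- structure$residues
  if (length(parts) == 3L) {
    hit <- which(res$chain[at$res_index] == parts[1] &
                 res$resno[at$res_index] == as.integer(parts[2]) &
                 at$name == parts[3])
  } else if (length(parts) == 2L) {
    hit <- which(res$resno[at$res_index] == as.integer(parts[1]) &
                 at$name == parts[2])
  } else {
    stop_setphen("atom spec '%s' must be [chain:]resno:atomname", spec,
                 class = "setphen_argument_error")
  }
  if (length(hit) == 0L) {
    avail <- unique(paste0(res$resno[at$res_index], ":", at$name))
    stop_setphen("atom '%s' not found; available: %s", spec,
                 paste(utils::head(avail, 20), collapse = ", "),
                 class = "setphen_argument_error")
  }
  hit[1]
}

#' Hydrogen-bond (donor-acceptor distance) occupancy over a trajectory window
#'
#' A bond is counted as formed in a frame when the donor-acceptor heavy-atom
#' distance lies inside [d_min, d_max] (defaults 2.2-3.3 Angstrom). The
#' occupancy is the fraction of frames inside the analysis window (default
#' the last quarter of the trajectory) in which the bond is formed.
#'
#' @param trajectory \code{md_trajectory}.
#' @param pairs data.frame with columns \code{label}, \code{from_atom},
#'   \code{to_atom} (atom specs \code{"[chain:]resno:name"}).
#' @param window fraction of trailing frames analyzed (default 0.25).
#' @param d_min,d_max distance bounds, Angstrom.
#' @return list of class \code{hbond_monitor}: \code{occupancy} (data.frame
#'   label, occupancy), \code{distances} (frames-in-window x pairs),
#'   \code{window_frames} (indices).
#' @export
hbond_occupancy <- function(trajectory, pairs, window = 0.25,
                            d_min = 2.2, d_max = 3.3) {
  stopifnot(window > 0, window <= 1, d_min <= d_max)
  nf <- nrow(trajectory$frames)
  n_win <- max(1L, floor(window * nf))
  win <- seq.int(nf - n_win + 1L, nf)
  ai <- vapply(pairs$from_atom, .resolve_atom, integer(1),
               structure = trajectory$topology)
  aj <- vapply(pairs$to_atom, .resolve_atom, integer(1),
               structure = trajectory$topology)
  dmat <- matrix(NA_real_, length(win), nrow(pairs),
                 dimnames = list(NULL, pairs$label))
  for (k in seq_along(win)) {
    xyz <- frame_coords(trajectory, win[k])
    dmat[k, ] <- sqrt(rowSums((xyz[ai, , drop = FALSE] -
                               xyz[aj, , drop = FALSE])^2))
  }
  occ <- colMeans(dmat >= d_min & dmat <= d_max)
  out <- list(occupancy = data.frame(label = pairs$label,
                                     occupancy = unname(occ),
                                     stringsAsFactors = FALSE),
              distances = dmat, window_frames = win)
  class(out) <- "hbond_monitor"
  out
}
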