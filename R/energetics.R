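# MM-PBSA aggregation and pairwise nonbonded interaction energies.
#
# Energy tables arrive as per-frame component rows from an external engine
# (or the synthetic generator): for each of the three states (complex,
# receptor, ligand) the molecular-mechanics terms E_vdw, E_ele, E_bnd, the
# polar/non-polar solvation terms G_PB, G_SA, and the entropic term TS.

ENERGY_COMPONENTS <- c("E_vdw", "E_ele", "E_bnd", "G_PB", "G_SA", "TS")
ENERGY_STATES <- c("complex", "receptor", "ligand")

#' Read a per-frame energy-component table
#'
#' @param path TSV with columns \code{frame_ps}, \code{state} (complex /
#'   receptor / ligand), and the six components ([ENERGY_COMPONENTS]); a
#'   missing TS column is treated as zero (entropy omitted, the common
#'   end-point practice).
#' @return data.frame.
#' @export
read_energy_table <- function(path) {
  tab <- read_tsv_table(path)
  if (!"TS" %in% names(tab)) tab$TS <- 0
  need <- c("frame_ps", "state", ENERGY_COMPONENTS)
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_setphen("energy table lacks column(s): %s",
                 paste(missing, collapse = ", "), class = "setphen_format_error")
  }
  bad <- setdiff(unique(tab$state), ENERGY_STATES)
  if (length(bad)) {
    stop_setphen("unknown state '%s'", bad[1], class = "setphen_format_error")
  }
  tab
}

#' Free energy of one state snapshot
#'
#' G = (E_vdw + E_ele + E_bnd) + G_PB + G_SA - TS; the bracket is the
#' molecular-mechanics energy E_MM.
#'
#' @param row one-row data.frame or list with the six components (a missing
#'   or NULL TS is treated as 0).
#' @return kcal/mol.
#' @export
state_free_energy <- function(row) {
  for (cc in c("E_vdw", "E_ele", "E_bnd", "G_PB", "G_SA")) {
    v <- row[[cc]]
    if (is.null(v) || !is.finite(v)) {
      stop_setphen("missing or non-finite energy component '%s'", cc,
                   class = "setphen_format_error")
    }
  }
  ts <- row[["TS"]]
  if (is.null(ts) || is.na(ts)) ts <- 0
  e_mm <- row$E_vdw + row$E_ele + row$E_bnd
  e_mm + row$G_PB + row$G_SA - ts
}

#' Per-frame binding free energies and their summary
#'
#' dG_bind(frame) = G_complex - G_receptor - G_ligand, evaluated on aligned
#' frames; the headline value is the arithmetic mean over frames.
#'
#' @param tbl energy table ([read_energy_table] layout).
#' @return list of class \code{binding_result}: \code{per_frame} (data.frame
#'   frame_ps, dg_bind), \code{mean}, \code{sd}, \code{n_frames}.
#' @export
binding_series <- function(tbl) {
  if (!"TS" %in% names(tbl)) tbl$TS <- 0
  sp <- split(tbl, tbl$state)
  missing <- setdiff(ENERGY_STATES, names(sp))
  if (length(missing)) {
    stop_setphen("energy table lacks state(s): %s",
                 paste(missing, collapse = ", "), class = "setphen_format_error")
  }
  frames <- sort(unique(tbl$frame_ps))
  for (st in ENERGY_STATES) {
    lack <- setdiff(frames, sp[[st]]$frame_ps)
    if (length(lack)) {
      stop_setphen("state '%s' lacks frame(s): %s", st,
                   paste(utils::head(lack, 5), collapse = ", "),
                   class = "setphen_format_error")
    }
  }
  g <- lapply(sp, function(d) {
    d <- d[match(frames, d$frame_ps), , drop = FALSE]
    vapply(seq_len(nrow(d)), function(i) state_free_energy(d[i, ]), numeric(1))
  })
  dg <- g$complex - g$receptor - g$ligand
  out <- list(per_frame = data.frame(frame_ps = frames, dg_bind = dg),
              mean = mean(dg),
              sd = if (length(dg) > 1) stats::sd(dg) else 0,
              n_frames = length(dg))
  class(out) <- "binding_result"
  out
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("MM-PBSA binding free energy: %.1f +/- %.1f kcal/mol (n = %d frames)\n",
              x$mean, x$sd, x$n_frames))
  invisible(x)
}

#' Binding free-energy change of a variant against a reference
#'
#' ddG_bind = mean(variant) - mean(reference). Negative values mean the
#' variant binds more tightly than the reference (improved affinity);
#' positive values mean weaker binding.
#'
#' @param mut,wt \code{binding_result} objects (or numbers).
#' @return list: \code{ddg_bind} (kcal/mol), \code{interpretation}
#'   ("improved" / "weaker" / "unchanged").
#' @export
ddg_vs_reference <- function(mut, wt) {
  m <- if (inherits(mut, "binding_result")) mut$mean else mut
  w <- if (inherits(wt, "binding_result")) wt$mean else wt
  d <- m - w
  list(ddg_bind = d,
       interpretation = if (d < 0) "improved" else if (d > 0) "weaker" else "unchanged")
}

#' Pairwise nonbonded interaction energy between two atom groups
#'
#' Coulomb term with k_e = 332.0636 kcal A / (mol e^2) and a constant or
#' distance-dependent dielectric, plus a Lennard-Jones 12-6 term under
#' Lorentz-Berthelot combination (eps_ij = sqrt(eps_i eps_j), r_min_ij =
#' (r_min_i + r_min_j)/2, where r_min_i is the homo-pair minimum distance).
#' Used e.g. to follow the Zn(2+)-protein interaction along a trajectory.
#'
#' @param coords n x 3 coordinates.
#' @param group_a,group_b integer atom indices of the two groups (disjoint).
#' @param params data.frame with per-atom \code{q} (e), \code{eps}
#'   (kcal/mol, >= 0), \code{r_min} (Angstrom); row i = atom i.
#' @param dielectric constant relative dielectric (default 1).
#' @param distance_dependent if TRUE, eps_eff = dielectric * r_ij (the
#'   distance-dependent screening model used in implicit-solvent MD).
#' @return list: \code{E_ele}, \code{E_vdw}, \code{total} (kcal/mol).
#' @export
pair_interaction_energy <- function(coords, group_a, group_b, params,
                                    dielectric = 1, distance_dependent = FALSE) {
  coords <- as.matrix(coords)
  need <- c("q", "eps", "r_min")
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop_setphen("params lack column(s): %s", paste(missing, collapse = ", "),
                 class = "setphen_format_error")
  }
  if (nrow(params) < max(c(group_a, group_b))) {
    stop_setphen("params incomplete: %d rows for atom index up to %d",
                 nrow(params), max(c(group_a, group_b)),
                 class = "setphen_format_error")
  }
  ke <- 332.0636
  e_ele <- 0; e_vdw <- 0
  for (i in group_a) {
    dvec <- sweep(coords[group_b, , drop = FALSE], 2, coords[i, ])
    r <- sqrt(rowSums(dvec^2))
    if (any(r == 0)) {
      stop_setphen("zero interatomic distance between groups",
                   class = "setphen_argument_error")
    }
    eps_eff <- if (distance_dependent) dielectric * r else dielectric
    e_ele <- e_ele + sum(ke * params$q[i] * params$q[group_b] / (eps_eff * r))
    eps_ij <- sqrt(params$eps[i] * params$eps[group_b])
    rmin_ij <- (params$r_min[i] + params$r_min[group_b]) / 2
    sr <- (rmin_ij / r)
    e_vdw <- e_vdw + sum(eps_ij * (sr^12 - 2 * sr^6))
  }
  list(E_ele = e_ele, E_vdw = e_vdw, total = e_ele + e_vdw)
}
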