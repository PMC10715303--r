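# Synthetic-data generators: every input class the pipeline consumes, with
# known ground truth, so all stages are testable without downloads. All
# generators are deterministic under a fixed seed and restore the caller's
# RNG state.

with_local_seed <- function(seed, expr) {
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(seed)
  expr
}

#' Build an ideal alpha-helix structure
#'
#' Canonical helix geometry: 1.5 Angstrom rise and 100 degrees twist per
#' residue, C-alpha radius 2.3 Angstrom. Two backbone flavors: a CA+CB
#' pseudo-backbone (CB displaced outward, default) or a full 4-atom backbone
#' (N, CA, C, O at fixed offsets) so PDB-consuming analyses (SASA,
#' frustration) run unmodified.
#'
#' @param n_residues helix length.
#' @param sequence optional one-letter sequence (recycled/validated);
#'   default cycles through the 20 standard residues.
#' @param backbone \code{"cacb"} or \code{"full"}.
#' @param chain chain identifier.
#' @return \code{pdb_structure}.
#' @export
build_helix <- function(n_residues, sequence = NULL, backbone = c("cacb", "full"),
                        chain = "A") {
  backbone <- match.arg(backbone)
  stopifnot(n_residues >= 1)
  seq_aa <- sequence %||% rep_len(AA_ONE, n_residues)
  seq_aa <- rep_len(seq_aa, n_residues)
  stopifnot(all(seq_aa %in% AA_ONE))
  twist <- 100 * pi / 180; rise <- 1.5; r_ca <- 2.3
  atoms <- list()
  for (i in seq_len(n_residues)) {
    th <- (i - 1) * twist; z <- (i - 1) * rise
    ca <- c(r_ca * cos(th), r_ca * sin(th), z)
    if (backbone == "cacb") {
      cb <- c((r_ca + 1.5) * cos(th), (r_ca + 1.5) * sin(th), z)
      a <- data.frame(res_index = i,
                      name = if (seq_aa[i] == "G") "CA" else c("CA", "CB"),
                      element = "C",
                      x = if (seq_aa[i] == "G") ca[1] else c(ca[1], cb[1]),
                      y = if (seq_aa[i] == "G") ca[2] else c(ca[2], cb[2]),
                      z = if (seq_aa[i] == "G") ca[3] else c(ca[3], cb[3]),
                      o = 1, b = 0, stringsAsFactors = FALSE)
    } else {
      nn <- c(1.6 * cos(th - 0.5), 1.6 * sin(th - 0.5), z - 0.9)
      cc <- c(2.0 * cos(th + 0.4), 2.0 * sin(th + 0.4), z + 0.7)
      oo <- c(2.6 * cos(th + 0.55), 2.6 * sin(th + 0.55), z + 1.1)
      a <- data.frame(res_index = i, name = c("N", "CA", "C", "O"),
                      element = c("N", "C", "C", "O"),
                      x = c(nn[1], ca[1], cc[1], oo[1]),
                      y = c(nn[2], ca[2], cc[2], oo[2]),
                      z = c(nn[3], ca[3], cc[3], oo[3]),
                      o = 1, b = 0, stringsAsFactors = FALSE)
    }
    atoms[[i]] <- a
  }
  residues <- data.frame(chain = chain, resno = seq_len(n_residues),
                         aa = seq_aa, stringsAsFactors = FALSE)
  new_structure(residues, do.call(rbind, atoms))
}

#' Generate a Gaussian-fluctuation trajectory with known ground truth
#'
#' Each frame displaces every residue (all its atoms together) by an
#' independent isotropic Gaussian vector with per-residue standard deviation
#' \code{sigma[i]} per axis, then optionally applies a random global rigid
#' motion. The expected per-residue RMSF (about the trajectory average,
#' sample-variance convention) is \code{sigma_i * sqrt(3) * sqrt((n-1)/n)}.
#'
#' @param reference \code{pdb_structure} (e.g. [build_helix]).
#' @param sigma per-residue displacement sd, Angstrom (recycled).
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @param rigid_motion apply a random rotation + translation per frame
#'   (default FALSE); metrics must be invariant to it.
#' @param frame_interval ps per frame.
#' @return \code{md_trajectory} with attribute \code{sigma} (ground truth).
#' @export
gen_trajectory <- function(reference, sigma = 0.5, n_frames = 100, seed = 1,
                           rigid_motion = FALSE, frame_interval = 10) {
  stopifnot(n_frames >= 2)
  sigma <- rep_len(sigma, nrow(reference$residues))
  stopifnot(all(sigma >= 0))
  ref <- structure_coords(reference)
  res_idx <- reference$atoms$res_index
  nat <- nrow(ref)
  frames <- with_local_seed(seed, {
    out <- matrix(NA_real_, n_frames, 3 * nat)
    for (f in seq_len(n_frames)) {
      disp <- matrix(stats::rnorm(3 * length(sigma), sd = rep(sigma, 3)),
                     ncol = 3)
      xyz <- ref + disp[res_idx, , drop = FALSE]
      if (rigid_motion) {
        R <- random_rotation()
        xyz <- xyz %*% t(R) +
          matrix(stats::runif(3, -20, 20), nat, 3, byrow = TRUE)
      }
      out[f, ] <- as.vector(t(xyz))
    }
    out
  })
  tr <- new_trajectory(reference, frames, frame_interval)
  attr(tr, "sigma") <- sigma
  tr
}

#' Uniformly random proper rotation matrix
#'
#' Draws a random unit quaternion from the current RNG stream.
#' @return 3x3 rotation matrix, det +1.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a per-frame energy-component table with known binding energy
#'
#' Components of the receptor and ligand states are Gaussian around fixed
#' means; the complex state is constructed as receptor + ligand + a
#' per-frame binding term drawn around \code{dg_mean}, so the frame-wise
#' complex - receptor - ligand difference has the specified mean and sd.
#'
#' @param dg_mean target mean binding free energy, kcal/mol.
#' @param dg_sd per-frame sd of the binding term (default 2).
#' @param n_frames number of frames (default 150 snapshots, the common
#'   end-point sampling depth; a 100-frame last-nanosecond preset is the
#'   other convention).
#' @param seed integer seed.
#' @param component_sd sd of the individual state components (default 5).
#' @return data.frame in [read_energy_table] layout with attribute
#'   \code{dg_mean}.
#' @export
gen_energy_table <- function(dg_mean = -163.4, dg_sd = 2, n_frames = 150,
                             seed = 1, component_sd = 5) {
  base <- list(receptor = c(E_vdw = -800, E_ele = -1500, E_bnd = 2300,
                            G_PB = -350, G_SA = 90, TS = 0),
               ligand = c(E_vdw = -30, E_ele = -60, E_bnd = 85,
                          G_PB = -40, G_SA = 10, TS = 0))
  with_local_seed(seed, {
    frames <- seq_len(n_frames) * 10
    mk <- function(state, means) {
      comp <- vapply(ENERGY_COMPONENTS, function(cc) {
        if (cc == "TS") rep(0, n_frames)
        else stats::rnorm(n_frames, means[cc], component_sd)
      }, numeric(n_frames))
      data.frame(frame_ps = frames, state = state,
                 as.data.frame(comp), stringsAsFactors = FALSE)
    }
    rec <- mk("receptor", base$receptor)
    lig <- mk("ligand", base$ligand)
    dg <- stats::rnorm(n_frames, dg_mean, dg_sd)
    cpx <- rec
    cpx$state <- "complex"
    for (cc in setdiff(ENERGY_COMPONENTS, "TS")) {
      cpx[[cc]] <- rec[[cc]] + lig[[cc]]
    }
    # put the whole binding term in the van der Waals column; only the
    # state sums matter for the aggregation
    cpx$E_vdw <- cpx$E_vdw + dg
    out <- rbind(cpx, rec, lig)
    attr(out, "dg_mean") <- dg_mean
    out
  })
}

#' Generate a paralog alignment consistent with given position pairs
#'
#' Constructs two synthetic full-length sequences and their pairwise
#' alignment such that transferring each (source position, target position)
#' pair over the alignment reproduces it exactly, with the specified residue
#' letters at the constrained positions. Unconstrained positions are filled
#' with seeded random residues; changing the filler seed never changes the
#' mapped pairs. The sequences are a fixture construction, not biology.
#'
#' @param pairs data.frame with \code{source_pos}, \code{target_pos}
#'   (strictly increasing in both), \code{source_res}, \code{target_res}
#'   (one-letter).
#' @param source_id,target_id FASTA identifiers.
#' @param seed filler seed.
#' @param tail_length unconstrained residues appended after the last pair.
#' @return named character vector of two gapped sequences (aligned FASTA
#'   rows), usable directly with [build_position_map].
#' @export
gen_paralog_alignment <- function(pairs, source_id = "SOURCE",
                                  target_id = "TARGET", seed = 1,
                                  tail_length = 5) {
  stopifnot(nrow(pairs) >= 1)
  # several variants can share one residue position (mutation hotspots):
  # collapse duplicated position pairs, then require strict monotonicity
  key <- paste(pairs$source_pos, pairs$target_pos)
  dup <- duplicated(key)
  if (any(dup)) {
    same <- vapply(which(dup), function(k) {
      first <- match(key[k], key)
      pairs$source_res[k] == pairs$source_res[first] &&
        pairs$target_res[k] == pairs$target_res[first]
    }, logical(1))
    if (!all(same)) {
      stop_setphen("conflicting residues for a duplicated position pair",
                   class = "setphen_argument_error")
    }
    pairs <- pairs[!dup, , drop = FALSE]
  }
  pairs <- pairs[order(pairs$source_pos), , drop = FALSE]
  if (is.unsorted(pairs$source_pos, strictly = TRUE) ||
      is.unsorted(pairs$target_pos, strictly = TRUE)) {
    stop_setphen("position pairs must be strictly increasing in both coordinates",
                 class = "setphen_argument_error")
  }
  stopifnot(all(pairs$source_res %in% AA_ONE), all(pairs$target_res %in% AA_ONE))
  with_local_seed(seed, {
    filler <- function(n) if (n > 0) sample(AA_ONE, n, replace = TRUE) else character(0)
    src_col <- character(0); tgt_col <- character(0)
    cs <- 0L; ct <- 0L
    for (k in seq_len(nrow(pairs))) {
      ds <- pairs$source_pos[k] - cs - 1L
      dt <- pairs$target_pos[k] - ct - 1L
      both <- min(ds, dt)
      if (both > 0) {
        src_col <- c(src_col, filler(both))
        tgt_col <- c(tgt_col, filler(both))
      }
      if (ds > both) {
        src_col <- c(src_col, filler(ds - both))
        tgt_col <- c(tgt_col, rep("-", ds - both))
      }
      if (dt > both) {
        src_col <- c(src_col, rep("-", dt - both))
        tgt_col <- c(tgt_col, filler(dt - both))
      }
      src_col <- c(src_col, pairs$source_res[k])
      tgt_col <- c(tgt_col, pairs$target_res[k])
      cs <- pairs$source_pos[k]; ct <- pairs$target_pos[k]
    }
    if (tail_length > 0) {
      src_col <- c(src_col, filler(tail_length))
      tgt_col <- c(tgt_col, filler(tail_length))
    }
    stats::setNames(c(paste(src_col, collapse = ""),
                      paste(tgt_col, collapse = "")),
                    c(source_id, target_id))
  })
}

#' Generate a variant table with known class proportions
#'
#' Class counts are allocated deterministically by largest-remainder
#' rounding of \code{n * proportions} (so summaries are exact, not
#' multinomial), then rows are shuffled with the seed.
#'
#' @param proportions named numeric vector over [CLINICAL_CLASSES] subsets,
#'   summing to 1.
#' @param n number of variants.
#' @param seed integer seed.
#' @param gene gene label.
#' @param region protein-coordinate range positions are drawn from.
#' @return data.frame in the variant-table layout accepted by
#'   [read_variant_table] (columns gene, protein, clinical_significance, ...).
#' @export
gen_variant_table <- function(proportions, n, seed = 1, gene = "GENE",
                              region = c(1L, 1000L)) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8,
            all(names(proportions) %in% CLINICAL_CLASSES))
  if (n == 0L) {
    return(data.frame(gene = character(0), protein = character(0),
                      clinical_significance = character(0),
                      stringsAsFactors = FALSE))
  }
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  classes <- rep(names(proportions), counts)
  with_local_seed(seed, {
    classes <- sample(classes)
    pos <- sample(seq.int(region[1], region[2]), n, replace = TRUE)
    ref <- sample(AA_ONE, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(AA_ONE, r), 1), character(1))
    data.frame(gene = gene,
               protein = paste0("p.", AA_THREE[ref], pos, AA_THREE[alt]),
               clinical_significance = classes,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}
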