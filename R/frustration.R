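# Frustration engine: single-residue frustration indices computed as a
# decoy Z-score against a pairwise contact potential. This is a simplified,
# documented re-implementation of the decoy-ensemble scheme (mutational
# frustration: the residue identity is replaced, contacts and geometry are
# frozen); it is swappable down to the 20x20 potential table.

#' Default contact potential (synthetic, hydropathy-derived)
#'
#' A symmetric 20x20 residue-pair contact energy table built from
#' Kyte-Doolittle hydropathies so that hydrophobic-hydrophobic contacts are
#' the most favorable (most negative), in the spirit of quasi-chemical
#' knowledge-based potentials. Synthetic: it encodes the qualitative
#' structure such potentials share, not statistics from any PDB survey.
#' Swap in any 20x20 TSV via [read_contact_potential].
#'
#' @return 20x20 symmetric numeric matrix, dimnames = one-letter residues.
#' @export
default_contact_potential <- function() {
  h <- (KD_HYDROPATHY + 4.5) / 9   # map to [0, 1]
  m <- -2 * outer(h, h) - 0.5
  dimnames(m) <- list(names(KD_HYDROPATHY), names(KD_HYDROPATHY))
  m
}

#' Read a 20x20 contact potential from TSV
#'
#' @param path TSV: first column residue letters, remaining 20 columns the
#'   energies; must be symmetric over the 20 standard residues.
#' @return 20x20 symmetric matrix.
#' @export
read_contact_potential <- function(path) {
  tab <- read_tsv_table(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m <- m[AA_ONE, AA_ONE]
  if (max(abs(m - t(m))) > 1e-9) {
    stop_setphen("contact potential is not symmetric", class = "setphen_format_error")
  }
  m
}

# Representative side-chain point per residue: CB, or CA for glycine (or as
# fallback when CB is absent, with a warning).
.residue_points <- function(structure) {
  at <- structure$atoms
  res <- structure$residues
  pts <- matrix(NA_real_, nrow(res), 3)
  for (i in seq_len(nrow(res))) {
    sel <- at$res_index == i
    want <- if (res$aa[i] == "G") "CA" else "CB"
    j <- which(sel & at$name == want)
    if (length(j) == 0L) {
      j <- which(sel & at$name == "CA")
      if (length(j) && want == "CB") {
        warning(sprintf("residue %d (%s) lacks CB; using CA", i, res$aa[i]))
      }
    }
    if (length(j) == 0L) {
      stop_setphen("residue %d has no CB/CA atom", i, class = "setphen_format_error")
    }
    pts[i, ] <- c(at$x[j[1]], at$y[j[1]], at$z[j[1]])
  }
  pts
}

#' Residue-residue contact map
#'
#' Contacts are residue pairs whose representative side-chain atoms
#' (C-beta, C-alpha for glycine) lie within a distance cutoff, separated by
#' at least \code{min_sep} positions in sequence (default 2, excluding
#' trivially bonded neighbors).
#'
#' @param structure a \code{pdb_structure} (see [read_pdb] / [build_helix]).
#' @param cutoff contact distance cutoff, Angstrom (default 6.5).
#' @param min_sep minimum sequence separation |i - j| (default 2).
#' @return data.frame with columns \code{i}, \code{j} (i < j, residue
#'   indices) and \code{distance}; attribute \code{metric}.
#' @export
contact_map <- function(structure, cutoff = 6.5, min_sep = 2) {
  pts <- .residue_points(structure)
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(idx)) {
    sep_ok <- abs(idx[, 2] - idx[, 1]) >= min_sep
    idx <- idx[sep_ok, , drop = FALSE]
  }
  out <- data.frame(i = idx[, 1], j = idx[, 2],
                    distance = d[idx, drop = TRUE])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "metric") <- "CB (CA for Gly)"
  attr(out, "cutoff") <- cutoff
  attr(out, "min_sep") <- min_sep
  class(out) <- c("contact_set", "data.frame")
  out
}

# Native contact energy of residue i given its contact partners' identities.
.residue_energy <- function(aa_i, partner_aas, potential) {
  sum(potential[aa_i, partner_aas])
}

#' Single-residue mutational frustration index
#'
#' The native contact energy of residue i (sum of pair energies to its
#' contact partners) is compared against a decoy ensemble in which the
#' identity of residue i is replaced by an amino acid drawn uniformly from
#' the 19 alternatives, with contacts and geometry frozen. The index is
#' \code{(mean(E_decoy) - E_native) / sd(E_decoy)}: large positive means the
#' native identity is much more favorable than typical decoys (minimally
#' frustrated), strongly negative means it is worse (highly frustrated).
#'
#' @param structure a \code{pdb_structure}.
#' @param i residue index (1-based into the structure's residue list).
#' @param potential 20x20 symmetric contact energy matrix.
#' @param n_decoys number of decoy draws (default 1000).
#' @param seed integer seed (local RNG; does not disturb the global stream).
#' @param contacts optional precomputed [contact_map] (recomputed otherwise).
#' @param exhaustive if TRUE, enumerate all 19 substitutions exactly instead
#'   of Monte-Carlo sampling (then \code{n_decoys}/\code{seed} are ignored
#'   and the decoy sd is the population sd of the 19-point distribution).
#' @return list of class \code{frustration_result}: \code{residue},
#'   \code{native_energy}, \code{decoy_mean}, \code{decoy_sd}, \code{index},
#'   \code{n_decoys}, \code{flag} ("" or "ZeroContact").
#' @export
residue_frustration <- function(structure, i, potential = default_contact_potential(),
                                n_decoys = 1000, seed = 1, contacts = NULL,
                                exhaustive = FALSE) {
  if (max(abs(potential - t(potential))) > 1e-9) {
    stop_setphen("potential must be symmetric", class = "setphen_argument_error")
  }
  if (is.null(contacts)) contacts <- contact_map(structure)
  aa <- structure$residues$aa
  partners <- c(contacts$j[contacts$i == i], contacts$i[contacts$j == i])
  res <- list(residue = i, native_energy = 0, decoy_mean = NA_real_,
              decoy_sd = NA_real_, index = 0, n_decoys = 0L, flag = "")
  class(res) <- "frustration_result"
  if (length(partners) == 0L) {
    res$flag <- "ZeroContact"
    return(res)
  }
  partner_aas <- aa[partners]
  e_native <- .residue_energy(aa[i], partner_aas, potential)
  alternatives <- setdiff(AA_ONE, aa[i])
  # energy of each of the 19 possible decoy identities
  e_alt <- vapply(alternatives, .residue_energy, numeric(1),
                  partner_aas = partner_aas, potential = potential)
  if (exhaustive) {
    mu <- mean(e_alt)
    sdv <- sqrt(mean((e_alt - mu)^2))
    nd <- 19L
  } else {
    old <- .Random.seed_exists()
    set.seed(seed)
    pick <- sample.int(19L, n_decoys, replace = TRUE)
    .restore_seed(old)
    draws <- e_alt[pick]
    mu <- mean(draws)
    sdv <- stats::sd(draws)
    nd <- as.integer(n_decoys)
  }
  if (!is.finite(sdv) || sdv <= 0) {
    stop_setphen("degenerate decoy ensemble (zero energy spread) at residue %d",
                 i, class = "setphen_degenerate_decoys")
  }
  res$native_energy <- e_native
  res$decoy_mean <- mu
  res$decoy_sd <- sdv
  res$index <- (mu - e_native) / sdv
  res$n_decoys <- nd
  res
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Per-residue frustration profile with summary fractions
#'
#' @inheritParams residue_frustration
#' @return list of class \code{frustration_profile}: \code{table}
#'   (data.frame: residue, aa, native_energy, decoy_mean, decoy_sd, index,
#'   n_contacts, flag, effect), \code{fraction_highly},
#'   \code{fraction_minimally} (per the -1.0 / +0.78 cutoffs), \code{seed}.
#' @export
frustration_profile <- function(structure, potential = default_contact_potential(),
                                n_decoys = 1000, seed = 1, exhaustive = FALSE) {
  n <- nrow(structure$residues)
  if (n == 0L) {
    stop_setphen("empty structure", class = "setphen_argument_error")
  }
  contacts <- contact_map(structure)
  rows <- lapply(seq_len(n), function(i) {
    r <- residue_frustration(structure, i, potential, n_decoys,
                             seed = seed + i, contacts = contacts,
                             exhaustive = exhaustive)
    nc <- sum(contacts$i == i | contacts$j == i)
    data.frame(residue = i, aa = structure$residues$aa[i],
               native_energy = r$native_energy, decoy_mean = r$decoy_mean,
               decoy_sd = r$decoy_sd, index = r$index, n_contacts = nc,
               flag = r$flag,
               effect = classify_frustration(r$index),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  out <- list(table = tab,
              fraction_highly = mean(tab$effect == "HighlyFrustrated"),
              fraction_minimally = mean(tab$effect == "MinimallyFrustrated"),
              seed = seed)
  class(out) <- "frustration_profile"
  out
}

#' @export
print.frustration_profile <- function(x, ...) {
  cat(sprintf("Frustration profile: %d residues; %.0f%% highly, %.0f%% minimally frustrated\n",
              nrow(x$table), 100 * x$fraction_highly, 100 * x$fraction_minimally))
  invisible(x)
}
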