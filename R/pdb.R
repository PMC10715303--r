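# Structure and trajectory containers plus PDB input/output (via bio3d).
#
# A `pdb_structure` is a list:
#   residues: data.frame(chain, resno, aa)        -- aa is one-letter
#   atoms:    data.frame(res_index, name, element, x, y, z, o, b)
# A `md_trajectory` adds:
#   frames: n_frames x (3*n_atoms) coordinate matrix (bio3d xyz layout)
#   frame_interval: ps between stored frames

new_structure <- function(residues, atoms) {
  stopifnot(all(atoms$res_index >= 1), all(atoms$res_index <= nrow(residues)))
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop_setphen("non-finite coordinates", class = "setphen_format_error")
  }
  key <- paste(residues$chain, residues$resno)
  if (anyDuplicated(key)) {
    stop_setphen("duplicated residue number within a chain",
                 class = "setphen_format_error")
  }
  structure(list(residues = residues, atoms = atoms), class = "pdb_structure")
}

new_trajectory <- function(topology, frames, frame_interval = 10) {
  stopifnot(inherits(topology, "pdb_structure"), frame_interval > 0)
  frames <- as.matrix(frames)
  if (ncol(frames) != 3L * nrow(topology$atoms)) {
    stop_setphen("frame width %d does not match 3 x %d atoms",
                 ncol(frames), nrow(topology$atoms),
                 class = "setphen_format_error")
  }
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval),
            class = "md_trajectory")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("pdb_structure: %d residues, %d atoms\n",
              nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms (%g ps/frame)\n",
              nrow(x$frames), nrow(x$topology$atoms), x$frame_interval))
  invisible(x)
}

AA3_LOOKUP <- stats::setNames(names(AA_THREE), toupper(AA_THREE))

#' Read a PDB file as a structure or trajectory
#'
#' ATOM/HETATM records are parsed (via bio3d); a multi-MODEL file yields an
#' \code{md_trajectory} whose topology is the first MODEL.
#'
#' @param path PDB file.
#' @param frame_interval ps per stored frame for multi-MODEL files.
#' @return \code{pdb_structure} (single model) or \code{md_trajectory}.
#' @export
read_pdb <- function(path, frame_interval = 10) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop_setphen("empty or missing PDB file: %s", path, class = "setphen_io_error")
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) {
                    stop_setphen("PDB parse error in %s: %s", path,
                                 conditionMessage(e), class = "setphen_parse_error")
                  })
  at <- pdb$atom
  rk <- paste(at$chain, at$resno, at$insert %||% "")
  res_index <- match(rk, unique(rk))
  first <- !duplicated(rk)
  aa <- unname(AA3_LOOKUP[toupper(at$resid[first])])
  aa[is.na(aa)] <- "X"   # hetero groups / nonstandard residues
  residues <- data.frame(chain = at$chain[first], resno = at$resno[first],
                         aa = aa, stringsAsFactors = FALSE)
  atoms <- data.frame(res_index = res_index, name = at$elety,
                      element = ifelse(is.na(at$elesy) | at$elesy == "",
                                       substr(trimws(at$elety), 1, 1), at$elesy),
                      x = at$x, y = at$y, z = at$z,
                      o = at$o, b = at$b, stringsAsFactors = FALSE)
  s <- new_structure(residues, atoms)
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1L) {
    return(new_trajectory(s, xyz, frame_interval))
  }
  s
}

#' Write a structure to PDB, optionally with per-residue B-factors
#'
#' @param structure \code{pdb_structure}.
#' @param path output path.
#' @param b_residue optional numeric vector (one value per residue), written
#'   into the B-factor column of every atom of that residue -- the usual way
#'   to carry per-residue RMSF values into visualization software.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(structure, path, b_residue = NULL) {
  at <- structure$atoms
  res <- structure$residues
  b <- at$b
  if (!is.null(b_residue)) {
    stopifnot(length(b_residue) == nrow(res))
    b <- b_residue[at$res_index]
  }
  resid3 <- toupper(AA_THREE[res$aa[at$res_index]])
  resid3[is.na(resid3)] <- "UNK"
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = res$resno[at$res_index],
                   resid = resid3, chain = res$chain[at$res_index],
                   elety = at$name, o = at$o %||% 1, b = b)
  invisible(path)
}

# --- atom selections -------------------------------------------------------

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Atom-index selection masks
#'
#' @param structure \code{pdb_structure}.
#' @param selection "backbone" (N, CA, C, O), "CA", "heavy" (non-hydrogen),
#'   "all", or a character vector of atom names.
#' @return integer atom indices.
#' @export
select_atoms <- function(structure, selection = "backbone") {
  at <- structure$atoms
  if (length(selection) == 1L && selection %in% c("backbone", "CA", "heavy", "all")) {
    idx <- switch(selection,
                  backbone = which(at$name %in% BACKBONE_NAMES),
                  CA = which(at$name == "CA"),
                  heavy = which(toupper(at$element) != "H"),
                  all = seq_len(nrow(at)))
  } else {
    idx <- which(at$name %in% selection)
  }
  if (length(idx) == 0L) {
    stop_setphen("selection '%s' matches no atoms",
                 paste(selection, collapse = ","), class = "setphen_argument_error")
  }
  idx
}

# frame f of a trajectory as an n_atoms x 3 matrix
frame_coords <- function(trajectory, f) {
  matrix(trajectory$frames[f, ], ncol = 3, byrow = TRUE)
}

structure_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}
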