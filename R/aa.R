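# Amino-acid code tables used across the package.

#' The twenty standard amino acids, one-letter codes
#' @export
AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

#' Convert a three-letter amino-acid code to one-letter
#'
#' @param code character vector of three-letter codes (any case).
#' @return one-letter codes.
#' @export
aa3_to_aa1 <- function(code) {
  key <- paste0(toupper(substr(code, 1, 1)), tolower(substr(code, 2, 3)))
  idx <- match(key, AA_THREE)
  if (anyNA(idx)) {
    bad <- code[is.na(idx)][1]
    stop_setphen("unknown amino-acid residue code: '%s'", bad,
                 class = "setphen_residue_error")
  }
  names(AA_THREE)[idx]
}

# Kyte-Doolittle hydropathy; basis of the packaged synthetic contact potential.
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
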