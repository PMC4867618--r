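#' Random-coil Ca/Cb reference chemical shifts
#'
#' Wishart-style random-coil values (ppm) for the 20 standard residues,
#' referenced to DSS. Glycine has no Cb. The set can be swapped for any
#' data.frame with columns `resname`, `CA`, `CB` when forming secondary
#' shifts.
#'
#' @return data.frame with columns `resname` (3-letter code), `CA`, `CB`.
#' @export
random_coil_table <- function() {
  rc <- data.frame(
    resname = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                "THR", "TRP", "TYR", "VAL"),
    CA = c(52.5, 56.0, 52.8, 54.2, 58.2, 55.7, 56.6, 45.1,
           55.0, 61.1, 55.1, 56.2, 55.4, 57.7, 63.3, 58.3,
           61.8, 57.5, 57.9, 62.2),
    CB = c(19.1, 30.9, 37.9, 41.1, 28.0, 29.4, 29.9, NA,
           29.0, 38.8, 42.4, 33.1, 32.9, 39.6, 32.1, 63.8,
           69.8, 29.6, 38.8, 32.9),
    stringsAsFactors = FALSE)
  rc
}

aa1to3 <- function(seq1) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  out <- map[strsplit(toupper(seq1), "")[[1L]]]
  if (any(is.na(out))) stop("unknown one-letter residue code in sequence")
  unname(out)
}
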