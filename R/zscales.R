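#' Five-dimensional amino-acid z-scale descriptors
#'
#' The extended z-scales of Sandberg et al. (1998, J. Med. Chem. 41,
#' 2481-2491): five orthogonal physicochemical scores per residue
#' derived from a principal-component analysis of 26 measured and
#' computed property variables. z1 tracks hydrophobicity, z2 steric
#' bulk/polarizability, z3 polarity, z4 and z5 electronic effects.
#' Dimensionless.
#'
#' The table is returned (rather than hard-wired into the transform) so
#' alternative descriptor sets can be injected into [acc_transform()].
#'
#' @return A 20 x 5 numeric matrix, rownames the amino-acid letters,
#'   colnames `z1`..`z5`.
#' @export
zscale_table <- function() {
  tab <- rbind(
    A = c( 0.24, -2.32,  0.60, -0.14,  1.30),
    R = c( 3.52,  2.50, -3.50,  1.99, -0.17),
    N = c( 3.05,  1.62,  1.04, -1.15,  1.61),
    D = c( 3.98,  0.93,  1.93, -2.46,  0.75),
    C = c( 0.84, -1.67,  3.71,  0.18, -2.65),
    Q = c( 1.75,  0.50, -1.44, -1.34,  0.66),
    E = c( 3.11,  0.26, -0.11, -3.04, -0.25),
    G = c( 2.05, -4.06,  0.36, -0.82, -0.38),
    H = c( 2.47,  1.95,  0.26,  3.90,  0.09),
    I = c(-3.89, -1.73, -1.71, -0.84,  0.26),
    L = c(-4.28, -1.30, -1.49, -0.72,  0.84),
    K = c( 2.29,  0.89, -2.49,  1.49,  0.31),
    M = c(-2.85, -0.22,  0.47,  1.94, -0.98),
    F = c(-4.22,  1.94,  1.06,  0.54, -0.62),
    P = c(-1.66,  0.27,  1.84,  0.70,  2.00),
    S = c( 2.39, -1.07,  1.15, -1.39,  0.67),
    T = c( 0.75, -2.18, -1.12, -1.46, -0.40),
    W = c(-4.36,  3.94,  0.59,  3.44, -1.59),
    Y = c(-2.54,  2.44,  0.43,  0.04, -1.47),
    V = c(-2.59, -2.64, -1.54, -0.85, -0.02))
  colnames(tab) <- paste0("z", 1:5)
  tab[aa_alphabet(), , drop = FALSE]
}

check_zscale_table <- function(table) {
  if (!is.matrix(table) || ncol(table) != 5 || !all(is.finite(table)))
    stop("z-scale table must be a numeric matrix with 5 finite columns")
  if (!setequal(rownames(table), aa_alphabet()))
    stop("z-scale table must have exactly the 20 standard amino acids as rows")
  table[aa_alphabet(), , drop = FALSE]
}
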