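# Amino-acid reference data: alphabet, heavy-atom counts, element masses,
# and loaders for the pairwise parameter tables (contact energies U, optimal
# contact distances d). Tables are plain TSV so users can substitute their own.

#' The 20-letter amino-acid alphabet
#'
#' One-letter codes in alphabetical order. This ordering is the canonical
#' internal ordering of every 20-vector and 20x20 matrix in the package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# three-letter -> one-letter, including common non-standard mappings
# (MSE selenomethionine -> M etc.); anything absent is dropped with a warning.
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S",
  TPO = "T", PTR = "Y", CSO = "C", MLY = "K", M3L = "K"
)

# heavy (non-hydrogen) atom count per amino acid, backbone included
.aa_size <- c(
  A = 5, C = 6, D = 8, E = 9, F = 11, G = 4, H = 10, I = 8, K = 9, L = 8,
  M = 8, N = 8, P = 7, Q = 9, R = 11, S = 6, T = 7, V = 7, W = 14, Y = 12
)

# Kyte-Doolittle hydropathy (used only to construct the synthetic U table)
.aa_kd <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

.elem_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, SE = 78.971)

#' Heavy-atom counts per amino acid
#'
#' Number of non-hydrogen atoms of each amino acid (backbone plus side chain),
#' the size term s(a) of the mutation-force model.
#'
#' @return Named integer vector over [aa_alphabet()].
#' @export
aa_sizes <- function() .aa_size[aa_alphabet()]

.check_aa_table <- function(M, what) {
  aa <- aa_alphabet()
  if (!all(aa %in% rownames(M)) || !all(aa %in% colnames(M)))
    stop(what, " table must have the 20 amino acids as row and column names")
  M <- as.matrix(M[aa, aa])
  if (max(abs(M - t(M))) > 1e-8)
    stop(what, " table must be symmetric")
  M
}

#' Read a 20x20 symmetric amino-acid pair table from TSV
#'
#' @param path TSV file with amino-acid one-letter row and column names.
#' @param what Label used in error messages.
#' @return 20x20 symmetric numeric matrix in alphabet order.
#' @export
read_pair_table <- function(path, what = "pair") {
  M <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  .check_aa_table(M, what)
}

#' Default contact-energy table U(a,b)
#'
#' A synthetic stand-in for a statistical contact potential, constructed from
#' hydrophobicity products so that hydrophobic pairs form stabilizing
#' (negative) contacts and polar pairs are weakly repulsive. Shipped as
#' \code{inst/extdata/contact_energies_synthetic.tsv}; replace via
#' \code{read_pair_table()} for production use with a fitted potential.
#'
#' @return 20x20 symmetric matrix (k_BT units).
#' @export
default_energy_table <- function() {
  read_pair_table(system.file("extdata", "contact_energies_synthetic.tsv",
                              package = "sscpe"), "contact energy")
}

#' Default optimal contact-distance table d(a,b)
#'
#' Synthetic stand-in built from heavy-atom-count radii
#' (d = 2.0 + 0.55 (s_a^{1/3} + s_b^{1/3}) Angstrom); shipped as
#' \code{inst/extdata/contact_distances_synthetic.tsv}.
#'
#' @return 20x20 symmetric matrix (Angstrom).
#' @export
default_distance_table <- function() {
  read_pair_table(system.file("extdata", "contact_distances_synthetic.tsv",
                              package = "sscpe"), "contact distance")
}

#' Mutation-force model parameters
#'
#' Weights of the three force components (amino-acid size, contact stability,
#' optimal contact distance), the distance exponent g and length scale R0, the
#' per-amino-acid heavy-atom counts, and the two pair tables. The default
#' weights are the published fitted values W_size = 3.05, W_stab = 2.39,
#' W_dist = 15.6, with g = 2 and R0 = 3.25 Angstrom.
#'
#' @param W_size,W_stab,W_dist Component weights.
#' @param g Distance exponent in the force kernel 1/|r|^(1+g).
#' @param R0 Length scale (Angstrom); the K R0^g prefactor keeps the typical
#'   deformation roughly independent of g.
#' @param K Overall elastic force constant (arbitrary units).
#' @param size_table Named vector of heavy-atom counts.
#' @param U 20x20 contact energy table.
#' @param d 20x20 optimal-distance table.
#' @return Object of class \code{mutation_parameters}.
#' @export
mutation_parameters <- function(W_size = 3.05, W_stab = 2.39, W_dist = 15.6,
                                g = 2, R0 = 3.25, K = 1,
                                size_table = aa_sizes(),
                                U = default_energy_table(),
                                d = default_distance_table()) {
  stopifnot(g >= 0, R0 > 0, K > 0, all(size_table > 0))
  structure(list(W_size = W_size, W_stab = W_stab, W_dist = W_dist,
                 g = g, R0 = R0, K = K,
                 size_table = size_table[aa_alphabet()],
                 U = .check_aa_table(U, "U"),
                 d = .check_aa_table(d, "d")),
            class = "mutation_parameters")
}

#' Stability-model parameters
#'
#' Contact-energy table plus the entropic constants of the unfolded and
#' compact (misfolded) ensembles, in units where k_B T = 1. The numeric
#' defaults are shipped order-of-magnitude values; no result in the package's
#' tests depends on them, only on limits and oracle identities.
#'
#' @param U 20x20 contact energy table.
#' @param S_U Conformational entropy per residue of the unfolded chain.
#' @param S_C Log number of compact contact matrices per residue.
#' @param use_misfold If FALSE the misfolded ensemble is disabled and
#'   Delta G = G_nat + L S_U (the hydrophilic limit).
#' @return Object of class \code{stability_parameters}.
#' @export
stability_parameters <- function(U = default_energy_table(),
                                 S_U = 0.2, S_C = 0.03, use_misfold = TRUE) {
  stopifnot(S_U > 0, S_C > 0)
  structure(list(U = .check_aa_table(U, "U"), S_U = S_U, S_C = S_C,
                 use_misfold = isTRUE(use_misfold)),
            class = "stability_parameters")
}
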