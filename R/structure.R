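# Protein structures and contact maps.
#
# A `protein_structure` holds the structured residues of one chain with all
# heavy-atom coordinates. Contact maps come in two flavors sharing the same
# closest-heavy-atom distance cutoff (default 4.5 A):
#   * "enm":       all contacts, used by the elastic network;
#   * "stability": contacts with sequence separation |i-j| <= 2 removed, used
#                  by the contact free-energy model (short-range contacts are
#                  formed in essentially every compact conformation, so they
#                  cancel in native-vs-misfolded free energy differences).

#' Construct a protein structure from residue/atom data
#'
#' Usually created by [load_structure()] or [make_backbone()].
#'
#' @param seq Character vector of one-letter residue codes (length L >= 3).
#' @param atoms Data frame with columns \code{res} (1-based residue index),
#'   \code{name} (atom name, e.g. "CA"), \code{elem} (element symbol),
#'   \code{x,y,z} (Angstrom).
#' @param chain Chain identifier.
#' @param resno_orig Original residue numbers for reporting (default 1..L).
#' @return Object of class \code{protein_structure}.
#' @export
protein_structure <- function(seq, atoms, chain = "A", resno_orig = NULL) {
  L <- length(seq)
  if (L < 3) stop("structure must have at least 3 residues")
  if (!all(seq %in% aa_alphabet()))
    stop("unknown amino-acid codes: ",
         paste(unique(seq[!seq %in% aa_alphabet()]), collapse = ","))
  atoms <- as.data.frame(atoms)
  need <- c("res", "name", "elem", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  mass <- .elem_mass[toupper(atoms$elem)]
  if (anyNA(mass)) stop("unknown element(s): ",
                        paste(unique(atoms$elem[is.na(mass)]), collapse = ","))
  atoms$mass <- unname(mass)
  if (is.null(resno_orig)) resno_orig <- seq_len(L)
  structure(list(seq = seq, n = L, atoms = atoms, chain = chain,
                 resno_orig = resno_orig),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: %d residues, %d heavy atoms, chain %s\n",
              x$n, nrow(x$atoms), x$chain))
  invisible(x)
}

#' Load a single-chain protein structure from a PDB file
#'
#' Parses ATOM records of the requested chain (first model only), keeps all
#' heavy atoms at the highest-occupancy alternate location, maps common
#' non-standard residues (e.g. MSE to MET) and drops unmapped residues and
#' residues missing any backbone atom (N, CA, C), with a warning.
#'
#' @param path PDB file.
#' @param chain Chain identifier; default first chain in the file.
#' @return A \code{protein_structure}.
#' @export
load_structure <- function(path, chain = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  # heavy atoms only
  at <- at[!(toupper(at$elesy) %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0) stop("no standard residues found in chain ", chain)
  # alternate locations: keep highest occupancy per (resno, insert, atom name)
  key <- paste(at$resno, at$insert, at$elety)
  keep <- !duplicated(key[order(-at$o)])
  at <- at[order(-at$o), ][keep, ]
  at <- at[order(at$resno, at$insert, na.last = FALSE), ]
  rkey <- paste(at$resno, at$insert)
  res_ids <- unique(rkey)
  res3 <- at$resid[match(res_ids, rkey)]
  res1 <- .aa3to1[res3]
  drop_unk <- is.na(res1)
  if (any(drop_unk))
    warning("dropping ", sum(drop_unk), " unmapped residue(s): ",
            paste(unique(res3[drop_unk]), collapse = ","))
  # backbone completeness
  has_bb <- vapply(res_ids, function(k) {
    nm <- at$elety[rkey == k]
    all(c("N", "CA", "C") %in% nm)
  }, TRUE)
  if (any(!has_bb & !drop_unk))
    warning("dropping ", sum(!has_bb & !drop_unk),
            " residue(s) with missing backbone atoms")
  ok <- !drop_unk & has_bb
  if (sum(ok) == 0) stop("no standard residues with complete backbone")
  res_ids <- res_ids[ok]
  at <- at[rkey %in% res_ids, , drop = FALSE]
  ridx <- match(paste(at$resno, at$insert), res_ids)
  elem <- toupper(at$elesy)
  elem[!nzchar(elem) | is.na(elem)] <- substr(at$elety[!nzchar(elem) | is.na(elem)], 1, 1)
  atoms <- data.frame(res = ridx, name = at$elety, elem = elem,
                      x = at$x, y = at$y, z = at$z)
  protein_structure(unname(res1[ok]), atoms, chain = chain,
                    resno_orig = at$resno[match(res_ids, paste(at$resno, at$insert))])
}

#' Write a structure as PDB text
#'
#' Fixed-width ATOM records; used for generated fixtures.
#'
#' @param s A \code{protein_structure}.
#' @param path Output file.
#' @export
write_structure_pdb <- function(s, path) {
  aa1to3 <- names(.aa3to1)[match(aa_alphabet(), .aa3to1)]
  names(aa1to3) <- aa_alphabet()
  con <- file(path, "w")
  on.exit(close(con))
  a <- s$atoms
  for (i in seq_len(nrow(a))) {
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, ifelse(nchar(a$name[i]) < 4, paste0(" ", a$name[i]), a$name[i]),
      aa1to3[s$seq[a$res[i]]], s$chain, a$res[i],
      a$x[i], a$y[i], a$z[i], 1, 0, a$elem[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Build a contact map from a structure
#'
#' Two residues are in contact when their closest heavy atoms are closer than
#' \code{cutoff} (4.5 A). The stability flavor additionally removes contacts
#' with sequence separation \code{|i-j| <= min_seqsep - 1} (default: removes
#' separations up to 2). For each contact the closest atom pair, its vector
#' r_i' - r_j' and the distance are recorded.
#'
#' @param s A \code{protein_structure}.
#' @param flavor "enm" or "stability".
#' @param cutoff Distance cutoff in Angstrom.
#' @param min_seqsep Minimum |i-j| retained by the stability flavor.
#' @return Object of class \code{contact_map} with elements \code{C}
#'   (L x L 0/1 matrix), \code{pairs} (data frame i, j, ai, aj, dist, vx, vy,
#'   vz with i < j; ai/aj are row indices into \code{s$atoms}), \code{flavor},
#'   \code{cutoff}.
#' @export
build_contact_map <- function(s, flavor = c("enm", "stability"),
                              cutoff = 4.5, min_seqsep = 3) {
  flavor <- match.arg(flavor)
  L <- s$n
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  res <- s$atoms$res
  # cell-list free O(L^2) residue pruning via residue bounding spheres
  cen <- rowsum(xyz, res) / as.vector(table(res))
  rad <- vapply(seq_len(L), function(i) {
    d <- xyz[res == i, , drop = FALSE]
    sqrt(max(rowSums((d - rep(cen[i, ], each = nrow(d)))^2)))
  }, 0)
  C <- matrix(0L, L, L)
  plist <- vector("list", L * 4L)
  np <- 0L
  for (i in seq_len(L - 1L)) {
    ii <- which(res == i)
    for (j in (i + 1L):L) {
      if (flavor == "stability" && (j - i) < min_seqsep) next
      if (sqrt(sum((cen[i, ] - cen[j, ])^2)) - rad[i] - rad[j] >= cutoff) next
      jj <- which(res == j)
      d2 <- outer(rowSums(xyz[ii, , drop = FALSE]^2),
                  rowSums(xyz[jj, , drop = FALSE]^2), `+`) -
        2 * tcrossprod(xyz[ii, , drop = FALSE], xyz[jj, , drop = FALSE])
      k <- arrayInd(which.min(d2), dim(d2))
      dmin <- sqrt(max(d2[k], 0))
      if (dmin < cutoff) {
        C[i, j] <- C[j, i] <- 1L
        ai <- ii[k[1]]; aj <- jj[k[2]]
        np <- np + 1L
        plist[[np]] <- c(i, j, ai, aj, dmin,
                         xyz[ai, 1] - xyz[aj, 1],
                         xyz[ai, 2] - xyz[aj, 2],
                         xyz[ai, 3] - xyz[aj, 3])
      }
    }
  }
  pairs <- if (np > 0) {
    m <- do.call(rbind, plist[seq_len(np)])
    data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
               ai = as.integer(m[, 3]), aj = as.integer(m[, 4]),
               dist = m[, 5], vx = m[, 6], vy = m[, 7], vz = m[, 8])
  } else {
    data.frame(i = integer(), j = integer(), ai = integer(), aj = integer(),
               dist = numeric(), vx = numeric(), vy = numeric(), vz = numeric())
  }
  structure(list(C = C, pairs = pairs, flavor = flavor, cutoff = cutoff,
                 min_seqsep = min_seqsep),
            class = "contact_map")
}

#' Per-site contact counts
#'
#' n_i = row sums of the contact matrix.
#'
#' @param cm A \code{contact_map} (or a bare 0/1 matrix).
#' @return Integer vector of length L.
#' @export
contact_counts <- function(cm) {
  C <- if (inherits(cm, "contact_map")) cm$C else cm
  as.integer(rowSums(C))
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map (%s): %d residues, %d contacts, cutoff %.2f A\n",
              x$flavor, nrow(x$C), nrow(x$pairs), x$cutoff))
  invisible(x)
}
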