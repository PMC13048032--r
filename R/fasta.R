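# Minimal aligned-FASTA I/O. The package works on protein MSAs held as plain
# character matrices (rows = sequences, columns = alignment columns, gap "-").

#' Read an aligned protein FASTA file
#'
#' @param path FASTA file; all sequences must have equal aligned length.
#' @return Character matrix (sequences x columns) with sequence names as
#'   row names; letters upper-cased, gaps "-" ("." converted to "-").
#' @export
read_fasta_msa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- vapply(strsplit(names_, "\\s+"), `[`, "", 1)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  seqs <- toupper(gsub("[. ]", "-", seqs))
  n <- nchar(seqs)
  if (length(unique(n)) != 1)
    stop("sequences have unequal aligned lengths")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- make.unique(names_)
  m
}

#' Write an aligned protein MSA as FASTA
#'
#' @param msa Character matrix as returned by [read_fasta_msa()].
#' @param path Output file.
#' @param width Line width.
#' @export
write_fasta_msa <- function(msa, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(msa))) {
    s <- paste(msa[i, ], collapse = "")
    writeLines(paste0(">", rownames(msa)[i]), con)
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# ungapped sequence of one MSA row
.degap <- function(x) x[x != "-"]
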