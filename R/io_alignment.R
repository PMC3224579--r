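#' Construct a domain alignment
#'
#' A `domain_alignment` holds an MSA of peptide-recognition-domain sequences
#' as an n x m character matrix over the 20 canonical amino acids plus the
#' gap symbol `-`, with unique sequence identifiers as row names.
#'
#' @param seqs Character vector of aligned sequences (equal length), or an
#'   n x m character matrix of single residues.
#' @param ids Character vector of unique, non-empty sequence identifiers.
#' @return An object of class `domain_alignment`: the residue matrix with
#'   row names `ids`.
#' @export
domain_alignment <- function(seqs, ids = names(seqs)) {
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(ids)) ids <- rownames(mat)
  } else {
    if (length(seqs) < 1L) stop_sdr("alignment must contain at least one sequence")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- if (!is.null(ids)) ids[which(lens != lens[1L])[1L]] else which(lens != lens[1L])[1L]
      stop_sdr("ragged alignment: sequence '%s' has length %d, expected %d",
               bad, lens[lens != lens[1L]][1L], lens[1L], class = "sdrcov_alignment_length_error")
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  n <- nrow(mat)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n || anyDuplicated(ids) || any(!nzchar(ids)))
    stop_sdr("sequence ids must be unique, non-empty and match the number of rows")
  mat <- toupper(mat)
  mat[mat == "."] <- GAP
  bad <- which(!(mat %in% c(AA20, GAP)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(mat))
    stop_sdr("illegal character '%s' in sequence '%s' at site %d",
             mat[bad[1L]], ids[i[1L]], i[2L], class = "sdrcov_parse_error")
  }
  dimnames(mat) <- list(ids, NULL)
  structure(mat, class = "domain_alignment")
}

#' @export
print.domain_alignment <- function(x, ...) {
  cat(sprintf("domain_alignment: %d sequences x %d sites\n", nrow(x), ncol(x)))
  show <- utils::head(rownames(x), 6L)
  for (id in show)
    cat(sprintf("  %-12s %s\n", id, paste(utils::head(x[id, ], 60L), collapse = "")))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Alignment dimensions
#' @param aln A `domain_alignment`.
#' @return Number of sequences (`n_seqs`) or sites (`n_sites`).
#' @export
n_seqs <- function(aln) nrow(aln)

#' @rdname n_seqs
#' @export
n_sites <- function(aln) ncol(aln)

#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment in FASTA format.  Lowercase residues
#' are upper-cased and the gap alias `.` is normalised to `-`.  All rows
#' must have identical length; characters outside the 20 canonical amino
#' acids plus gap are rejected.
#'
#' @param path Path to an aligned FASTA file with at least one record.
#' @return A [domain_alignment].
#' @examples
#' aln <- read_alignment(system.file("extdata", "toy_msa.fa",
#'                                   package = "sdrcov"))
#' n_seqs(aln)
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop_sdr("alignment file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 1L) stop_sdr("no FASTA records in %s", path)
  seqs <- as.character(ss)
  ids <- sub("\\s.*$", "", names(ss))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1L])[1L]
    stop_sdr("ragged alignment in %s: sequence '%s' has length %d, expected %d",
             path, ids[off], lens[off], lens[1L], class = "sdrcov_alignment_length_error")
  }
  domain_alignment(seqs, ids)
}

#' Write an alignment to FASTA
#'
#' @param aln A [domain_alignment].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(aln)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
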