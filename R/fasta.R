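#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased and RNA-style U residues are normalised to T.
#' Record identifiers are the first whitespace-delimited token of each
#' header.  Duplicate identifiers and empty files are errors.
#'
#' @param path path to a FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[[1]])
  seqs <- chartr("U", "T", toupper(as.character(set)))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line width for wrapping
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (length(seqs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}
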