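# small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#'
#' Ambiguity code N is preserved; the input must be an upper-case DNA string.
#'
#' @param x character scalar
#' @return character scalar
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# random DNA with a given AT fraction, using the session RNG
rand_dna <- function(n, at = 0.5) {
  if (n <= 0) return("")
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# in-frame premature termination codon scan: i0 is the 0-based offset of the
# first complete codon inside the intron, set by the host reading frame
has_ptc <- function(intron_seq, cds_offset) {
  n <- nchar(intron_seq)
  i0 <- (3L - cds_offset %% 3L) %% 3L
  if (n - i0 < 3L) return(FALSE)
  starts <- seq.int(i0 + 1L, n - 2L, by = 3L)
  codons <- substring(intron_seq, starts, starts + 2L)
  any(codons %in% STOP_CODONS)
}

# does a CDS read as a single open reading frame?
is_orf <- function(cds) {
  n <- nchar(cds)
  if (n < 6L || n %% 3L != 0L) return(FALSE)
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  substr(cds, 1L, 3L) == "ATG" &&
    codons[length(codons)] %in% STOP_CODONS &&
    !any(codons[-length(codons)] %in% STOP_CODONS)
}

# stable short hash of a configuration list (used to stamp output files)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(substr(tools::md5sum(f), 1L, 12L))
}

write_tsv_stamped <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config: ", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_stamped <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
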