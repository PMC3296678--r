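#' Construct a gene model with explicit intron records
#'
#' A gene model describes one protein-coding gene in one species: its CDS
#' exon intervals on the genome (0-based, half-open, in transcription
#' order), the spliced strand-corrected coding sequence, and one intron
#' record per exon-exon junction.  Intron records carry the position of the
#' intron in CDS coordinates (`cds_offset`, the CDS position immediately 3'
#' of the intron), the intron sequence in transcription orientation, and the
#' terminal donor/acceptor dinucleotides.
#'
#' @param gene_id,species,seq_region identifiers
#' @param strand "+" or "-"
#' @param cds_exons integer matrix with columns `start`, `end` (0-based,
#'   half-open), rows in transcription order
#' @param cds_seq spliced coding sequence (transcription orientation)
#' @param introns data.frame with columns `index`, `cds_offset`,
#'   `length_nt`, `seq`, `donor2`, `acceptor2`
#' @param frame_ok FALSE flags a CDS whose length is not divisible by 3
#' @return object of class `gene_model`
#' @export
gene_model <- function(gene_id, species, seq_region, strand, cds_exons,
                       cds_seq, introns, frame_ok = TRUE) {
  gm <- structure(list(gene_id = gene_id, species = species,
                       seq_region = seq_region, strand = strand,
                       cds_exons = cds_exons, cds_seq = cds_seq,
                       introns = introns, frame_ok = frame_ok),
                  class = "gene_model")
  validate_gene_model(gm)
  gm
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s strand %s: CDS %d nt, %d introns\n",
              x$gene_id, x$species, x$seq_region, x$strand,
              nchar(x$cds_seq), nrow(x$introns)))
  invisible(x)
}

validate_gene_model <- function(gm) {
  stopifnot(gm$strand %in% c("+", "-"))
  n_ex <- nrow(gm$cds_exons)
  if (nchar(gm$cds_seq) < 3L) stop("CDS shorter than one codon: ", gm$gene_id)
  widths <- gm$cds_exons[, "end"] - gm$cds_exons[, "start"]
  if (any(widths <= 0L)) stop("empty CDS exon in ", gm$gene_id)
  if (sum(widths) != nchar(gm$cds_seq))
    stop("exon widths do not sum to CDS length in ", gm$gene_id)
  ir <- gm$introns
  if (nrow(ir) != n_ex - 1L)
    stop("intron count must be exon count - 1 in ", gm$gene_id)
  if (nrow(ir)) {
    if (any(diff(ir$cds_offset) <= 0L))
      stop("intron cds_offsets not strictly increasing in ", gm$gene_id)
    if (any(ir$cds_offset <= 0L) || any(ir$cds_offset >= nchar(gm$cds_seq)))
      stop("intron cds_offset outside CDS in ", gm$gene_id)
    if (any(ir$length_nt != nchar(ir$seq)))
      stop("intron length_nt disagrees with seq in ", gm$gene_id)
    if (any(ir$donor2 != substr(ir$seq, 1L, 2L)) ||
        any(ir$acceptor2 != substring(ir$seq, ir$length_nt - 1L)))
      stop("donor/acceptor dinucleotides disagree with seq in ", gm$gene_id)
    # offsets must coincide with cumulative exon lengths
    expected <- cumsum(widths)[seq_len(n_ex - 1L)]
    if (any(ir$cds_offset != expected))
      stop("intron offsets do not match exon boundaries in ", gm$gene_id)
  }
  invisible(gm)
}

intron_frame <- function(cds_offset) (3L - cds_offset %% 3L) %% 3L

make_intron_df <- function(offsets, seqs) {
  offsets <- as.integer(offsets)
  if (length(offsets) == 0L) {
    return(data.frame(index = integer(), cds_offset = integer(),
                      length_nt = integer(), seq = character(),
                      donor2 = character(), acceptor2 = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(index = seq_along(offsets) - 1L,
             cds_offset = offsets,
             length_nt = nchar(seqs),
             seq = seqs,
             donor2 = substr(seqs, 1L, 2L),
             acceptor2 = substring(seqs, nchar(seqs) - 1L),
             stringsAsFactors = FALSE)
}

# assemble a gene model from a spliced CDS and intron table.  The gene body
# (exons + introns, sense orientation) is taken to start `offset` nt into the
# sense strand of the contig; for minus-strand genes the contig is the
# reverse complement, so sense-relative intervals are mirrored through
# `contig_len`.  Exon rows stay in transcription order.
gene_model_from_parts <- function(gene_id, species, seq_region, cds_seq,
                                  introns, offset = 0L, strand = "+",
                                  contig_len = NULL) {
  offs <- introns$cds_offset
  ex_starts_cds <- c(0L, offs)
  ex_ends_cds <- c(offs, nchar(cds_seq))
  ilen <- c(0L, cumsum(introns$length_nt))
  g_start <- offset + ex_starts_cds + ilen[seq_along(ex_starts_cds)]
  g_end <- offset + ex_ends_cds + ilen[seq_along(ex_ends_cds)]
  if (strand == "-") {
    stopifnot(!is.null(contig_len))
    exons <- cbind(start = contig_len - g_end, end = contig_len - g_start)
  } else {
    exons <- cbind(start = g_start, end = g_end)
  }
  gene_model(gene_id, species, seq_region, strand, exons, cds_seq, introns)
}

# unspliced gene sequence (exons + introns, transcription orientation)
gene_sense_seq <- function(cds_seq, introns) {
  if (nrow(introns) == 0L) return(cds_seq)
  out <- character(0)
  prev <- 0L
  for (i in seq_len(nrow(introns))) {
    out <- c(out, substr(cds_seq, prev + 1L, introns$cds_offset[i]),
             introns$seq[i])
    prev <- introns$cds_offset[i]
  }
  paste(c(out, substring(cds_seq, prev + 1L)), collapse = "")
}

# re-splice a gene model from its genome and check it reproduces cds_seq
splice_from_genome <- function(gm, genome) {
  contig <- genome[[gm$seq_region]]
  if (is.null(contig)) stop("seq_region absent from genome: ", gm$seq_region)
  ex <- gm$cds_exons
  pieces <- substring(contig, ex[, "start"] + 1L, ex[, "end"])
  if (gm$strand == "-") pieces <- vapply(pieces, revcomp, character(1))
  paste(pieces, collapse = "")
}
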