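#' Assemble gene models from a GFF3 annotation and its genome
#'
#' Expects gene/mRNA/CDS features linked by `Parent` attributes.  When a
#' gene carries several transcripts the longest CDS wins, ties broken
#' lexicographically by transcript id.  Minus-strand genes are
#' strand-corrected so the CDS and intron records read in transcription
#' order.  A CDS whose length is not divisible by 3 is retained but flagged
#' (`frame_ok = FALSE`) with a warning.
#'
#' @param gff_path path to a GFF3 file
#' @param genome named character vector of contig sequences (as returned by
#'   [read_fasta()])
#' @return list of [gene_model()] objects
#' @export
read_gff_genes <- function(gff_path, genome) {
  gr <- rtracklayer::import(gff_path)
  typ <- as.character(gr$type)
  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1]] else NA_character_, character(1))
  mrna <- gr[typ == "mRNA"]
  cds <- gr[typ == "CDS"]
  if (length(mrna) == 0L || length(cds) == 0L)
    stop("GFF3 contains no mRNA/CDS features: ", gff_path)
  mrna_gene <- setNames(first_parent(mrna$Parent), mrna$ID)
  cds_tx <- first_parent(cds$Parent)

  # pick one transcript per gene: longest CDS, ties lexicographic
  tx_len <- tapply(GenomicRanges::width(cds), cds_tx, sum)
  tx_tbl <- data.frame(tx = names(tx_len), gene = unname(mrna_gene[names(tx_len)]),
                       len = as.integer(tx_len), stringsAsFactors = FALSE)
  tx_tbl <- tx_tbl[order(tx_tbl$gene, -tx_tbl$len, tx_tbl$tx), ]
  chosen <- tx_tbl[!duplicated(tx_tbl$gene), ]

  out <- vector("list", nrow(chosen))
  for (i in seq_len(nrow(chosen))) {
    sel <- cds[cds_tx == chosen$tx[i]]
    seq_region <- as.character(GenomicRanges::seqnames(sel))[1]
    if (!seq_region %in% names(genome))
      stop("CDS references absent seq_region: ", seq_region)
    strand <- as.character(GenomicRanges::strand(sel))[1]
    st <- GenomicRanges::start(sel) - 1L   # to 0-based half-open
    en <- GenomicRanges::end(sel)
    ord <- order(st)
    if (strand == "-") ord <- rev(ord)
    exons <- cbind(start = st[ord], end = en[ord])
    contig <- genome[[seq_region]]
    pieces <- substring(contig, exons[, "start"] + 1L, exons[, "end"])
    if (strand == "-") pieces <- vapply(pieces, revcomp, character(1))
    cds_seq <- paste(pieces, collapse = "")
    n_ex <- nrow(exons)
    ioffs <- integer(0); iseqs <- character(0)
    if (n_ex > 1L) {
      widths <- exons[, "end"] - exons[, "start"]
      ioffs <- cumsum(widths)[seq_len(n_ex - 1L)]
      iseqs <- vapply(seq_len(n_ex - 1L), function(k) {
        if (strand == "+") {
          substr(contig, exons[k, "end"] + 1L, exons[k + 1L, "start"])
        } else {
          revcomp(substr(contig, exons[k + 1L, "end"] + 1L, exons[k, "start"]))
        }
      }, character(1))
    }
    frame_ok <- nchar(cds_seq) %% 3L == 0L
    if (!frame_ok)
      warning("CDS length not divisible by 3 for gene ", chosen$gene[i])
    out[[i]] <- gene_model(gene_id = chosen$gene[i],
                           species = NA_character_,
                           seq_region = seq_region, strand = strand,
                           cds_exons = exons, cds_seq = cds_seq,
                           introns = make_intron_df(ioffs, iseqs),
                           frame_ok = frame_ok)
  }
  names(out) <- chosen$gene
  out
}

# write gene models as GFF3 (one mRNA per gene); coordinates back to 1-based
write_gff3 <- function(models, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(hash)) writeLines(paste0("# config: ", hash), con)
  for (gm in models) {
    ex <- gm$cds_exons
    lo <- min(ex[, "start"]) + 1L
    hi <- max(ex[, "end"])
    gid <- gm$gene_id
    tid <- paste0(gid, ".t1")
    writeLines(sprintf("%s\tintronevo\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       gm$seq_region, lo, hi, gm$strand, gid), con)
    writeLines(sprintf("%s\tintronevo\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       gm$seq_region, lo, hi, gm$strand, tid, gid), con)
    # CDS rows sorted by genomic coordinate; phase from transcription order
    widths <- ex[, "end"] - ex[, "start"]
    phase <- c(0L, (3L - cumsum(widths)[-length(widths)] %% 3L) %% 3L)
    ord <- order(ex[, "start"])
    for (k in ord) {
      writeLines(sprintf("%s\tintronevo\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                         gm$seq_region, ex[k, "start"] + 1L, ex[k, "end"],
                         gm$strand, phase[k], tid, tid), con)
    }
  }
  invisible(path)
}
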