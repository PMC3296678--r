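# FASTA/GFF3/Newick IO and gene-model assembly.

test_that("read_fasta normalises case and RNA residues and validates input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "acgu", ">b desc", "GT"), f)
  x <- read_fasta(f)
  expect_identical(x, c(a = "ACGT", b = "GT"))

  writeLines(c(">a", "AC", ">a", "GT"), f)
  expect_error(read_fasta(f), "duplicate FASTA id: a")

  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("write_fasta / read_fasta round-trips normalised records", {
  f <- withr::local_tempfile(fileext = ".fa")
  set.seed(1)
  seqs <- setNames(vapply(1:5, function(i)
    intronevo:::rand_dna(sample(10:200, 1)), character(1)),
    paste0("s", 1:5))
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
})

write_toy_gff <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("read_gff_genes assembles plus-strand genes with intron records", {
  # contig: 10 nt flank, exon1 1..15 (0-based 10..25? 1-based 11-25),
  # intron GT..AG, exon2
  exon1 <- "ATGAAACCCGGGTTT"
  intron <- "GTATATATATATAG"
  exon2 <- "AAACCCGGGTAA"
  contig <- paste0(strrep("C", 10), exon1, intron, exon2, strrep("C", 10))
  genome <- c(chr1 = contig)
  s1 <- 11; e1 <- 10 + nchar(exon1)
  s2 <- e1 + nchar(intron) + 1; e2 <- s2 + nchar(exon2) - 1
  gff <- write_toy_gff(c(
    sprintf("chr1\tx\tgene\t%d\t%d\t.\t+\t.\tID=g1", s1, e2),
    sprintf("chr1\tx\tmRNA\t%d\t%d\t.\t+\t.\tID=t1;Parent=g1", s1, e2),
    sprintf("chr1\tx\tCDS\t%d\t%d\t.\t+\t0\tID=c1;Parent=t1", s1, e1),
    sprintf("chr1\tx\tCDS\t%d\t%d\t.\t+\t0\tID=c2;Parent=t1", s2, e2)))
  gm <- read_gff_genes(gff, genome)[[1]]
  expect_equal(gm$cds_seq, paste0(exon1, exon2))
  expect_equal(nrow(gm$introns), 1L)
  expect_equal(gm$introns$seq, intron)
  expect_equal(gm$introns$donor2, "GT")
  expect_equal(gm$introns$acceptor2, "AG")
  expect_equal(gm$introns$cds_offset, nchar(exon1))
})

test_that("minus-strand genes are strand-corrected (manual 40 nt toy locus)", {
  # sense gene: exon1 "ATGGCT", intron "GTAAAG", exon2 "CATTAA"; the contig
  # is the reverse complement, so the genomic slice of the intron is
  # revcomp("GTAAAG") = "CTTTAC"
  exon1 <- "ATGGCT"; intron <- "GTAAAG"; exon2 <- "CATTAA"
  sense <- paste0(strrep("A", 11), exon1, intron, exon2, strrep("T", 11))
  contig <- revcomp(sense)
  L <- nchar(contig)
  # sense coords (1-based): exon1 12..17, exon2 24..29 -> mirrored
  g1 <- c(L - 17 + 1, L - 12 + 1)
  g2 <- c(L - 29 + 1, L - 24 + 1)
  gff <- write_toy_gff(c(
    sprintf("c\tx\tgene\t%d\t%d\t.\t-\t.\tID=g1", g2[1], g1[2]),
    sprintf("c\tx\tmRNA\t%d\t%d\t.\t-\t.\tID=t1;Parent=g1", g2[1], g1[2]),
    sprintf("c\tx\tCDS\t%d\t%d\t.\t-\t0\tID=c1;Parent=t1", g1[1], g1[2]),
    sprintf("c\tx\tCDS\t%d\t%d\t.\t-\t0\tID=c2;Parent=t1", g2[1], g2[2])))
  gm <- read_gff_genes(gff, c(c = contig))[[1]]
  expect_equal(gm$strand, "-")
  expect_equal(gm$cds_seq, paste0(exon1, exon2))
  expect_equal(gm$introns$seq, intron)
  expect_equal(revcomp(intron), "CTTTAC")  # the raw genomic slice
})

test_that("multi-isoform genes reduce to the longest CDS, single-exon genes have no introns", {
  exon <- "ATGGGGTAA"
  contig <- paste0("AAAA", exon, "GGTCTTTAA", "TTTT")
  gff <- write_toy_gff(c(
    "c\tx\tgene\t5\t22\t.\t+\t.\tID=g1",
    "c\tx\tmRNA\t5\t13\t.\t+\t.\tID=tShort;Parent=g1",
    sprintf("c\tx\tCDS\t5\t13\t.\t+\t0\tID=cs;Parent=tShort"),
    "c\tx\tmRNA\t5\t22\t.\t+\t.\tID=tLong;Parent=g1",
    sprintf("c\tx\tCDS\t5\t22\t.\t+\t0\tID=cl;Parent=tLong")))
  gm <- read_gff_genes(gff, c(c = contig))[[1]]
  expect_equal(nchar(gm$cds_seq), 18L)
  expect_equal(nrow(gm$introns), 0L)
})

test_that("GFF errors and warnings: absent seq_region, frame violation", {
  gff <- write_toy_gff(c(
    "nope\tx\tgene\t1\t9\t.\t+\t.\tID=g1",
    "nope\tx\tmRNA\t1\t9\t.\t+\t.\tID=t1;Parent=g1",
    "nope\tx\tCDS\t1\t9\t.\t+\t0\tID=c1;Parent=t1"))
  expect_error(read_gff_genes(gff, c(c = "ATGAAATAA")), "absent seq_region")

  gff2 <- write_toy_gff(c(
    "c\tx\tgene\t1\t8\t.\t+\t.\tID=g1",
    "c\tx\tmRNA\t1\t8\t.\t+\t.\tID=t1;Parent=g1",
    "c\tx\tCDS\t1\t8\t.\t+\t0\tID=c1;Parent=t1"))
  expect_warning(gm <- read_gff_genes(gff2, c(c = "ATGAAATAA"))[[1]],
                 "not divisible by 3")
  expect_false(gm$frame_ok)
})

test_that("read_newick validates leaves and preserves multifurcations", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),(C,D));", f)
  tr <- read_newick(f)
  expect_equal(length(tr$tip.label), 4L)
  expect_equal(tr$Nnode, 3L)

  writeLines("((A,B),C);", f)
  tr <- read_newick(f, outgroup = "C")
  expect_identical(attr(tr, "outgroup"), "C")
  expect_error(read_newick(f, outgroup = "Z"), "not a leaf")

  writeLines("(A,B,C);", f)
  tr <- read_newick(f)
  expect_equal(tr$Nnode, 1L)   # root trifurcation preserved

  writeLines("((A,),B);", f)
  expect_error(read_newick(f), "unlabelled|parse")
})

test_that("simulated gene models re-splice from their genomes exactly", {
  fx <- small_fixture()
  models <- as_gene_models(fx$sim)
  for (sp in names(models)) {
    for (gm in models[[sp]]) {
      genome <- setNames(list(attr(gm, "contig")), gm$seq_region)
      expect_identical(intronevo:::splice_from_genome(gm, genome),
                       gm$cds_seq)
      if (nrow(gm$introns) > 1L)
        expect_true(all(diff(gm$introns$cds_offset) > 0))
    }
  }
})
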