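# Artificial-intron markers, progressive alignment, column mapping.

toy_gene <- function(cds, offsets, iseqs, id = "g", sp = "s") {
  gene_model_from_parts(id, sp, paste0(id, "_scaf"), cds,
                        make_intron_df(offsets, iseqs))
}

test_that("insert_markers places 30-X blocks at intron offsets and round-trips", {
  set.seed(21)
  cds <- intronevo:::rand_dna(30)
  gm0 <- toy_gene(cds, integer(0), character(0))
  expect_identical(insert_markers(gm0), cds)

  gm1 <- toy_gene(cds, 9L, "GTAAAG")
  m <- insert_markers(gm1)
  expect_equal(nchar(m), 60L)
  expect_identical(substr(m, 10, 39), strrep("X", 30))
  expect_identical(gsub("X", "", m), cds)

  cds2 <- intronevo:::rand_dna(100)
  gm2 <- toy_gene(cds2, c(20L, 25L), c("GTAG", "GTCAG"))
  m2 <- insert_markers(gm2)
  blocks <- gregexpr("X+", m2)[[1]]
  expect_equal(length(blocks), 2L)
  expect_true(all(attr(blocks, "match.length") == 30L))
  expect_identical(gsub("X", "", m2), cds2)
})

test_that("identical marked strings align without gaps, markers co-columnar", {
  set.seed(22)
  cds <- intronevo:::rand_dna(120)
  gm <- toy_gene(cds, 50L, "GTAAAG")
  m <- insert_markers(gm)
  aln <- align_group(c(a = m, b = m, c = m))
  expect_true(all(vapply(aln$rows, function(r) !grepl("-", r, fixed = TRUE),
                         logical(1))))
  starts <- vapply(aln$marker_blocks, function(b) b$start_col, integer(1))
  expect_true(all(starts == starts[1]))
})

test_that("a species-specific intron aligns as one marker block against gaps", {
  set.seed(23)
  cds <- intronevo:::rand_dna(150)
  with_intron <- insert_markers(toy_gene(cds, 70L, "GTAAAG"))
  without <- cds
  aln <- align_group(c(a = with_intron, b = without))
  expect_equal(nrow(aln$marker_blocks$a), 1L)
  expect_equal(nrow(aln$marker_blocks$b), 0L)
  blk <- aln$marker_blocks$a
  gap_cols <- substr(aln$rows[["b"]], blk$start_col, blk$end_col)
  expect_identical(gap_cols, strrep("-", 30))
  # stripping X and gaps restores each CDS
  expect_identical(gsub("[-X]", "", aln$rows[["a"]]), cds)
  expect_identical(gsub("[-X]", "", aln$rows[["b"]]), cds)
})

test_that("a small exonic insertion is gapped outside any marker block", {
  set.seed(24)
  left <- intronevo:::rand_dna(60)
  right <- intronevo:::rand_dna(60)
  ins <- "TTT"
  plain <- paste0(left, right)
  gm_a <- toy_gene(plain, 60L, "GTAAAG")
  gm_b <- toy_gene(plain, 60L, "GTAAAG")
  gm_c <- toy_gene(paste0(left, ins, right), 63L, "GTAAAG")
  aln <- align_group(c(a = insert_markers(gm_a), b = insert_markers(gm_b),
                       c = insert_markers(gm_c)))
  # rows strip back to their inputs
  expect_identical(gsub("[-X]", "", aln$rows[["a"]]), plain)
  expect_identical(gsub("[-X]", "", aln$rows[["c"]]), paste0(left, ins, right))
  # the 3-column gap in rows a/b must not sit inside their X-blocks
  for (r in c("a", "b")) {
    gaps <- gregexpr("-+", aln$rows[[r]])[[1]]
    blk <- aln$marker_blocks[[r]]
    if (gaps[1] != -1) {
      for (gi in seq_along(gaps)) {
        s <- gaps[gi]; e <- s + attr(gaps, "match.length")[gi] - 1L
        expect_true(e < blk$start_col || s > blk$end_col)
      }
    }
  }
  # all three marker blocks stack in one column class
  cm <- map_intron_columns(aln)
  expect_equal(length(unique(cm$column)), 1L)
  expect_equal(nrow(cm), 3L)
})

test_that("column classes merge within the window and split beyond it", {
  mk_aln <- function(starts) {
    # synthetic marked_alignment with given block start columns
    rows <- lapply(seq_along(starts), function(i) {
      pre <- strrep("A", starts[i] - 1L)
      paste0(pre, strrep("X", 30), strrep("A", 60 - starts[i]))
    })
    names(rows) <- paste0("s", seq_along(starts))
    structure(list(rows = rows,
                   marker_blocks = intronevo:::marker_blocks(rows)),
              class = "marked_alignment")
  }
  cm <- map_intron_columns(mk_aln(c(5, 5, 5, 5, 5)))
  expect_equal(length(unique(cm$column)), 1L)

  cm2 <- map_intron_columns(mk_aln(c(5, 55)))
  expect_equal(length(unique(cm2$column)), 2L)

  # 100 vs 106: within the 10-column window -> one class
  cm3 <- map_intron_columns(mk_aln(c(10, 16)))
  expect_equal(length(unique(cm3$column)), 1L)
})

test_that("marker round-trip holds for every simulated gene", {
  fx <- small_fixture()
  for (gid in names(fx$fit$artifacts)) {
    art <- fx$fit$artifacts[[gid]]
    if (is.null(art$aln)) next
    for (sp in names(art$aln$rows)) {
      cds <- fx$ds$models[[sp]][[sub("^[^|]*\\|", "", art$group[[sp]])]]$cds_seq
      expect_identical(gsub("[-X]", "", art$aln$rows[[sp]]), cds)
    }
  }
})
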