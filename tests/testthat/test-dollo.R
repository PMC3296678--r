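# Dollo parsimony: polarization, event calling, QC filters, summaries.

tree4 <- ape::read.tree(text = "((A:1,B:1)nAB:1,(C:1,D:1)nCD:1)nR;")

states4 <- function(A, B, C, D) setNames(c(A, B, C, D), c("A", "B", "C", "D"))

test_that("outgroup need follows the reconstruction-cost tie rule", {
  # presence confined to one nested clade -> internal
  expect_equal(partition_outgroup_need(states4(1, 0, 0, 0), tree4), "internal")
  # presence everywhere: no discordance -> internal
  expect_equal(partition_outgroup_need(states4(1, 1, 1, 1), tree4), "internal")
  # presence in one of two basal sister clades: costs tie -> needs outgroup
  expect_equal(partition_outgroup_need(states4(1, 1, 0, 0), tree4),
               "needs_outgroup")
  # discordant pattern across the basal split: costs differ -> internal
  expect_equal(partition_outgroup_need(states4(1, 0, 1, 0), tree4), "internal")
})

test_that("dollo_events matches the worked four-taxon cases", {
  mat <- rbind(r1 = states4(1, 1, 0, 0))
  # outgroup absent: a single gain on the edge to the MRCA of A,B
  calls <- dollo_events(mat, tree4, outgroup_states = 0L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$type, "gain")
  expect_equal(calls$branch, "nAB")

  # present A and C, absent B and D, outgroup absent: gain at the root with
  # losses on the edges to B and D (brute-force minimal-loss placement)
  calls <- dollo_events(rbind(r1 = states4(1, 0, 1, 0)), tree4, 0L)
  expect_equal(calls$type[order(calls$branch)], c("loss", "loss", "gain"))
  expect_setequal(calls$branch[calls$type == "loss"], c("B", "D"))
  expect_equal(calls$branch[calls$type == "gain"], "nR")

  # all present, outgroup present: ancestral intron, zero events
  calls <- dollo_events(rbind(r1 = states4(1, 1, 1, 1)), tree4, 1L)
  expect_equal(nrow(calls), 0L)

  # zero present cells: the column never existed in this group
  calls <- dollo_events(rbind(r1 = states4(0, 0, 0, 0)), tree4, 1L)
  expect_equal(nrow(calls), 0L)

  # needs-outgroup row with missing outgroup state is excluded
  calls <- dollo_events(rbind(r1 = states4(1, 1, 0, 0)), tree4, NA_integer_)
  expect_equal(nrow(calls), 0L)
  expect_equal(attr(calls, "excluded"), "r1")

  # missing data constrains nothing: NA leaf does not generate a loss
  calls <- dollo_events(rbind(r1 = states4(1, NA, 0, 0)), tree4, 0L)
  expect_equal(calls$type, "gain")
  expect_equal(calls$branch, "A")
})

test_that("Dollo reconstruction equals exhaustive minimisation on all rooted trees with <= 6 leaves", {
  skip_if_not_installed("phangorn")
  agree <- dollo_oracle_sweep(max_leaves = 5L)  # 6-leaf sweep runs in acceptance
  expect_true(agree$all_equal)
  expect_gt(agree$n_cases, 3000)
})

test_that("gain QC rejects 3n stop-free single-species gains and noncanonical splice sites", {
  call <- data.frame(column = "col1", type = "gain", branch = "A",
                     single_species = TRUE, n_leaves = 1L, leaves = "A",
                     status = "accepted", qc_flags = "",
                     stringsAsFactors = FALSE)
  gene <- NULL
  mk_intron <- function(seq, off) {
    data.frame(index = 0L, cds_offset = off, length_nt = nchar(seq),
               seq = seq, donor2 = substr(seq, 1, 2),
               acceptor2 = substring(seq, nchar(seq) - 1),
               stringsAsFactors = FALSE)
  }
  # 60 nt, stop-free in frame 0 (offset divisible by 3): rejected
  stopfree <- paste0("GT", paste(rep("GCA", 19), collapse = ""), "G")
  expect_equal(nchar(stopfree), 60L)
  out <- qc_gain_filters(call, mk_intron(stopfree, 300L), gene)
  expect_equal(out$status, "rejected")
  expect_match(out$qc_flags, "len3n_noPTC")

  # 61 nt with canonical ends: accepted
  ok61 <- paste0("GT", strrep("A", 57), "AG")
  out <- qc_gain_filters(call, mk_intron(ok61, 300L), gene)
  expect_equal(out$status, "accepted")

  # 60 nt but containing an in-frame stop: accepted (TAA sits at codon 2
  # of the frame set by an offset divisible by 3)
  withstop <- paste0("GTG", "TAA", paste(rep("GCA", 17), collapse = ""), "AAG")
  expect_equal(nchar(withstop) %% 3L, 0L)
  out <- qc_gain_filters(call, mk_intron(withstop, 300L), gene)
  expect_equal(out$status, "accepted")

  # noncanonical splice sites: rejected regardless of length
  noncan <- paste0("GC", strrep("A", 57), "AG")
  out <- qc_gain_filters(call, mk_intron(noncan, 300L), gene)
  expect_equal(out$status, "rejected")
  expect_match(out$qc_flags, "noncanonical_splice")

  # the frame is set by cds_offset: shifting the offset by one reads the
  # same 60-mer in another frame and loses the stop
  expect_true(intronevo:::has_ptc(withstop, 300L))
  expect_false(intronevo:::has_ptc(withstop, 301L))
})

test_that("summaries split single-species and ancestral events and add up", {
  mat <- rbind(r1 = states4(1, 1, 0, 0),   # gain at nAB
               r2 = states4(1, 0, 1, 1),   # ancestral + loss at B
               r3 = states4(0, 0, 0, 1))   # gain at D
  calls <- dollo_events(mat, tree4, outgroup_states = c(0L, 1L, 0L))
  s <- summarize_events(calls, tree4)
  expect_equal(sum(s$per_branch$gains), 2L)
  expect_equal(sum(s$per_branch$losses), 1L)
  expect_equal(s$totals$total, s$totals$single_species + s$totals$ancestral)
  expect_equal(s$per_species$gained_introns[s$per_species$species == "D"], 1L)
  expect_equal(s$per_species$lost_introns[s$per_species$species == "B"], 1L)

  empty <- summarize_events(calls[0, ], tree4)
  expect_true(all(empty$per_branch$gains == 0L))
  expect_true(all(empty$per_branch$losses == 0L))
})

test_that("flank filter keeps faithful flanks and drops noisy or short ones", {
  set.seed(31)
  mk_aln <- function(left, right) {
    rows <- lapply(seq_len(nrow(left)), function(i)
      paste0(paste(left[i, ], collapse = ""), strrep("X", 30),
             paste(right[i, ], collapse = "")))
    names(rows) <- paste0("s", seq_len(nrow(left)))
    structure(list(rows = rows,
                   marker_blocks = intronevo:::marker_blocks(rows)),
              class = "marked_alignment")
  }
  perfect <- matrix(rep(strsplit(intronevo:::rand_dna(20), "")[[1]],
                        each = 4), nrow = 4)
  ff <- flank_filter(mk_aln(perfect, perfect), 21L, 50L)
  expect_true(ff$keep)
  expect_equal(ff$left_identity, 1)

  noisy <- matrix(sample(c("A", "C", "G", "T"), 80, TRUE), nrow = 4)
  ff <- flank_filter(mk_aln(noisy, perfect), 21L, 50L)
  expect_false(ff$keep)

  # identity exactly at the threshold is kept (inclusive rule): with 4
  # rows there are 6 pairs per column; deviating one row in 3 of the 15
  # window columns gives (12*6 + 3*3)/(15*6) = 0.9 exactly
  dev <- perfect
  dev[1, 18:20] <- chartr("ACGT", "GTAC", dev[1, 18:20])
  ff <- flank_filter(mk_aln(dev, perfect), 21L, 50L, min_mean_identity = 0.9)
  expect_true(ff$keep)
  expect_equal(ff$left_identity, 0.9)

  # fewer than 5 comparable columns on a side -> drop
  short <- perfect[, 1:3, drop = FALSE]
  ff <- flank_filter(mk_aln(short, perfect), 4L, 33L)
  expect_false(ff$keep)
})
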