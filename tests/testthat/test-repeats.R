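# Direct repeats and target-site duplications at junctions.

test_that("find_direct_repeats spots shared junction words and orders them", {
  left <- paste0(strrep("C", 20), "ACGTA")
  intron <- paste0("ACGTA", strrep("C", 40))
  reps <- find_direct_repeats(left, intron, strrep("C", 25), min_len = 5)
  expect_true(any(reps$seq == "ACGTA" & reps$side == "5prime"))
  # longest-first ordering
  expect_true(all(diff(reps$len) <= 0))

  # no shared >= 5-mer between A-only and G-only windows
  reps <- find_direct_repeats(strrep("A", 30), strrep("G", 60),
                              strrep("A", 30), min_len = 5)
  expect_equal(nrow(reps), 0L)
})

test_that("find_direct_repeats equals the brute-force substring scan", {
  set.seed(41)
  for (i in 1:300) {
    left <- intronevo:::rand_dna(30)
    intron <- intronevo:::rand_dna(70)
    right <- intronevo:::rand_dna(30)
    got <- find_direct_repeats(left, intron, right, min_len = 5, window = 30)
    want5 <- substr_oracle(left, substr(intron, 1, 30), 5L)
    want3 <- substr_oracle(substring(intron, nchar(intron) - 29), right, 5L)
    expect_setequal(got$seq[got$side == "5prime"], want5)
    expect_setequal(got$seq[got$side == "3prime"], want3)
  }
})

test_that("repeat rates hit the planted extremes", {
  set.seed(43)
  planted <- lapply(1:30, function(i) {
    r <- intronevo:::rand_dna(8)
    list(paste0(intronevo:::rand_dna(22), r),
         paste0(r, intronevo:::rand_dna(50)),
         intronevo:::rand_dna(30))
  })
  expect_equal(repeat_flanking_rate(planted, min_len = 5)$fraction, 1)

  # constructed repeat-free set: disjoint alphabets on each side
  free <- lapply(1:20, function(i)
    list(strrep("A", 30), paste0(strrep("G", 30), strrep("C", 30)),
         strrep("T", 30)))
  expect_equal(repeat_flanking_rate(free, min_len = 5)$fraction, 0)

  # seeded junctions exceed an unseeded background, chi-square attached
  bg <- lapply(1:30, function(i)
    list(strrep("A", 30), paste0(strrep("G", 30), strrep("C", 30)),
         strrep("T", 30)))
  r <- repeat_flanking_rate(planted, min_len = 5, background = bg)
  expect_gt(r$fraction, r$background_fraction)
  expect_lt(r$chisq$p_value, 0.01)
})

test_that("detect_tsd recovers planted duplications, tolerates one mismatch, and ignores clean junctions", {
  set.seed(47)
  t_site <- "GTCATTGC"
  up <- intronevo:::rand_dna(30)
  core <- intronevo:::rand_dna(80)
  intron <- paste0(t_site, core, "AG")
  down <- paste0(t_site, intronevo:::rand_dna(22))  # copy at the 3' junction
  tsd <- detect_tsd(up, intron, down)
  expect_false(is.null(tsd))
  expect_true(startsWith(tsd$tsd, t_site) || startsWith(t_site, tsd$tsd))
  expect_gte(tsd$len, 8L)

  # one mismatch in the downstream copy is tolerated
  mm <- paste0("GACATTGC", intronevo:::rand_dna(22))
  tsd <- detect_tsd(up, intron, mm, max_mismatch = 1)
  expect_false(is.null(tsd))
  # two mismatches are not (low-complexity context so no chance prefix
  # match can fire)
  mm2 <- paste0("CACATTGC", strrep("A", 22))
  tsd2 <- detect_tsd(up, paste0(t_site, strrep("C", 60), "AG"), mm2,
                     max_mismatch = 1)
  expect_null(tsd2)

  # repeat-free junctions yield nothing
  expect_null(detect_tsd(strrep("A", 30), paste0("GT", strrep("C", 60), "AG"),
                         strrep("A", 30)))
})

test_that("simulated transposon gains carry their recorded TSD at the junction", {
  cfg <- sim_config(seed = 29, n_taxa = 5, n_genes = 12, subst_rate = 0,
                    gain_rate = 0.4, loss_rate = 0,
                    gain_mix = c(transposon_tsd = 1, mito_filler = 0, plain = 0))
  sim <- evolve_family(cfg)
  gains <- sim$truth[sim$truth$type == "gain", , drop = FALSE]
  expect_gt(nrow(gains), 5)
  found <- 0L
  for (i in seq_len(nrow(gains))) {
    carriers <- sim$intron_map[sim$intron_map$column == gains$column[i], ,
                               drop = FALSE]
    if (!nrow(carriers)) next
    sp <- carriers$species[1]
    st <- sim$genes[[sp]][[gains$gene[i]]]
    j <- match(gains$column[i], st$introns$column)
    o <- st$introns$cds_offset[j]
    tsd <- detect_tsd(substr(st$cds, o - 29, o), st$introns$seq[j],
                      substr(st$cds, o + 1, o + 30))
    expect_false(is.null(tsd), label = paste("tsd found for", gains$column[i]))
    found <- found + 1L
  }
  expect_gt(found, 3L)
})
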