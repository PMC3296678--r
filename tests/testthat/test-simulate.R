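# Forward simulator: root genes, event bookkeeping, determinism, emission.

test_that("simulate_root_gene builds ORFs with well-spaced canonical introns", {
  cfg0 <- sim_config(seed = 3, root_introns_mean = 0)
  gm0 <- simulate_root_gene(cfg0)
  expect_equal(nrow(gm0$introns), 0L)
  expect_true(intronevo:::is_orf(gm0$cds_seq))

  cfg <- sim_config(seed = 11, root_introns_mean = 6)
  gm <- simulate_root_gene(cfg)
  expect_true(intronevo:::is_orf(gm$cds_seq))
  if (nrow(gm$introns) > 1L) {
    expect_true(all(diff(gm$introns$cds_offset) >= cfg$min_intron_spacing))
  }
  expect_true(all(gm$introns$donor2 == "GT"))
  expect_true(all(gm$introns$acceptor2 == "AG"))
  expect_true(all(gm$introns$length_nt >= cfg$intron_len_min))

  # determinism
  gm2 <- simulate_root_gene(cfg)
  expect_identical(gm, gm2)
})

test_that("zero event rates leave the root intron chain untouched at every leaf", {
  cfg <- sim_config(seed = 5, n_taxa = 4, n_genes = 3, gain_rate = 0,
                    loss_rate = 0, subst_rate = 0)
  sim <- evolve_family(cfg)
  expect_equal(nrow(sim$truth), 0L)
  for (g in names(sim$genes[[1]])) {
    ref <- sim$genes[[sim$outgroup]][[g]]
    for (sp in setdiff(names(sim$genes), sim$outgroup)) {
      st <- sim$genes[[sp]][[g]]
      expect_identical(st$cds, ref$cds)
      expect_identical(st$introns$seq, ref$introns$seq)
      expect_identical(st$introns$cds_offset, ref$introns$cds_offset)
    }
  }
})

test_that("leaf CDS stays an ORF and intron counts obey the truth log", {
  fx <- small_fixture()
  sim <- fx$sim
  ing <- sim$ingroup
  for (sp in names(sim$genes)) {
    for (g in names(sim$genes[[sp]])) {
      expect_true(intronevo:::is_orf(sim$genes[[sp]][[g]]$cds))
    }
  }
  # conservation: introns at a leaf = root introns + gains - losses on path
  truth <- sim$truth
  for (sp in ing$tip.label) {
    path_nodes <- intronevo:::node_label(
      ing, c(intronevo:::node_id(ing, sp),
             setdiff(unlist(ape::nodepath(ing, intronevo:::root_id(ing),
                                          intronevo:::node_id(ing, sp))),
                     intronevo:::root_id(ing))))
    for (g in names(sim$genes[[sp]])) {
      ev <- truth[truth$gene == g & truth$branch %in% path_nodes, ,
                  drop = FALSE]
      n_root <- nrow(sim$genes[[sim$outgroup]][[g]]$introns)
      expected <- n_root + sum(ev$type == "gain") - sum(ev$type == "loss")
      expect_equal(nrow(sim$genes[[sp]][[g]]$introns), expected,
                   info = paste(sp, g))
    }
  }
})

test_that("identical seeds give byte-identical datasets", {
  cfg <- sim_config(seed = 19, n_taxa = 4, n_genes = 4, annot_error_rate = 0.1)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_dataset(evolve_family(cfg), d1)
  write_dataset(evolve_family(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("pure mito-filler gains align to the organelle genome at full identity", {
  cfg <- sim_config(seed = 13, n_taxa = 5, n_genes = 12, subst_rate = 0,
                    gain_rate = 0.4, loss_rate = 0,
                    gain_mix = c(transposon_tsd = 0, mito_filler = 1, plain = 0))
  sim <- evolve_family(cfg)
  gains <- sim$truth[sim$truth$type == "gain", , drop = FALSE]
  expect_gt(nrow(gains), 5L)
  both <- paste0(sim$mito, "NN", revcomp(sim$mito))
  for (i in seq_len(nrow(gains))) {
    h <- local_align(gains$seq[i], sim$mito)
    h2 <- local_align(revcomp(gains$seq[i]), sim$mito)
    best <- if (h$score >= h2$score) h else h2
    # the optimal local alignment may pick up a column or two of the
    # forced splice ends beyond the filler slice
    expect_gte(best$identity_pct, 98)
    expect_gte(best$query_coverage_pct, 90)
    # the filler interior occurs verbatim in the organelle genome
    expect_true(grepl(substr(gains$seq[i], 3, 62), both, fixed = TRUE))
  }
})

test_that("emitted datasets read back to the same gene models", {
  fx <- small_fixture()
  models <- as_gene_models(fx$sim)
  for (sp in names(models)) {
    for (gm in models[[sp]]) {
      back <- fx$ds$models[[sp]][[gm$gene_id]]
      expect_false(is.null(back))
      expect_identical(back$cds_seq, gm$cds_seq)
      expect_identical(back$strand, gm$strand)
      expect_identical(back$introns$seq, gm$introns$seq)
      expect_identical(back$introns$cds_offset, gm$introns$cds_offset)
    }
  }
})

test_that("an eventless simulation emits a valid dataset with an empty truth log", {
  cfg <- sim_config(seed = 2, n_taxa = 3, n_genes = 2, gain_rate = 0,
                    loss_rate = 0)
  d <- file.path(tempdir(), "empty-truth")
  write_dataset(evolve_family(cfg), d)
  ds <- read_dataset(d)
  expect_equal(nrow(ds$truth), 0L)
  expect_equal(length(ds$models), 4L)  # 3 ingroup + outgroup
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(gain_mix = c(transposon_tsd = 0.5, mito_filler = 0.2,
                                       plain = 0.2)), "sum to 1")
  expect_error(sim_config(loss_rate = -1), "nonnegative")
  expect_error(sim_config(nhej_k = c(10L)), "multiples of 3")
  expect_error(sim_config(germline_prob_event = 1.2), "0, 1")
})
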