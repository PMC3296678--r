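# Insertion-source scans, shuffle null, NHEJ residues, sliding, and the
# full mechanism-attribution driver.

test_that("scan_insertion_source finds planted inserts on either strand and passes nulls", {
  set.seed(51)
  lib <- setNames(lapply(1:4, function(i) intronevo:::rand_dna(500)),
                  paste0("TE", 1:4))
  lib <- vapply(lib, identity, character(1))
  insert <- substr(lib[["TE2"]], 100, 300)
  intron <- paste0("GT", insert, "AG")
  hits <- scan_insertion_source(intron, lib)
  expect_gt(nrow(hits), 0L)
  expect_equal(hits$partner[1], "TE2")
  expect_gte(hits$coverage_pct[1], 90)

  # reverse-complement insert is found on the minus strand
  hits <- scan_insertion_source(paste0("GT", revcomp(insert), "AG"), lib)
  expect_equal(hits$partner[1], "TE2")
  expect_equal(hits$strand[1], "-")

  # empty library -> empty result; short query errors
  expect_equal(nrow(scan_insertion_source(intron, character(0))), 0L)
  expect_error(scan_insertion_source("GTACGTAG", lib), "too short")

  # random introns almost never hit an unrelated library
  fp <- mean(replicate(40, nrow(scan_insertion_source(
    intronevo:::rand_dna(150), lib)) > 0))
  expect_lte(fp, 0.05)
})

test_that("shuffle_null_p flags planted identity and is calibrated under the null", {
  set.seed(53)
  target <- intronevo:::rand_dna(400)
  query <- substr(target, 50, 170)
  p <- shuffle_null_p(query, target, n_shuffles = 99, seed = 5)
  expect_equal(p, 1 / 100)

  expect_error(shuffle_null_p(query, target, n_shuffles = 0), "at least 1")
  expect_error(shuffle_null_p("GTAG", target), "shorter than 20")

  # null calibration at a light setting (the acceptance run uses 500
  # replicates): the p-value must not be anti-conservative
  ps <- replicate(120, shuffle_null_p(intronevo:::rand_dna(40),
                                      intronevo:::rand_dna(200),
                                      n_shuffles = 49))
  expect_lte(mean(ps <= 0.1), 0.16)
  # dinucleotide mode returns a valid p as well
  p2 <- shuffle_null_p(query, target, n_shuffles = 49, mode = "di")
  expect_lte(p2, 1 / 50 * 2)
})

test_that("imprecise NHEJ losses are recognised from junction residues, precise losses are not", {
  cfg <- sim_config(seed = 61, n_taxa = 6, n_genes = 12, subst_rate = 0,
                    gain_rate = 0, loss_rate = 0.35,
                    loss_mix = c(precise = 0.5, nhej_imprecise = 0.5))
  sim <- evolve_family(cfg)
  d <- file.path(tempdir(), "nhej-fixture")
  write_dataset(sim, d)
  ds <- read_dataset(d)
  fit <- intron_events(ds)
  rs <- recovery_stats(fit, ds)
  acc <- rs$calls[rs$calls$status == "accepted" & rs$calls$type == "loss", ,
                  drop = FALSE]
  truth_mech <- setNames(ds$truth$mechanism,
                         paste(ds$truth$column, ds$truth$branch))
  n_nhej <- 0L; n_prec <- 0L
  for (i in seq_len(nrow(acc))) {
    mech <- truth_mech[[paste(acc$truth_column[i], acc$branch[i])]]
    hit <- detect_imprecise_loss(fit, acc[i, , drop = FALSE])
    if (mech == "nhej_imprecise") {
      n_nhej <- n_nhej + 1L
      expect_false(is.null(hit), label = paste("nhej hit", acc$truth_column[i]))
      expect_lte(hit$e_value, 0.1)
    } else {
      n_prec <- n_prec + 1L
      expect_null(hit)
    }
  }
  expect_gt(n_nhej, 2L)
  expect_gt(n_prec, 2L)
})

test_that("planted slides are detected with conserved sequence; honest columns are not paired", {
  cfg <- sim_config(seed = 9, n_genes = 30, n_taxa = 8, subst_rate = 0,
                    slide_rate = 0.08, gain_rate = 0.05, loss_rate = 0.08)
  sim <- evolve_family(cfg)
  d <- file.path(tempdir(), "slide-fixture")
  write_dataset(sim, d)
  ds <- read_dataset(d)
  fit <- intron_events(ds)
  slides <- ds$truth[ds$truth$type == "slide", , drop = FALSE]
  expect_gt(nrow(slides), 0L)
  sl <- do.call(rbind, lapply(names(fit$groups), function(g)
    detect_sliding(fit, g)))
  expect_gte(nrow(sl), nrow(slides))
  expect_true(all(sl$e_value <= 0.1))
  expect_true(all(sl$shift_cols > 10))
  # coincidental gain+loss pairs with unrelated intron sequence almost
  # never reach the similarity threshold
  slid_genes <- unique(slides$gene)
  fam_of <- vapply(fit$artifacts, function(a)
    sub("^[^|]*\\|[^_]*_", "", a$group[[1]]), character(1))
  quiet <- names(fam_of)[!fam_of %in% slid_genes]
  false_pairs <- sum(vapply(quiet, function(g)
    nrow(detect_sliding(fit, g)), integer(1)))
  expect_lte(false_pairs, 2L)
})

test_that("scan_mechanisms attributes planted mechanisms and reports biases", {
  cfg <- sim_config(seed = 5, n_genes = 25, n_taxa = 6, subst_rate = 0)
  sim <- evolve_family(cfg)
  d <- file.path(tempdir(), "scan-fixture")
  write_dataset(sim, d)
  ds <- read_dataset(d)
  fit <- intron_events(ds)
  rs <- recovery_stats(fit, ds)
  cfg2 <- pipeline_config(n_shuffles = 200L, n_perm = 500L)
  scan <- scan_mechanisms(fit, ds, cfg2)
  v <- scan$verdicts
  key <- paste(v$group_id, v$column, v$branch, v$type)
  rkey <- paste(rs$calls$group_id, rs$calls$column, rs$calls$branch,
                rs$calls$type)
  v$truth_col <- rs$calls$truth_column[match(key, rkey)]
  v$truth_mech <- ds$truth$mechanism[match(paste(v$truth_col, v$branch),
                                           paste(ds$truth$column,
                                                 ds$truth$branch))]
  tab <- table(v$truth_mech, v$mechanism)
  recall <- function(mech, verdict) {
    if (!mech %in% rownames(tab)) return(NA_real_)
    tab[mech, verdict] / sum(tab[mech, ])
  }
  for (m in c("transposon_tsd", "mito_filler", "nhej_imprecise")) {
    vd <- c(transposon_tsd = "transposon", mito_filler = "mito_dsbr",
            nhej_imprecise = "nhej_loss")[[m]]
    r <- recall(m, vd)
    if (!is.na(r)) expect_gte(r, 0.9)
  }
  # planted mito hits get a significant shuffle p
  mp <- v$shuffle_p[v$mechanism == "mito_dsbr"]
  if (length(mp)) expect_true(all(mp <= 0.05))
  # verdicts are deterministic given the seed
  scan2 <- scan_mechanisms(fit, ds, cfg2)
  expect_identical(scan$verdicts, scan2$verdicts)
})
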