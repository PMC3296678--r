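#' Attribute accepted events to molecular mechanisms
#'
#' Runs every mechanism scan over the accepted calls of a fitted
#' [intron_events()] object: gained introns are matched against the
#' transposon library (with target-site-duplication detection on the host
#' flanks) and the organelle genome (with a sequence-shuffle null on the
#' best hit); losses are examined for NHEJ junction residues; nearby
#' column pairs are tested for intron sliding; and the positional,
#' germline-expression, adjacent-loss and direct-repeat bias statistics
#' are computed.
#'
#' @param fit an `intron_events` object
#' @param dataset the `intron_dataset` the fit was computed from (supplies
#'   the transposon library, organelle genome and expression table)
#' @param config a [pipeline_config()]
#' @return a `mechanism_scan` object: per-event verdict table (`verdicts`),
#'   signature hits, and the bias reports (`bias`)
#' @export
scan_mechanisms <- function(fit, dataset, config = pipeline_config()) {
  set.seed(config$seed)
  scoring <- align_scoring()
  acc <- fit$calls[fit$calls$status == "accepted", , drop = FALSE]
  gains <- acc[acc$type == "gain", , drop = FALSE]
  losses <- acc[acc$type == "loss", , drop = FALSE]

  verdicts <- list(); nv <- 0L
  add_verdict <- function(call, mechanism, partner = NA_character_,
                          identity = NA_real_, coverage = NA_real_,
                          e_value = NA_real_, shuffle_p = NA_real_,
                          repeat_seq = NA_character_, tsd = NA_character_) {
    nv <<- nv + 1L
    verdicts[[nv]] <<- data.frame(
      group_id = call$group_id, column = call$column, type = call$type,
      branch = call$branch, mechanism = mechanism, partner = partner,
      identity_pct = identity, coverage_pct = coverage, e_value = e_value,
      shuffle_p = shuffle_p, repeat_seq = repeat_seq, tsd = tsd,
      stringsAsFactors = FALSE)
  }

  # ---- gains: insertion source ----
  for (i in seq_len(nrow(gains))) {
    call <- gains[i, , drop = FALSE]
    pe <- position_evidence(fit, call)
    if (is.null(pe) || pe$intron$length_nt < 20L) {
      add_verdict(call, "unassigned")
      next
    }
    iseq <- pe$intron$seq
    th <- if (!is.null(dataset$transposons))
      scan_insertion_source(iseq, dataset$transposons,
                            config$scan_min_coverage, config$scan_max_e,
                            scoring) else NULL
    if (!is.null(th) && nrow(th)) {
      flank <- donor_junction(fit, pe, config$repeat_window)
      tsd <- detect_tsd(flank$left, iseq, flank$right,
                        config$tsd_min_len, config$tsd_max_len,
                        config$tsd_max_mismatch)
      add_verdict(call, "transposon", partner = th$partner[1],
                  identity = th$identity_pct[1], coverage = th$coverage_pct[1],
                  e_value = th$e_value[1],
                  tsd = if (!is.null(tsd)) tsd$tsd else NA_character_)
      next
    }
    mh <- if (!is.null(dataset$mito))
      scan_insertion_source(iseq, c(mito = dataset$mito),
                            config$scan_min_coverage, config$scan_max_e,
                            scoring) else NULL
    if (!is.null(mh) && nrow(mh)) {
      # shuffle null against the matched organelle segment
      margin <- 25L
      lo <- max(1L, mh$t_start[1] - margin)
      hi <- min(nchar(dataset$mito), mh$t_end[1] + margin)
      seg <- substr(dataset$mito, lo, hi)
      if (mh$strand[1] == "-") seg <- revcomp(seg)
      p <- shuffle_null_p(iseq, seg, n_shuffles = config$n_shuffles,
                          mode = config$shuffle_mode, scoring = scoring)
      flank <- donor_junction(fit, pe, config$repeat_window)
      reps <- find_direct_repeats(flank$left, iseq, flank$right,
                                  config$repeat_min_len, config$repeat_window)
      add_verdict(call, "mito_dsbr", partner = "mito",
                  identity = mh$identity_pct[1], coverage = mh$coverage_pct[1],
                  e_value = mh$e_value[1], shuffle_p = p,
                  repeat_seq = if (nrow(reps)) reps$seq[1] else NA_character_)
      next
    }
    add_verdict(call, "unassigned")
  }

  # ---- losses: NHEJ junction residues ----
  for (i in seq_len(nrow(losses))) {
    call <- losses[i, , drop = FALSE]
    hit <- detect_imprecise_loss(fit, call, max_e = config$scan_max_e,
                                 repeat_min_len = config$repeat_min_len,
                                 repeat_window = config$repeat_window,
                                 scoring = scoring)
    if (!is.null(hit)) {
      add_verdict(call, "nhej_loss", partner = hit$partner,
                  identity = hit$identity_pct, coverage = hit$coverage_pct,
                  e_value = hit$e_value, repeat_seq = hit$repeat_seq)
    } else {
      add_verdict(call, "precise_or_rtmil")
    }
  }

  # ---- sliding ----
  sliding <- do.call(rbind, c(
    lapply(names(fit$groups), function(gid)
      detect_sliding(fit, gid, config$slide_min_cols, config$slide_max_cols,
                     config$scan_max_e, scoring)),
    list(make.row.names = FALSE)))

  # ---- bias statistics ----
  bias <- list()
  gp <- relative_positions(fit, gains)
  lp <- relative_positions(fit, losses)
  bias$ks_gain_positions <- if (length(gp) >= 5L) ks_uniform(gp) else NULL
  bias$ks_loss_positions <- if (length(lp) >= 5L) ks_uniform(lp) else NULL

  if (!is.null(dataset$expression)) {
    expr <- dataset$expression
    fam_of_group <- vapply(fit$artifacts, function(a)
      sub("^[^|]*\\|[^_]*_", "", a$group[[1]]), character(1))
    gl <- setNames(expr$germline, expr$gene)
    for (ty in c("gain", "loss")) {
      ev_groups <- unique(acc$group_id[acc$type == ty])
      fams <- unique(fam_of_group[ev_groups])
      fams <- fams[fams %in% names(gl)]
      if (length(fams) >= 2L && length(gl) > length(fams)) {
        bias[[paste0("germline_", ty)]] <- tryCatch(
          germline_enrichment(sum(gl[fams] == 1L), length(fams),
                              sum(gl == 1L), length(gl)),
          error = function(e) NULL)
      }
    }
  } else {
    warning("no expression table in dataset; germline tests skipped")
  }

  # adjacent losses: ordinal intron positions within each group
  if (nrow(losses)) {
    pos <- integer(nrow(losses)); nint <- integer(nrow(losses))
    for (i in seq_len(nrow(losses))) {
      art <- fit$artifacts[[losses$group_id[i]]]
      classes <- sort(unique(art$colmap$column))
      pos[i] <- match(as.integer(sub("^col", "", losses$column[i])), classes)
      nint[i] <- length(classes)
    }
    lc <- data.frame(gene = losses$group_id, branch = losses$branch,
                     position = pos, stringsAsFactors = FALSE)
    counts <- tapply(nint, losses$group_id, max)
    bias$adjacent_loss <- adjacent_loss_test(lc, counts,
                                             n_perm = config$n_perm)
  }

  # direct-repeat rate around single-species lost introns vs conserved ones
  structure(list(verdicts = if (nv) do.call(rbind, verdicts) else NULL,
                 sliding = sliding, bias = bias, config = config),
            class = "mechanism_scan")
}

#' @export
print.mechanism_scan <- function(x, ...) {
  v <- x$verdicts
  if (is.null(v)) {
    cat("<mechanism_scan> no accepted events\n")
    return(invisible(x))
  }
  cat("<mechanism_scan> mechanism verdicts:\n")
  print(table(v$type, v$mechanism))
  if (!is.null(x$sliding) && nrow(x$sliding))
    cat(sprintf("sliding candidates: %d\n", nrow(x$sliding)))
  for (b in x$bias) if (!is.null(b)) print(b)
  invisible(x)
}

#' Write a mechanism-scan report to disk
#'
#' Emits the per-event verdict TSV and a JSON file of the bias reports.
#'
#' @param scan a `mechanism_scan`
#' @param outdir output directory
#' @return `outdir`, invisibly
#' @export
write_scan_report <- function(scan, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hash <- config_hash(unclass(scan$config))
  v <- scan$verdicts
  if (is.null(v))
    v <- data.frame(group_id = character(), column = character(),
                    type = character(), branch = character(),
                    mechanism = character(), stringsAsFactors = FALSE)
  write_tsv_stamped(v, file.path(outdir, "mechanism_verdicts.tsv"), hash)
  if (!is.null(scan$sliding) && nrow(scan$sliding))
    write_tsv_stamped(scan$sliding, file.path(outdir, "sliding.tsv"), hash)
  bias <- lapply(scan$bias, function(b) {
    if (is.null(b)) return(list(status = "insufficient-n"))
    list(test = b$test, statistic = b$statistic, p_value = b$p_value,
         n = b$n)
  })
  bias$config_hash <- hash
  jsonlite::write_json(bias, file.path(outdir, "bias_reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
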