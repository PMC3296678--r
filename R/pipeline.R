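# Command-style entry points: simulate, infer, scan.  Thin wrappers over
# the package functions that read/write flat files, for use from scripts
# (see inst/cli/intronevo.R) or interactively.

#' Simulate a dataset and write it to disk
#'
#' @param outdir output directory
#' @param config a [sim_config()]; `seed` overrides its seed when given
#' @param seed optional integer seed
#' @return the dataset directory, invisibly
#' @export
run_simulate <- function(outdir, config = sim_config(), seed = NULL) {
  if (missing(outdir) || is.null(outdir)) stop("an output path is required")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sim <- evolve_family(config)
  write_dataset(sim, outdir)
  message(sprintf("simulated %d families (seed %d): %d gains, %d losses",
                  config$n_genes, config$seed,
                  sum(sim$truth$type == "gain"),
                  sum(sim$truth$type == "loss")))
  invisible(outdir)
}

#' Infer events for a dataset directory and write result tables
#'
#' Writes the event calls, the per-branch and per-species summary tables,
#' and the presence/absence matrices.
#'
#' @param dataset_dir dataset directory (layout of [write_dataset()])
#' @param outdir output directory
#' @param config a [pipeline_config()]
#' @return the fitted `intron_events` object, invisibly
#' @export
run_infer <- function(dataset_dir, outdir, config = pipeline_config()) {
  fit <- intron_events(dataset_dir, config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  hash <- config_hash(unclass(config))
  write_tsv_stamped(fit$calls, file.path(outdir, "events.tsv"), hash)
  write_tsv_stamped(fit$summary$per_branch,
                    file.path(outdir, "per_branch.tsv"), hash)
  write_tsv_stamped(fit$summary$per_species,
                    file.path(outdir, "per_species.tsv"), hash)
  mats <- list()
  for (gid in names(fit$artifacts)) {
    m <- fit$artifacts[[gid]]$matrix
    if (is.null(m) || !nrow(m)) next
    mats[[gid]] <- data.frame(group_id = gid, column = rownames(m),
                              as.data.frame(unclass(m[, , drop = FALSE])),
                              outgroup = attr(m, "outgroup_states"),
                              kept = fit$artifacts[[gid]]$keep,
                              stringsAsFactors = FALSE)
  }
  if (length(mats))
    write_tsv_stamped(do.call(rbind, c(mats, list(make.row.names = FALSE))),
                      file.path(outdir, "matrix.tsv"), hash)
  invisible(fit)
}

#' Run mechanism scans for a dataset and write the report
#'
#' Recomputes the (deterministic) inference for the dataset, scans the
#' accepted events, and writes the verdict TSV and bias-report JSON.
#'
#' @param dataset_dir dataset directory
#' @param outdir output directory
#' @param config a [pipeline_config()]
#' @return the `mechanism_scan` object, invisibly
#' @export
run_scan <- function(dataset_dir, outdir, config = pipeline_config()) {
  ds <- read_dataset(dataset_dir)
  fit <- intron_events(ds, config)
  scan <- scan_mechanisms(fit, ds, config)
  write_scan_report(scan, outdir)
  invisible(scan)
}
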