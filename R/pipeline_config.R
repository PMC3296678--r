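#' Pipeline configuration
#'
#' Collects every tunable threshold of the inference and mechanism-scan
#' stages, with defaults matching the study design this package
#' implements: reciprocal-best-hit orthology at e <= 1e-30, identity >=
#' 70% and query coverage >= 80% (relaxed to 60/60 for the distant
#' outgroup), a 10-column window for merging marker blocks into intron
#' position classes, a 15-column flank filter at mean identity 0.8,
#' GT..AG as the canonical splice pair, mechanism matching at query
#' coverage >= 90% and e <= 0.1, direct repeats >= 5 bp within 30 nt
#' junction windows, target-site duplications of 4-15 nt with at most one
#' mismatch, sliding detected beyond 10 columns, and a 1000-fold
#' mononucleotide shuffle null.
#'
#' Unknown keys are rejected.
#'
#' @param seed seed used by stochastic scan components (shuffle null,
#'   permutation tests)
#' @param rbh_min_identity,rbh_min_coverage,rbh_max_e ortholog thresholds
#' @param og_min_identity,og_min_coverage,og_max_e outgroup thresholds
#' @param merge_window marker-block merge window (columns)
#' @param flank_window,flank_min_identity flank filter parameters
#' @param canonical_splice list of allowed c(donor, acceptor) pairs
#' @param scan_min_coverage,scan_max_e insertion-source thresholds
#' @param repeat_min_len,repeat_window direct-repeat scan parameters
#' @param tsd_min_len,tsd_max_len,tsd_max_mismatch TSD scan parameters
#' @param slide_min_cols,slide_max_cols sliding-scan column window
#' @param n_shuffles shuffle-null replicates
#' @param n_perm adjacent-loss permutation replicates
#' @param shuffle_mode "mono" or "di" nucleotide shuffling
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(seed = 1L,
                            rbh_min_identity = 70,
                            rbh_min_coverage = 80,
                            rbh_max_e = 1e-30,
                            og_min_identity = 60,
                            og_min_coverage = 60,
                            og_max_e = 1e-30,
                            merge_window = 10L,
                            flank_window = 15L,
                            flank_min_identity = 0.8,
                            canonical_splice = list(c("GT", "AG")),
                            scan_min_coverage = 90,
                            scan_max_e = 0.1,
                            repeat_min_len = 5L,
                            repeat_window = 30L,
                            tsd_min_len = 4L,
                            tsd_max_len = 15L,
                            tsd_max_mismatch = 1L,
                            slide_min_cols = 10L,
                            slide_max_cols = 100L,
                            n_shuffles = 1000L,
                            n_perm = 10000L,
                            shuffle_mode = c("mono", "di")) {
  cfg <- as.list(environment())
  cfg$shuffle_mode <- match.arg(shuffle_mode)
  structure(cfg, class = "pipeline_config")
}
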