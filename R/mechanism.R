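# Bias statistics used to assess reverse-transcriptase-mediated intron
# loss (positional uniformity, germline-expression enrichment, adjacent
# losses) and the positional distribution of gains.

bias_report <- function(test, statistic, p_value, counts = NULL, n = NA_integer_) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), counts = counts, n = n),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$test,
              x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Relative positions of events within their genes
#'
#' For every event the position is `cds_offset / cds_length` in the member
#' gene carrying the intron that is closest on the tree to the event
#' branch (ties broken alphabetically by species).
#'
#' @param fit an `intron_events` object
#' @param calls subset of event calls to place (defaults to accepted calls)
#' @return numeric vector in (0, 1); events with no intron-bearing member
#'   are skipped with a warning
#' @export
relative_positions <- function(fit, calls = NULL) {
  if (is.null(calls))
    calls <- fit$calls[fit$calls$status == "accepted", , drop = FALSE]
  out <- numeric(0)
  for (i in seq_len(nrow(calls))) {
    pe <- position_evidence(fit, calls[i, , drop = FALSE])
    if (is.null(pe)) {
      warning("no member gene carries the intron for event in ",
              calls$group_id[i], " ", calls$column[i])
      next
    }
    out <- c(out, pe$cds_offset / pe$cds_len)
  }
  out
}

# nearest intron-bearing member of a call's column: returns species, gene
# model, intron row, distances measured on the ingroup tree
position_evidence <- function(fit, call) {
  art <- fit$artifacts[[call$group_id]]
  cls <- as.integer(sub("^col", "", call$column))
  mem <- art$colmap[art$colmap$column == cls, , drop = FALSE]
  mem <- mem[mem$species %in% fit$ingroup$tip.label, , drop = FALSE]
  if (!nrow(mem)) return(NULL)
  D <- ape::dist.nodes(fit$ingroup)
  target <- node_id(fit$ingroup, call$branch)
  d <- D[cbind(match(mem$species, fit$ingroup$tip.label), target)]
  mem <- mem[order(d, mem$species), , drop = FALSE]
  sp <- mem$species[1]
  gm <- model_lookup(fit, sp, art$group[[sp]])
  intron <- gm$introns[mem$intron_index[1] + 1L, , drop = FALSE]
  list(species = sp, gene = gm, intron = intron,
       cds_offset = intron$cds_offset, cds_len = nchar(gm$cds_seq))
}

# `key` is the internal species|gene_id group-member key
model_lookup <- function(fit, species, key) {
  ds <- read_dataset_cached(fit)
  ds$models[[species]][[sub("^[^|]*\\|", "", key)]]
}

# datasets are re-read lazily and memoised on the fit object environment
read_dataset_cached <- function(fit) {
  env <- attr(fit, "ds_env")
  if (is.null(env)) stop("internal: dataset cache not initialised")
  if (is.null(env$ds)) env$ds <- read_dataset(fit$dataset_dir)
  env$ds
}

#' One-sample Kolmogorov-Smirnov test against Uniform(0, 1)
#'
#' Two-sided KS statistic with the asymptotic (Kolmogorov-distribution)
#' p-value.  The tail is evaluated from the alternating theta-function
#' series to machine precision; [stats::ks.test()]'s asymptotic path
#' truncates the same series at an absolute tolerance of 1e-6, which is
#' too coarse for this package's cross-validation against an independent
#' oracle.
#'
#' @param positions numeric vector in [0, 1], length >= 5
#' @return a `bias_report` with the two-sided asymptotic KS statistic
#' @export
ks_uniform <- function(positions) {
  if (length(positions) < 5L)
    stop("need at least 5 positions for the KS test (have ",
         length(positions), ")")
  stopifnot(all(positions >= 0), all(positions <= 1))
  n <- length(positions)
  x <- sort(positions)
  i <- seq_len(n)
  D <- max(pmax(i / n - x, x - (i - 1) / n))
  lam <- sqrt(n) * D
  k <- seq_len(1000L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * lam^2 * k^2))
  p <- min(1, max(0, p))
  bias_report("KS uniformity", c(D = D), p, n = n)
}

#' Germline-expression enrichment of event genes
#'
#' Pearson chi-square (no continuity correction) on the 2x2 table of
#' germline-expressed counts among event genes versus a background set.
#'
#' @param event_germline,event_total counts for genes with events
#' @param background_germline,background_total background counts
#' @return a `bias_report`
#' @export
germline_enrichment <- function(event_germline, event_total,
                                background_germline, background_total) {
  stopifnot(event_germline <= event_total,
            background_germline <= background_total)
  tab <- matrix(c(event_germline, event_total - event_germline,
                  background_germline, background_total - background_germline),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate contingency table (zero margin)")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  bias_report("germline enrichment (Pearson chi-square)",
              ct$statistic, ct$p.value, counts = tab,
              n = event_total + background_total)
}

#' Goodness-of-fit chi-square for an observed versus expected count
#'
#' One-cell goodness of fit, (obs - exp)^2 / exp with 1 degree of freedom;
#' used for the adjacent-loss excess.
#'
#' @param observed,expected counts (expected may be fractional)
#' @return a `bias_report`
#' @export
adjacent_loss_chisq <- function(observed, expected) {
  if (expected <= 0) {
    return(bias_report("adjacent-loss excess (GOF chi-square)",
                       if (observed > 0) Inf else 0,
                       if (observed > 0) 0 else 1,
                       counts = c(observed = observed, expected = expected)))
  }
  stat <- (observed - expected)^2 / expected
  bias_report("adjacent-loss excess (GOF chi-square)", stat,
              pchisq(stat, df = 1, lower.tail = FALSE),
              counts = c(observed = observed, expected = expected))
}

#' Excess of adjacent intron losses
#'
#' Counts pairs of losses at consecutive intron positions called on the
#' same branch of the same gene, and compares the count with its
#' permutation expectation (each gene's losses redistributed uniformly at
#' random over the gene's intron positions, `n_perm` times) by a
#' goodness-of-fit chi-square.
#'
#' @param loss_calls data.frame with columns `gene`, `branch`, `position`
#'   (ordinal intron position within the gene, 1-based)
#' @param intron_counts named integer vector: intron positions per gene
#' @param n_perm permutation replicates
#' @param seed optional RNG seed
#' @return a `bias_report`
#' @export
adjacent_loss_test <- function(loss_calls, intron_counts, n_perm = 10000L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  count_adjacent <- function(pos_by_key) {
    sum(vapply(pos_by_key, function(p)
      sum(diff(sort(p)) == 1L), numeric(1)))
  }
  key <- paste(loss_calls$gene, loss_calls$branch, sep = "\r")
  obs <- count_adjacent(split(loss_calls$position, key))
  genes_of_key <- vapply(split(loss_calls$gene, key), `[[`, character(1), 1L)
  k_of_key <- lengths(split(loss_calls$position, key))
  if (any(k_of_key > intron_counts[genes_of_key]))
    stop("a gene has more losses than intron positions")
  exp_vals <- vapply(seq_len(n_perm), function(i) {
    count_adjacent(mapply(function(g, k)
      sample.int(intron_counts[[g]], k), genes_of_key, k_of_key,
      SIMPLIFY = FALSE))
  }, numeric(1))
  expected <- mean(exp_vals)
  rep <- adjacent_loss_chisq(obs, expected)
  rep$test <- "adjacent-loss excess (permutation + GOF chi-square)"
  rep$n <- nrow(loss_calls)
  rep
}
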