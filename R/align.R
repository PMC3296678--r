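# Local alignment and e-value machinery.

# Gumbel parameters for the default nucleotide scoring, fitted once with
# calibrate_evalue() at its default length grid and seed; see that function.
EVALUE_LAMBDA <- 0.19504
EVALUE_K <- 0.57195

#' Scoring scheme for local alignment
#'
#' Match +5, mismatch -4, affine gaps costing `gap_open` for the first and
#' `gap_extend` for each further gapped position.  Ambiguity codes never
#' match.  The default gap costs keep random-alignment scores in the
#' logarithmic (Gumbel) regime, where the Karlin-Altschul e-value model is
#' valid across the query/target sizes the pipeline scans; cheaper gap
#' extension lets random alignments chain matches and grow near-linearly
#' with length, which no single (K, lambda) pair can describe.
#'
#' @param match,mismatch substitution scores
#' @param gap_open,gap_extend positive gap costs
#' @param lambda,K Karlin-Altschul parameters used to turn scores into
#'   e-values; defaults were fitted against a shuffled-pair score
#'   distribution with [calibrate_evalue()]
#' @return list of scoring parameters
#' @export
align_scoring <- function(match = 5, mismatch = -4, gap_open = 16,
                          gap_extend = 8, lambda = EVALUE_LAMBDA,
                          K = EVALUE_K) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, lambda = lambda, K = K)
}

#' Karlin-Altschul e-value for a local alignment score
#'
#' @param score alignment score
#' @param m,n lengths of the two sequences
#' @param scoring an [align_scoring()] list
#' @return expected number of chance alignments scoring at least `score`
#' @export
align_evalue <- function(score, m, n, scoring = align_scoring()) {
  scoring$K * m * n * exp(-scoring$lambda * score)
}

#' Optimal local alignment of two nucleotide sequences
#'
#' Smith-Waterman with affine gaps.  Returns the score together with
#' percent identity over aligned columns, percent of the query covered,
#' and the Karlin-Altschul e-value.
#'
#' @param query,target nucleotide strings
#' @param scoring an [align_scoring()] list
#' @return one-row data.frame: `score`, `identity_pct`,
#'   `query_coverage_pct`, `e_value`, plus the aligned coordinate ranges
#'   (1-based)
#' @export
local_align <- function(query, target, scoring = align_scoring()) {
  stopifnot(nchar(query) > 0L, nchar(target) > 0L)
  al <- sw_align_cpp(toupper(query), toupper(target),
                     match = scoring$match, mismatch = scoring$mismatch,
                     gap_open = scoring$gap_open,
                     gap_extend = scoring$gap_extend)
  idp <- if (al$aligned_cols > 0L) 100 * al$n_ident / al$aligned_cols else 0
  cov <- 100 * al$q_aligned / nchar(query)
  data.frame(score = al$score, identity_pct = idp, query_coverage_pct = cov,
             e_value = align_evalue(al$score, nchar(query), nchar(target),
                                    scoring),
             q_start = al$q_start, q_end = al$q_end, t_start = al$t_start,
             t_end = al$t_end, stringsAsFactors = FALSE)
}

#' Fit Karlin-Altschul parameters against a shuffle null
#'
#' Aligns independent random sequence pairs over a grid of query/target
#' lengths spanning the sizes the pipeline scans (junction residues up to
#' full coding sequences against introns up to an organelle genome) and
#' fits the Gumbel law P(S <= x) = exp(-K m n e^(-lambda x)): the scale
#' 1/lambda is pooled over grid cells by the method of moments, and K is
#' taken from the grid cell with the largest implied K so that e-values
#' stay conservative in every regime.  The package default constants were
#' produced by this function with its default arguments; it is exported so
#' the calibration is reproducible.
#'
#' @param n_per_cell random pairs per grid cell
#' @param query_lens,target_lens the length grid
#' @param seed RNG seed
#' @param scoring an [align_scoring()] list (substitution/gap scores only;
#'   lambda/K ignored)
#' @return list with elements `lambda`, `K` and the per-cell fit table
#' @export
calibrate_evalue <- function(n_per_cell = 300L,
                             query_lens = c(24L, 60L, 113L, 400L),
                             target_lens = c(400L, 2000L, 16000L),
                             seed = 1L, scoring = align_scoring()) {
  set.seed(seed)
  grid <- expand.grid(m = query_lens, n = target_lens)
  grid$mu <- grid$beta <- NA_real_
  for (i in seq_len(nrow(grid))) {
    s <- vapply(seq_len(n_per_cell), function(j) {
      sw_score_cpp(rand_dna(grid$m[i]), rand_dna(grid$n[i]),
                   match = scoring$match, mismatch = scoring$mismatch,
                   gap_open = scoring$gap_open,
                   gap_extend = scoring$gap_extend)
    }, numeric(1))
    grid$beta[i] <- stats::sd(s) * sqrt(6) / pi
    grid$mu[i] <- mean(s) - 0.5772156649 * grid$beta[i]
  }
  lambda <- 1 / mean(grid$beta)
  grid$K <- exp(lambda * grid$mu) / (grid$m * grid$n)
  list(lambda = lambda, K = max(grid$K), grid = grid)
}

# strided k-mers of a sequence (used to prescreen all-vs-all pairs); the
# stride thins the index without losing sensitivity for near-identical pairs
kmer_set <- function(seq, k = 12L, stride = 1L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq.int(1L, n - k + 1L, by = stride)
  unique(substring(seq, starts, starts + k - 1L))
}

#' All-against-all similarity hits between species' coding sequences
#'
#' Computes Smith-Waterman hits for every cross-species sequence pair that
#' passes a shared k-mer prescreen (pairs sharing fewer than `min_kmers`
#' k-mers cannot approach the reciprocal-best-hit thresholds and are
#' skipped).  Both query/target directions are reported for every aligned
#' pair.
#'
#' @param seqs named character vector of CDS sequences
#' @param species named character vector: species of each sequence id
#' @param scoring an [align_scoring()] list
#' @param k,min_kmers prescreen parameters
#' @return data.frame of hits (`query_id`, `target_id`, `score`,
#'   `identity_pct`, `query_coverage_pct`, `e_value`)
#' @export
all_vs_all_hits <- function(seqs, species, scoring = align_scoring(),
                            k = 12L, min_kmers = 3L, stride = 4L) {
  ids <- names(seqs)
  stopifnot(!is.null(ids), all(ids %in% names(species)))
  kmers <- lapply(seqs, kmer_set, k = k, stride = stride)
  # invert the index: k-mer -> sequence indices
  inv <- split(rep(seq_along(ids), lengths(kmers)), unlist(kmers))
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (v in inv) {
    if (length(v) < 2L) next
    for (a in seq_len(length(v) - 1L)) {
      for (b in seq((a + 1L), length(v))) {
        i <- v[a]; j <- v[b]
        if (species[[ids[i]]] == species[[ids[j]]]) next
        key <- paste0(i, "_", j)
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  rows <- list(); nr <- 0L
  for (key in ls(counts)) {
    if (counts[[key]] < min_kmers) next
    ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    qi <- ids[ij[1]]; ti <- ids[ij[2]]
    al <- sw_align_cpp(seqs[[qi]], seqs[[ti]],
                       match = scoring$match, mismatch = scoring$mismatch,
                       gap_open = scoring$gap_open,
                       gap_extend = scoring$gap_extend)
    if (al$score <= 0) next
    idp <- 100 * al$n_ident / al$aligned_cols
    t_aligned <- al$t_end - al$t_start + 1L
    nr <- nr + 1L
    rows[[nr]] <- data.frame(
      query_id = c(qi, ti), target_id = c(ti, qi),
      score = al$score, identity_pct = idp,
      query_coverage_pct = 100 * c(al$q_aligned / nchar(seqs[[qi]]),
                                   t_aligned / nchar(seqs[[ti]])),
      e_value = align_evalue(al$score, nchar(seqs[[qi]]), nchar(seqs[[ti]]),
                             scoring),
      stringsAsFactors = FALSE)
  }
  if (!nr) {
    return(data.frame(query_id = character(), target_id = character(),
                      score = numeric(), identity_pct = numeric(),
                      query_coverage_pct = numeric(), e_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
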