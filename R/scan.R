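# Mechanism attribution for accepted events: insertion-source scans
# (transposon library, organelle genome), shuffle-null significance,
# NHEJ junction residues, and intron sliding.

#' Scan a gained intron against an insertion-source library
#'
#' Locally aligns the intron (both strands) against every library sequence
#' and returns hits passing the query-coverage and e-value thresholds,
#' best first.
#'
#' @param intron_seq gained intron sequence (>= 20 nt)
#' @param library named character vector (e.g. transposon library, or a
#'   single organelle genome)
#' @param min_coverage,max_e acceptance thresholds
#' @param scoring an [align_scoring()] list
#' @return data.frame of hits: `partner`, `strand`, `score`,
#'   `identity_pct`, `coverage_pct`, `e_value`, `t_start`, `t_end`
#' @export
scan_insertion_source <- function(intron_seq, library, min_coverage = 90,
                                  max_e = 0.1, scoring = align_scoring()) {
  empty <- data.frame(partner = character(), strand = character(),
                      score = numeric(), identity_pct = numeric(),
                      coverage_pct = numeric(), e_value = numeric(),
                      t_start = integer(), t_end = integer(),
                      stringsAsFactors = FALSE)
  if (length(library) == 0L) return(empty)
  if (nchar(intron_seq) < 20L)
    stop("intron too short to scan (< 20 nt)")
  rows <- list(); nr <- 0L
  for (strand in c("+", "-")) {
    q <- if (strand == "+") intron_seq else revcomp(intron_seq)
    for (id in names(library)) {
      h <- local_align(q, library[[id]], scoring)
      if (h$query_coverage_pct >= min_coverage && h$e_value <= max_e) {
        nr <- nr + 1L
        rows[[nr]] <- data.frame(partner = id, strand = strand,
                                 score = h$score,
                                 identity_pct = h$identity_pct,
                                 coverage_pct = h$query_coverage_pct,
                                 e_value = h$e_value, t_start = h$t_start,
                                 t_end = h$t_end, stringsAsFactors = FALSE)
      }
    }
  }
  if (!nr) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$e_value, -out$score), , drop = FALSE]
}

#' Shuffle-null p-value for a local alignment
#'
#' Shuffles the query `n_shuffles` times (mononucleotide permutation by
#' default, dinucleotide shuffling optionally), realigns against the fixed
#' target, and returns `(1 + #\{shuffled score >= observed\}) /
#' (n_shuffles + 1)`.
#'
#' @param query,target nucleotide strings (query >= 20 nt)
#' @param n_shuffles number of shuffles (>= 1)
#' @param seed optional RNG seed
#' @param mode "mono" or "di" nucleotide shuffle
#' @param scoring an [align_scoring()] list
#' @return p-value in (0, 1]
#' @export
shuffle_null_p <- function(query, target, n_shuffles = 1000L, seed = NULL,
                           mode = c("mono", "di"),
                           scoring = align_scoring()) {
  mode <- match.arg(mode)
  if (n_shuffles < 1L) stop("n_shuffles must be at least 1")
  if (nchar(query) < 20L) stop("query shorter than 20 nt")
  if (!is.null(seed)) set.seed(seed)
  obs <- sw_score_cpp(query, target, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  shuffle <- function() {
    if (mode == "mono") {
      paste(sample(chars(query)), collapse = "")
    } else {
      # dinucleotide shuffle: permute non-overlapping dinucleotide tiles
      v <- chars(query)
      n <- length(v) - length(v) %% 2L
      tiles <- paste0(v[seq(1, n, 2)], v[seq(2, n, 2)])
      paste0(paste(sample(tiles), collapse = ""),
             if (n < length(v)) v[length(v)] else "")
    }
  }
  ge <- 0L
  for (i in seq_len(n_shuffles)) {
    s <- sw_score_cpp(shuffle(), target, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
    if (s >= obs) ge <- ge + 1L
  }
  (1 + ge) / (n_shuffles + 1)
}

# junction residues left in a losing species: alignment columns near the
# lost column where the loser has nucleotides and every intron-bearing
# species has a gap
junction_residues <- function(aln, colmap, cls, loser, window = 45L) {
  mem <- colmap[colmap$column == cls, , drop = FALSE]
  donors <- setdiff(unique(mem$species), loser)
  if (!length(donors) || !loser %in% names(aln$rows)) return(NULL)
  cm <- do.call(rbind, strsplit(unname(unlist(aln$rows[c(loser, donors)])), ""))
  lo <- max(1L, min(mem$block_start) - window)
  hi <- min(ncol(cm), max(mem$block_end) + window)
  sel <- lo:hi
  loser_nt <- cm[1, sel] %in% c("A", "C", "G", "T", "N")
  donors_gap <- colSums(cm[-1, sel, drop = FALSE] == "-") == length(donors)
  res <- cm[1, sel][loser_nt & donors_gap]
  if (!length(res)) return(NULL)
  paste(res, collapse = "")
}

#' NHEJ signature of an imprecise intron loss
#'
#' Extracts nucleotides that the losing species retains at the former
#' intron position (alignment columns where the loser has sequence and all
#' intron-bearing members have gaps), aligns them against the conserved
#' orthologous intron of the closest intron-bearing species, and reports a
#' hit when the alignment reaches `max_e`.  Junction direct repeats of the
#' donor intron are included.
#'
#' @param fit an `intron_events` object
#' @param call one-row loss call
#' @param max_e e-value threshold
#' @param repeat_min_len,repeat_window direct-repeat scan parameters
#' @param scoring an [align_scoring()] list
#' @return list signature hit (`mechanism = "nhej_loss"`) or NULL for a
#'   precise loss
#' @export
detect_imprecise_loss <- function(fit, call, max_e = 0.1,
                                  repeat_min_len = 5L, repeat_window = 30L,
                                  scoring = align_scoring()) {
  stopifnot(nrow(call) == 1L, call$type == "loss")
  art <- fit$artifacts[[call$group_id]]
  cls <- as.integer(sub("^col", "", call$column))
  losers <- strsplit(call$leaves, ";", fixed = TRUE)[[1]]
  pe <- position_evidence(fit, call)
  if (is.null(pe)) return(NULL)
  for (loser in sort(losers)) {
    res <- junction_residues(art$aln, art$colmap, cls, loser)
    if (is.null(res) || nchar(res) < 3L) next
    h <- local_align(res, pe$intron$seq, scoring)
    if (h$e_value <= max_e) {
      flank <- donor_junction(fit, pe)
      reps <- find_direct_repeats(flank$left, pe$intron$seq, flank$right,
                                  min_len = repeat_min_len,
                                  window = repeat_window)
      return(list(mechanism = "nhej_loss", loser = loser,
                  partner = paste0(pe$species, ":intron",
                                   pe$intron$index),
                  residues = res, identity_pct = h$identity_pct,
                  coverage_pct = h$query_coverage_pct,
                  e_value = h$e_value,
                  repeat_seq = if (nrow(reps)) reps$seq[1] else NA_character_))
    }
  }
  NULL
}

# exonic flanks around a donor intron
donor_junction <- function(fit, pe, window = 30L) {
  cds <- pe$gene$cds_seq
  o <- pe$intron$cds_offset
  list(left = substr(cds, max(1L, o - window + 1L), o),
       right = substr(cds, o + 1L, min(nchar(cds), o + window)))
}

#' Detect intron sliding between nearby intron-position columns
#'
#' Column classes that failed the merge window but lie within
#' `slide_max_cols` of each other are candidate slid pairs.  For each
#' pair, the intron of a species present only in one class is aligned
#' against the intron of the closest species present only in the other;
#' sequence similarity at `max_e` marks sliding rather than coincidental
#' loss plus gain.
#'
#' @param fit an `intron_events` object
#' @param group_id ortholog group to scan
#' @param min_shift_cols,max_sep_cols column-shift window
#' @param max_e e-value threshold
#' @param scoring an [align_scoring()] list
#' @return data.frame of sliding signature hits
#' @export
detect_sliding <- function(fit, group_id, min_shift_cols = 10L,
                           max_sep_cols = 100L, max_e = 0.1,
                           scoring = align_scoring()) {
  empty <- data.frame(group_id = character(), column_a = integer(),
                      column_b = integer(), species_a = character(),
                      species_b = character(), shift_cols = integer(),
                      identity_pct = numeric(), e_value = numeric(),
                      stringsAsFactors = FALSE)
  art <- fit$artifacts[[group_id]]
  if (is.null(art$colmap) || !nrow(art$colmap)) return(empty)
  cm <- art$colmap
  classes <- sort(unique(cm$column))
  starts <- vapply(classes, function(cl)
    min(cm$block_start[cm$column == cl]), integer(1))
  rows <- list(); nr <- 0L
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      if (j <= i) next
      shift <- abs(starts[j] - starts[i])
      if (shift <= min_shift_cols || shift > max_sep_cols) next
      sa <- unique(cm$species[cm$column == classes[i]])
      sb <- unique(cm$species[cm$column == classes[j]])
      only_a <- setdiff(sa, sb); only_b <- setdiff(sb, sa)
      if (!length(only_a) || !length(only_b)) next
      pa <- sort(only_a)[1]; pb <- sort(only_b)[1]
      ia <- intron_of(fit, group_id, classes[i], pa)
      ib <- intron_of(fit, group_id, classes[j], pb)
      if (is.null(ia) || is.null(ib)) next
      h <- local_align(ia$seq, ib$seq, scoring)
      if (h$e_value <= max_e) {
        nr <- nr + 1L
        rows[[nr]] <- data.frame(group_id = group_id,
                                 column_a = classes[i],
                                 column_b = classes[j],
                                 species_a = pa, species_b = pb,
                                 shift_cols = shift,
                                 identity_pct = h$identity_pct,
                                 e_value = h$e_value,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  if (!nr) return(empty)
  do.call(rbind, rows)
}

intron_of <- function(fit, group_id, cls, species) {
  art <- fit$artifacts[[group_id]]
  mem <- art$colmap[art$colmap$column == cls &
                      art$colmap$species == species, , drop = FALSE]
  if (!nrow(mem)) return(NULL)
  gm <- model_lookup(fit, species, art$group[[species]])
  gm$introns[mem$intron_index[1] + 1L, , drop = FALSE]
}
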