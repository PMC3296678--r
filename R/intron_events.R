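#' Infer intron gain and loss events for a dataset
#'
#' The central fitting function of the package.  Runs ortholog detection
#' (reciprocal best hits over Smith-Waterman alignments, with relaxed
#' thresholds for the designated outgroup), marked progressive alignment
#' of every ortholog group, intron-position column mapping, the
#' flank-identity filter, Dollo-parsimony event calling with outgroup
#' polarization, and the annotation-error quality controls for
#' single-species gains.
#'
#' @param x a dataset directory or an `intron_dataset` from
#'   [read_dataset()]
#' @param config a [pipeline_config()]
#' @return an `intron_events` object: the event-call table (`calls`),
#'   ortholog groups, per-group alignments/column maps/matrices
#'   (`artifacts`), the trees, and the per-branch summary
#' @export
intron_events <- function(x, config = pipeline_config()) {
  ds <- if (inherits(x, "intron_dataset")) x else read_dataset(x)
  tree <- ds$tree
  outg <- ds$outgroup
  ingroup <- if (!is.null(outg)) ape::drop.tip(tree, outg) else tree
  attr(ingroup, "outgroup") <- NULL
  ing_species <- intersect(ds$species, ingroup$tip.label)
  if (!length(ing_species)) stop("no ingroup species found in dataset")

  # flatten models; keys are species|gene so ids stay globally unique
  keys <- character(0); species_of <- character(0); seqs <- character(0)
  model_of <- list()
  for (sp in ds$species) {
    for (g in names(ds$models[[sp]])) {
      key <- paste0(sp, "|", g)
      keys <- c(keys, key)
      species_of[key] <- sp
      seqs[key] <- ds$models[[sp]][[g]]$cds_seq
      model_of[[key]] <- ds$models[[sp]][[g]]
    }
  }

  scoring <- align_scoring()
  hits <- all_vs_all_hits(seqs, species_of, scoring)
  is_og <- function(v) !is.null(outg) & v == outg
  hq <- species_of[hits$query_id]; ht <- species_of[hits$target_id]
  ing_hits <- hits[!is_og(hq) & !is_og(ht), , drop = FALSE]
  groups <- reciprocal_best_hits(ing_hits, species_of,
                                 min_identity = config$rbh_min_identity,
                                 min_coverage = config$rbh_min_coverage,
                                 max_e = config$rbh_max_e)
  if (!length(groups)) stop("no ortholog groups found")
  if (!is.null(outg)) {
    og_hits <- hits[xor(is_og(hq), is_og(ht)), , drop = FALSE]
    groups <- attach_outgroup(groups, og_hits, species_of, outg,
                              min_identity = config$og_min_identity,
                              min_coverage = config$og_min_coverage,
                              max_e = config$og_max_e)
  }

  calls_all <- list(); artifacts <- list()
  dropped_cols <- 0L
  for (gid in names(groups)) {
    grp <- groups[[gid]]
    members <- setNames(lapply(grp, function(k) model_of[[k]]), names(grp))
    marked <- vapply(members, insert_markers, character(1))
    if (sum(vapply(members, function(m) nrow(m$introns), integer(1))) == 0L) {
      artifacts[[gid]] <- list(group = grp, aln = NULL, colmap = NULL,
                               matrix = NULL)
      next
    }
    aln <- align_group(marked)
    colmap <- map_intron_columns(aln, max_offset_cols = config$merge_window)
    mat <- presence_matrix(colmap, grp, ing_species, outg)
    # flank filter per column class
    keep <- logical(nrow(mat))
    flanks <- vector("list", nrow(mat))
    for (r in seq_len(nrow(mat))) {
      ff <- flank_filter(aln, attr(mat, "col_start")[r],
                         attr(mat, "col_end")[r],
                         window = config$flank_window,
                         min_mean_identity = config$flank_min_identity)
      keep[r] <- ff$keep
      flanks[[r]] <- ff
    }
    dropped_cols <- dropped_cols + sum(!keep)
    og_states <- attr(mat, "outgroup_states")[keep]
    submat <- mat[keep, , drop = FALSE]
    calls <- dollo_events(submat, ingroup, og_states)
    if (nrow(calls)) {
      calls$group_id <- gid
      cls <- as.integer(sub("^col", "", calls$column))
      calls$col_start <- attr(mat, "col_start")[match(
        calls$column, rownames(mat))]
      # annotation-error QC for single-species gains
      for (i in seq_len(nrow(calls))) {
        if (calls$type[i] != "gain" || !calls$single_species[i]) next
        sp <- calls$branch[i]
        mem <- colmap[colmap$column == cls[i] & colmap$species == sp, ,
                      drop = FALSE]
        if (!nrow(mem)) next
        gm <- members[[sp]]
        intron <- gm$introns[mem$intron_index[1] + 1L, , drop = FALSE]
        calls[i, ] <- qc_gain_filters(calls[i, , drop = FALSE], intron, gm,
                                      canonical = config$canonical_splice)
      }
      calls_all[[gid]] <- calls
    }
    artifacts[[gid]] <- list(group = grp, aln = aln, colmap = colmap,
                             matrix = mat, keep = keep, flanks = flanks,
                             excluded = attr(calls, "excluded"))
  }
  calls <- if (length(calls_all)) do.call(rbind, calls_all) else
    data.frame(column = character(), type = character(), branch = character(),
               single_species = logical(), n_leaves = integer(),
               leaves = character(), status = character(),
               qc_flags = character(), group_id = character(),
               col_start = integer(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  fit <- structure(list(calls = calls, groups = groups,
                        artifacts = artifacts, tree = tree,
                        ingroup = ingroup, outgroup = outg,
                        species = ds$species, config = config,
                        dataset_dir = ds$dir,
                        dropped_columns = dropped_cols,
                        summary = summarize_events(calls, ingroup)),
                   class = "intron_events")
  env <- new.env(parent = emptyenv())
  env$ds <- ds
  attr(fit, "ds_env") <- env
  fit
}

# assign at most one outgroup gene to each group via mutual best hits at
# relaxed thresholds
attach_outgroup <- function(groups, og_hits, species_of, outg,
                            min_identity, min_coverage, max_e) {
  if (nrow(og_hits) == 0L) return(groups)
  ok <- og_hits[og_hits$identity_pct >= min_identity &
                  og_hits$query_coverage_pct >= min_coverage &
                  og_hits$e_value <= max_e, , drop = FALSE]
  if (nrow(ok) == 0L) return(groups)
  best_to_og <- character(0)   # ingroup key -> best outgroup key
  from_in <- ok[species_of[ok$query_id] != outg, , drop = FALSE]
  for (q in unique(from_in$query_id)) {
    sub <- from_in[from_in$query_id == q, , drop = FALSE]
    top <- sub[sub$score == max(sub$score), , drop = FALSE]
    if (nrow(top) == 1L) best_to_og[q] <- top$target_id
  }
  from_og <- ok[species_of[ok$query_id] == outg, , drop = FALSE]
  best_from_og <- character(0) # "oggene\rspecies" -> ingroup key
  key <- paste(from_og$query_id, species_of[from_og$target_id], sep = "\r")
  for (k in unique(key)) {
    sub <- from_og[key == k, , drop = FALSE]
    top <- sub[sub$score == max(sub$score), , drop = FALSE]
    if (nrow(top) == 1L) best_from_og[k] <- top$target_id
  }
  for (gid in names(groups)) {
    grp <- groups[[gid]]
    cand <- unique(stats::na.omit(unname(best_to_og[grp])))
    if (length(cand) != 1L) next
    # reciprocity: the outgroup gene must point back at a group member
    back <- best_from_og[paste(cand, names(grp), sep = "\r")]
    if (any(!is.na(back) & back %in% grp)) {
      grp[outg] <- cand
      groups[[gid]] <- grp
    }
  }
  groups
}

#' @export
print.intron_events <- function(x, ...) {
  acc <- x$calls[x$calls$status == "accepted", , drop = FALSE]
  cat(sprintf(paste0("<intron_events> %d ortholog groups, %d accepted ",
                     "events (%d gains, %d losses), %d rejected by QC\n"),
              length(x$groups), nrow(acc), sum(acc$type == "gain"),
              sum(acc$type == "loss"),
              sum(x$calls$status == "rejected")))
  invisible(x)
}

#' @export
summary.intron_events <- function(object, ...) {
  s <- object$summary
  cat("Accepted intron gain/loss events\n")
  cat(sprintf("  gains:  %d (%d single-species, %d ancestral)\n",
              s$totals$total[1], s$totals$single_species[1],
              s$totals$ancestral[1]))
  cat(sprintf("  losses: %d (%d single-species, %d ancestral)\n",
              s$totals$total[2], s$totals$single_species[2],
              s$totals$ancestral[2]))
  cat(sprintf("  columns dropped by flank filter: %d\n",
              object$dropped_columns))
  cat("\nPer-species events (single-species calls):\n")
  print(s$per_species, row.names = FALSE)
  invisible(s)
}

#' Plot the species tree with per-branch event counts
#'
#' Draws the ingroup tree and labels each edge with the number of accepted
#' gains (+) and losses (-) placed on it.
#'
#' @param x an `intron_events` object
#' @param ... passed to [ape::plot.phylo()]
#' @export
plot.intron_events <- function(x, ...) {
  tr <- x$ingroup
  pb <- x$summary$per_branch
  lab <- sprintf("+%d/-%d", pb$gains, pb$losses)
  lab[pb$gains == 0 & pb$losses == 0] <- ""
  ape::plot.phylo(tr, ...)
  idx <- match(node_label(tr, tr$edge[, 2]), pb$branch)
  ape::edgelabels(lab[idx], frame = "none", adj = c(0.5, -0.3))
  invisible(x)
}

#' Compare inferred calls with a simulation truth log
#'
#' Maps every accepted call to the simulator's column identity through the
#' per-leaf intron map and computes exact-recovery precision and recall
#' against the real (non-annotation-error) events, plus the rejection rate
#' of injected annotation errors and the retention rate of true
#' single-species gains.
#'
#' @param fit an `intron_events` object
#' @param dataset an `intron_dataset` carrying `truth` and `intron_map`
#' @return list of precision/recall/QC rates and the matched tables
#' @export
recovery_stats <- function(fit, dataset) {
  truth <- dataset$truth
  imap <- dataset$intron_map
  if (is.null(truth) || is.null(imap))
    stop("dataset carries no simulation truth")
  imap_key <- paste(imap$species, imap$gene, imap$intron_index, sep = "\r")
  col_of <- setNames(imap$column, imap_key)

  # resolve each call to a truth column id via its member introns
  resolve <- function(calls) {
    out <- character(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      art <- fit$artifacts[[calls$group_id[i]]]
      cls <- as.integer(sub("^col", "", calls$column[i]))
      mem <- art$colmap[art$colmap$column == cls, , drop = FALSE]
      fams <- sub("^[^|]*\\|[^_]*_", "", art$group[mem$species])
      k <- paste(mem$species, fams, mem$intron_index, sep = "\r")
      cols <- unique(stats::na.omit(unname(col_of[k])))
      out[i] <- if (length(cols) == 1L) cols else NA_character_
    }
    out
  }
  calls <- fit$calls
  calls$truth_column <- resolve(calls)
  acc <- calls[calls$status == "accepted", , drop = FALSE]

  real <- truth[!truth$mechanism %in% "annotation_error" &
                  truth$type %in% c("gain", "loss"), , drop = FALSE]
  truth_set <- paste(real$column, real$branch, real$type, sep = "\r")
  call_set <- paste(acc$truth_column, acc$branch, acc$type, sep = "\r")
  tp <- sum(call_set %in% truth_set)
  precision <- if (nrow(acc)) tp / nrow(acc) else NA_real_
  recall <- if (length(truth_set)) sum(truth_set %in% call_set) /
    length(truth_set) else NA_real_

  fake <- truth[truth$mechanism %in% "annotation_error", , drop = FALSE]
  fake_set <- paste(fake$column, fake$branch, "gain", sep = "\r")
  rej <- calls[calls$status == "rejected", , drop = FALSE]
  rej_set <- paste(rej$truth_column, rej$branch, rej$type, sep = "\r")
  fake_rejected <- if (nrow(fake)) mean(fake_set %in% rej_set) else NA_real_

  true_ss <- real[real$type == "gain" &
                    real$branch %in% fit$ingroup$tip.label, , drop = FALSE]
  tss_set <- paste(true_ss$column, true_ss$branch, "gain", sep = "\r")
  acc_set <- paste(acc$truth_column, acc$branch, acc$type, sep = "\r")
  true_gain_retained <- if (nrow(true_ss)) mean(tss_set %in% acc_set)
                        else NA_real_

  list(precision = precision, recall = recall,
       n_called = nrow(acc), n_truth = nrow(real),
       annot_error_rejected = fake_rejected,
       true_single_gain_retained = true_gain_retained,
       calls = calls)
}
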