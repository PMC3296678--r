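# Presence/absence matrices over homologous intron-position columns, and
# the flank-identity filter that removes unreliable columns.

#' Build an intron presence/absence matrix for one ortholog group
#'
#' Rows are homologous intron-position classes, columns are ingroup
#' species.  A cell is 1 when the species carries a marker block in the
#' class, 0 when the species belongs to the group but lacks the intron,
#' and NA (missing) when the species has no gene in the group.  Outgroup
#' presence/absence is carried alongside as an attribute, not as a matrix
#' column.
#'
#' @param colmap an `intron_column_map`
#' @param group named character vector (species -> gene id)
#' @param ingroup_species all ingroup species names (matrix columns)
#' @param outgroup outgroup species name or NULL
#' @return integer matrix with attributes `outgroup_states`, `col_start`,
#'   `col_end`
#' @export
presence_matrix <- function(colmap, group, ingroup_species, outgroup = NULL) {
  classes <- sort(unique(colmap$column))
  mat <- matrix(NA_integer_, length(classes), length(ingroup_species),
                dimnames = list(paste0("col", classes), ingroup_species))
  og_states <- rep(NA_integer_, length(classes))
  col_start <- col_end <- integer(length(classes))
  in_group <- intersect(ingroup_species, names(group))
  for (i in seq_along(classes)) {
    members <- colmap[colmap$column == classes[i], , drop = FALSE]
    mat[i, in_group] <- 0L
    mat[i, intersect(members$species, ingroup_species)] <- 1L
    if (!is.null(outgroup) && outgroup %in% names(group))
      og_states[i] <- as.integer(outgroup %in% members$species)
    col_start[i] <- min(members$block_start)
    col_end[i] <- max(members$block_end)
  }
  attr(mat, "outgroup_states") <- og_states
  attr(mat, "col_start") <- col_start
  attr(mat, "col_end") <- col_end
  mat
}

#' Flank-identity filter for an intron-position column
#'
#' A column is kept only when the alignment flanking the marker region is
#' credible on both sides: over the `window` nearest marker-free columns
#' on each side, the mean pairwise identity of non-gap positions must
#' reach `min_mean_identity`.  Fewer than 5 comparable columns on a side
#' (after truncation at the alignment ends) drops the column.
#'
#' @param aln a `marked_alignment`
#' @param col_start,col_end first and last alignment column of the marker
#'   region (class representative block range)
#' @param window flank width in columns
#' @param min_mean_identity inclusive acceptance threshold
#' @return list: `keep` plus the per-side identities
#' @export
flank_filter <- function(aln, col_start, col_end, window = 15L,
                         min_mean_identity = 0.8) {
  cm <- do.call(rbind, strsplit(unname(unlist(aln$rows)), ""))
  L <- ncol(cm)
  has_x <- colSums(cm == "X") > 0
  # comparable: at least two rows carry sequence (single-row insertions,
  # e.g. junction residues of an imprecise loss, say nothing about flank
  # credibility and are passed over)
  comparable <- colSums(cm != "-") >= 2L
  side_cols <- function(idx) {
    idx <- idx[idx >= 1L & idx <= L]
    idx <- idx[!has_x[idx] & comparable[idx]]
    head(idx, window)
  }
  left <- side_cols(rev(seq_len(col_start - 1L)))
  right <- side_cols(seq(col_end + 1L, length.out = L))
  side_identity <- function(cols) {
    comp <- 0; match <- 0
    for (cc in cols) {
      vals <- cm[, cc]
      ng <- vals[vals != "-"]
      comp <- comp + choose(length(ng), 2L)
      tab <- table(ng[ng %in% c("A", "C", "G", "T")])
      match <- match + sum(choose(tab, 2L))
    }
    if (comp > 0) match / comp else NA_real_
  }
  li <- side_identity(left)
  ri <- side_identity(right)
  keep <- length(left) >= 5L && length(right) >= 5L &&
    !is.na(li) && !is.na(ri) &&
    li >= min_mean_identity && ri >= min_mean_identity
  list(keep = keep, left_identity = li, right_identity = ri,
       left_usable = length(left), right_usable = length(right))
}
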