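# Marked progressive multiple alignment: coding sequences carry 30-X
# artificial introns at every intron position, so that homologous intron
# positions stack into shared columns of the group alignment.

MARKER_LEN <- 30L

#' Insert artificial intron markers into a coding sequence
#'
#' Places a block of 30 X characters at every intron position of the gene
#' (immediately before the CDS position `cds_offset`).  Removing the X
#' characters restores the CDS exactly.
#'
#' @param gene a [gene_model()]
#' @return marked string over A,C,G,T,N,X
#' @export
insert_markers <- function(gene) {
  cds <- gene$cds_seq
  offs <- gene$introns$cds_offset
  if (!length(offs)) return(cds)
  block <- strrep("X", MARKER_LEN)
  pieces <- character(0)
  prev <- 0L
  for (o in offs) {
    pieces <- c(pieces, substr(cds, prev + 1L, o), block)
    prev <- o
  }
  paste(c(pieces, substring(cds, prev + 1L)), collapse = "")
}

# substitution matrix over the marked alphabet A,C,G,T,N,X,-
# (transitions are penalised less than transversions; X stacks with X,
# repels nucleotides and is indifferent to gaps).  The X/X reward fixes the
# coalescence radius: two marker blocks closer than ~x_match*30/match nt
# can be stacked by the aligner even when non-homologous, so x_match is
# kept at the substitution match score (radius ~30 nt, below the distance
# at which distinct intron positions are simulated or biologically
# expected to sit).
marked_subst_matrix <- function(match = 5, transition = -3, transversion = -4,
                                x_match = 5, x_mismatch = -20) {
  A <- length(MARK_ALPHABET)
  S <- matrix(transversion, A, A, dimnames = list(MARK_ALPHABET, MARK_ALPHABET))
  diag(S) <- match
  S["A", "G"] <- S["G", "A"] <- transition
  S["C", "T"] <- S["T", "C"] <- transition
  S["N", ] <- S[, "N"] <- transversion
  S["N", "N"] <- transversion
  S["X", ] <- S[, "X"] <- x_mismatch
  S["X", "X"] <- x_match
  S["X", "-"] <- S["-", "X"] <- 0
  S["-", ] <- S[, "-"] <- 0
  S
}

row_to_idx <- function(row) {
  match(chars(row), MARK_ALPHABET)
}

profile_of <- function(rows) {
  L <- nchar(rows[[1]])
  A <- length(MARK_ALPHABET)
  P <- matrix(0, A, L)
  for (r in rows) {
    idx <- row_to_idx(r)
    P[cbind(idx, seq_len(L))] <- P[cbind(idx, seq_len(L))] + 1
  }
  P / length(rows)
}

near_gap_flags <- function(P, within = 10L) {
  gapped <- P[length(MARK_ALPHABET), ] > 0
  if (!any(gapped)) return(rep(FALSE, ncol(P)))
  idx <- which(gapped)
  flags <- rep(FALSE, ncol(P))
  for (i in idx) {
    lo <- max(1L, i - within); hi <- min(ncol(P), i + within)
    flags[lo:hi] <- TRUE
  }
  flags
}

apply_path <- function(rows, path) {
  vapply(rows, function(r) {
    v <- chars(r)
    out <- character(length(path))
    out[path == 0L] <- "-"
    out[path != 0L] <- v[path[path != 0L]]
    paste(out, collapse = "")
  }, character(1))
}

# UPGMA guide order from 6-mer frequency distance on unmarked sequences
guide_merge_order <- function(marked) {
  seqs <- gsub("X", "", marked, fixed = TRUE)
  km <- lapply(seqs, kmer_set, k = 6L)
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      shared <- length(intersect(km[[i]], km[[j]]))
      D[i, j] <- D[j, i] <- 1 - shared / max(1L, min(lengths(km)[c(i, j)]))
    }
  }
  dimnames(D) <- list(names(marked), names(marked))
  hc <- hclust(as.dist(D), method = "average")
  hc$merge
}

#' Progressive global alignment of marked coding sequences
#'
#' Aligns the marked strings of an ortholog group with a profile-profile
#' progressive strategy: UPGMA guide tree on k-mer distances, affine gaps
#' with a high opening and zero extension cost, a surcharge for opening a
#' gap within 10 columns of an existing one, transitions penalised less
#' than transversions, and marker-aware scores (X/X +10, X/nucleotide -20,
#' X/gap 0) so that homologous marker blocks stack into shared columns.
#'
#' The gap-opening cost is expressed on this package's +5/-4 substitution
#' scale: it must exceed the cost of a few substitutions (so near-identical
#' sequences are not fragmented) but stay below the cost of absorbing the
#' smallest real insertion (about 12 nt, the shortest NHEJ junction
#' remnant) as mismatches, otherwise small insertions adjacent to marker
#' gaps are soaked up as mismatch columns and corrupt the flanks.
#'
#' @param marked named character vector (species -> marked string), length
#'   >= 2
#' @param gap_open,gap_extend,gap_sep gap costs
#' @return a `marked_alignment`: aligned rows plus per-row marker blocks
#' @export
align_group <- function(marked, gap_open = 40, gap_extend = 0, gap_sep = 10) {
  stopifnot(length(marked) >= 2L, !is.null(names(marked)))
  S <- marked_subst_matrix()
  merge <- guide_merge_order(marked)
  clusters <- list()
  singles <- lapply(seq_along(marked), function(i) marked[i])
  for (m in seq_len(nrow(merge))) {
    pick <- function(v) if (v < 0) singles[[-v]] else clusters[[v]]
    r1 <- pick(merge[m, 1]); r2 <- pick(merge[m, 2])
    P1 <- profile_of(r1); P2 <- profile_of(r2)
    path <- profile_align_cpp(P1, P2, S,
                              near_gap_flags(P1), near_gap_flags(P2),
                              gap_open = gap_open, gap_extend = gap_extend,
                              gap_sep = gap_sep)
    clusters[[m]] <- c(apply_path(r1, path$path1), apply_path(r2, path$path2))
  }
  rows <- clusters[[nrow(merge)]]
  rows <- rows[order(match(names(rows), names(marked)))]
  structure(list(rows = rows, marker_blocks = marker_blocks(rows)),
            class = "marked_alignment")
}

# per-row marker blocks: maximal runs of X (gaps inside a block tolerated),
# reported as (start column, intron index)
marker_blocks <- function(rows) {
  lapply(rows, function(r) {
    v <- chars(r)
    isx <- v == "X"
    if (!any(isx)) {
      return(data.frame(start_col = integer(), end_col = integer(),
                        intron_index = integer()))
    }
    xpos <- which(isx)
    # group X positions separated only by gap characters into one block
    brk <- c(TRUE, vapply(seq(2, length.out = length(xpos) - 1L), function(i) {
      if (xpos[i] - xpos[i - 1L] == 1L) return(FALSE)
      any(v[(xpos[i - 1L] + 1L):(xpos[i] - 1L)] != "-")
    }, logical(1)))
    grp <- cumsum(brk)
    starts <- tapply(xpos, grp, min)
    ends <- tapply(xpos, grp, max)
    data.frame(start_col = as.integer(starts), end_col = as.integer(ends),
               intron_index = seq_along(starts) - 1L)
  })
}

#' @export
print.marked_alignment <- function(x, ...) {
  cat(sprintf("<marked_alignment> %d rows x %d columns, %d marker blocks\n",
              length(x$rows), nchar(x$rows[[1]]),
              sum(vapply(x$marker_blocks, nrow, integer(1)))))
  invisible(x)
}

#' Map marker blocks to homologous intron-position columns
#'
#' Marker blocks whose start columns lie within `max_offset_cols` of each
#' other merge into one column class (clustered by ascending start column;
#' a gap larger than the window starts a new class).  Each block belongs to
#' exactly one class.
#'
#' @param aln a `marked_alignment`
#' @param max_offset_cols merge window in alignment columns
#' @return an `intron_column_map` data.frame: `column` (class index),
#'   `col_start` (class representative start), `species`, `intron_index`,
#'   `block_start`, `block_end`
#' @export
map_intron_columns <- function(aln, max_offset_cols = 10L) {
  mb <- aln$marker_blocks
  rows <- list()
  for (sp in names(mb)) {
    if (nrow(mb[[sp]]) == 0L) next
    rows[[sp]] <- data.frame(species = sp, mb[[sp]], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(structure(data.frame(column = integer(), col_start = integer(),
                                species = character(), intron_index = integer(),
                                block_start = integer(), block_end = integer(),
                                stringsAsFactors = FALSE),
                     class = c("intron_column_map", "data.frame")))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start_col, df$species), , drop = FALSE]
  cls <- cumsum(c(TRUE, diff(df$start_col) > max_offset_cols))
  out <- data.frame(column = cls,
                    col_start = as.integer(tapply(df$start_col, cls, min)[as.character(cls)]),
                    species = df$species,
                    intron_index = df$intron_index,
                    block_start = df$start_col,
                    block_end = df$end_col,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("intron_column_map", "data.frame"))
}
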