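# Dollo parsimony on intron presence/absence columns: a derived state
# (intron presence) arises exactly once and may be lost repeatedly.
# Missing data (species absent from the ortholog group) constrains nothing.

# postorder node status: "P" if any present leaf below, "A" if no present
# leaf but at least one absent leaf, "M" if all leaves below are missing
node_status <- function(tree, states) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  s <- states[tree$tip.label]
  hasP <- hasA <- logical(N)
  hasP[seq_len(n)] <- !is.na(s) & s == 1L
  hasA[seq_len(n)] <- !is.na(s) & s == 0L
  eo <- reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1]; ch <- eo[k, 2]
    hasP[p] <- hasP[p] || hasP[ch]
    hasA[p] <- hasA[p] || hasA[ch]
  }
  ifelse(hasP, "P", ifelse(hasA, "A", "M"))
}

# minimal losses below `from` given presence at `from`: edges into maximal
# all-absent subtrees
min_loss_nodes <- function(tree, status, from) {
  n <- length(tree$tip.label)
  out <- integer(0)
  stack <- tree_children(tree, from)
  if (from <= n) return(out)
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (status[v] == "A") {
      out <- c(out, v)
    } else if (status[v] == "P" && v > n) {
      stack <- c(stack, tree_children(tree, v))
    }
  }
  sort(out)
}

# single-column Dollo reconstruction given the root state.
# Returns gain_node (MRCA of present leaves; NA when the intron is
# ancestral, i.e. root_state = 1) and the minimal loss edge set (child
# node ids).  With no present leaf the column yields no events.
dollo_reconstruct <- function(tree, states, root_state) {
  present <- names(states)[!is.na(states) & states == 1L]
  if (!length(present))
    return(list(gain_node = NA_integer_, loss_nodes = integer(0),
                ancestral = FALSE, empty = TRUE))
  status <- node_status(tree, states)
  if (root_state == 1L) {
    top <- root_id(tree)
    gain <- NA_integer_
  } else {
    top <- mrca_of(tree, present)
    gain <- as.integer(top)
  }
  list(gain_node = gain, loss_nodes = min_loss_nodes(tree, status, top),
       ancestral = root_state == 1L, empty = FALSE)
}

#' Does a presence/absence column need the outgroup to be polarized?
#'
#' Under single-gain (Dollo) logic a column is decidable from ingroup
#' states alone when the two candidate reconstructions - a gain inside the
#' ingroup at the MRCA of present species (cost 1 gain + minimal losses)
#' versus presence at the ingroup root (cost: minimal losses only) - differ
#' in total event cost.  When the costs tie, the root state is ambiguous
#' and an outgroup state is required.
#'
#' @param states named vector over ingroup species: 1 present, 0 absent,
#'   NA missing (at least two non-missing entries)
#' @param ingroup_tree rooted `phylo` of the ingroup
#' @return `"internal"` or `"needs_outgroup"`
#' @export
partition_outgroup_need <- function(states, ingroup_tree) {
  nm <- states[!is.na(states)]
  if (length(nm) < 2L) stop("need at least two non-missing states")
  present <- names(states)[!is.na(states) & states == 1L]
  if (!length(present)) stop("column with no present species")
  status <- node_status(ingroup_tree, states)
  cost_gain <- 1L + length(min_loss_nodes(ingroup_tree, status,
                                          mrca_of(ingroup_tree, present)))
  cost_root <- length(min_loss_nodes(ingroup_tree, status,
                                     root_id(ingroup_tree)))
  if (cost_gain == cost_root) "needs_outgroup" else "internal"
}

#' Call intron gain and loss events by Dollo parsimony
#'
#' For every matrix row the intron gains exactly once, at the most recent
#' common ancestor of the present species, or is ancestral when the root
#' state is presence; losses are the minimal edge set explaining all
#' absences below.  A non-missing outgroup state fixes the root state.
#' With a missing outgroup state, rows whose root state is unambiguous
#' from ingroup states alone ("internal" rows) use the cheaper
#' reconstruction; ambiguous rows are excluded, mirroring outgroup-less
#' alignments being dropped from the source analysis.
#'
#' @param mat integer matrix, rows = intron columns, columns = ingroup
#'   species; 1 present, 0 absent, NA missing
#' @param tree rooted ingroup `phylo`
#' @param outgroup_states integer vector along rows: 1/0/NA
#' @return data.frame of event calls: `column` (rownames of `mat`), `type`
#'   (gain/loss), `branch` (child-node label), `single_species`,
#'   `n_leaves`, `status`, `qc_flags`; excluded rows are reported in the
#'   `excluded` attribute
#' @export
dollo_events <- function(mat, tree, outgroup_states = NULL) {
  if (is.null(outgroup_states)) outgroup_states <- rep(NA_integer_, nrow(mat))
  stopifnot(length(outgroup_states) == nrow(mat))
  n <- length(tree$tip.label)
  calls <- list(); nc <- 0L
  excluded <- character(0)
  for (r in seq_len(nrow(mat))) {
    states <- setNames(as.integer(mat[r, tree$tip.label]), tree$tip.label)
    present <- names(states)[!is.na(states) & states == 1L]
    if (!length(present)) next          # column never existed in this group
    og <- outgroup_states[[r]]
    if (!is.na(og)) {
      root_state <- as.integer(og)
    } else {
      if (sum(!is.na(states)) < 2L ||
          partition_outgroup_need(states, tree) == "needs_outgroup") {
        excluded <- c(excluded, rownames(mat)[r] %||% as.character(r))
        next
      }
      status <- node_status(tree, states)
      cost_gain <- 1L + length(min_loss_nodes(tree, status,
                                              mrca_of(tree, present)))
      cost_root <- length(min_loss_nodes(tree, status, root_id(tree)))
      root_state <- if (cost_root < cost_gain) 1L else 0L
    }
    rec <- dollo_reconstruct(tree, states, root_state)
    rn <- rownames(mat)[r] %||% as.character(r)
    add <- function(type, node) {
      nc <<- nc + 1L
      leaves <- tips_below(tree, node)
      calls[[nc]] <<- data.frame(
        column = rn, type = type, branch = node_label(tree, node),
        single_species = node <= n, n_leaves = length(leaves),
        leaves = paste(sort(tree$tip.label[leaves]), collapse = ";"),
        status = "accepted", qc_flags = "", stringsAsFactors = FALSE)
    }
    if (!is.na(rec$gain_node)) add("gain", rec$gain_node)
    for (v in rec$loss_nodes) add("loss", v)
  }
  out <- if (nc) do.call(rbind, calls) else
    data.frame(column = character(), type = character(), branch = character(),
               single_species = logical(), n_leaves = integer(),
               leaves = character(), status = character(),
               qc_flags = character(), stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Annotation-error quality controls for single-species intron gains
#'
#' A gain confined to one species is rejected when the gained intron (a)
#' has length divisible by 3 and contains no premature termination codon in
#' the reading frame set by its position - the signature of an
#' annotation error rather than a real intron - or (b) has noncanonical
#' splice-site dinucleotides.  Ancestral gains and all losses are exempt.
#'
#' @param call one-row event-call data.frame (a single-species gain)
#' @param intron the corresponding intron row from a [gene_model()]
#' @param gene the gene model carrying the intron
#' @param canonical list of allowed (donor, acceptor) dinucleotide pairs
#' @return the call with `qc_flags`/`status` updated
#' @export
qc_gain_filters <- function(call, intron, gene,
                            canonical = list(c("GT", "AG"))) {
  stopifnot(nrow(call) == 1L, call$type == "gain", isTRUE(call$single_species))
  flags <- character(0)
  if (intron$length_nt %% 3L == 0L && !has_ptc(intron$seq, intron$cds_offset))
    flags <- c(flags, "len3n_noPTC")
  ok_splice <- any(vapply(canonical, function(p)
    intron$donor2 == p[1] && intron$acceptor2 == p[2], logical(1)))
  if (!ok_splice) flags <- c(flags, "noncanonical_splice")
  call$qc_flags <- paste(flags, collapse = ";")
  if (length(flags)) call$status <- "rejected"
  call
}

#' Per-branch summary of accepted events
#'
#' @param calls event-call data.frame (accepted calls are summarised)
#' @param tree ingroup `phylo`
#' @return list with `per_branch` (gains/losses per edge, named by child
#'   node), `per_species` (single-species events), and `totals`
#' @export
summarize_events <- function(calls, tree) {
  acc <- calls[calls$status == "accepted", , drop = FALSE]
  branch_names <- node_label(tree, tree$edge[, 2])
  per_branch <- data.frame(branch = branch_names,
                           gains = 0L, losses = 0L, stringsAsFactors = FALSE)
  # events called at the ingroup root (ancestral presence has no branch row)
  root_lab <- node_label(tree, root_id(tree))
  if (!root_lab %in% per_branch$branch)
    per_branch <- rbind(per_branch,
                        data.frame(branch = root_lab, gains = 0L, losses = 0L,
                                   stringsAsFactors = FALSE))
  for (i in seq_len(nrow(acc))) {
    j <- match(acc$branch[i], per_branch$branch)
    if (acc$type[i] == "gain") per_branch$gains[j] <- per_branch$gains[j] + 1L
    else per_branch$losses[j] <- per_branch$losses[j] + 1L
  }
  sp <- per_branch[per_branch$branch %in% tree$tip.label, , drop = FALSE]
  names(sp) <- c("species", "gained_introns", "lost_introns")
  totals <- data.frame(
    type = c("gain", "loss"),
    single_species = c(sum(acc$type == "gain" & acc$single_species),
                       sum(acc$type == "loss" & acc$single_species)),
    ancestral = c(sum(acc$type == "gain" & !acc$single_species),
                  sum(acc$type == "loss" & !acc$single_species)))
  totals$total <- totals$single_species + totals$ancestral
  list(per_branch = per_branch, per_species = sp, totals = totals)
}
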