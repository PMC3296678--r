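# Forward simulator: a gene family evolves over a rooted species tree with
# mechanism-labelled intron gains and losses.  Every event is validated to
# keep the column's final leaf pattern Dollo-consistent with the recorded
# truth (single gain, minimal losses), so that exact recovery is a
# well-posed target for the inference side.

insert_str <- function(s, pos0, ins) {
  paste0(substr(s, 1L, pos0), ins, substring(s, pos0 + 1L))
}

draw_intron_len <- function(cfg) {
  cfg$intron_len_min + rgeom(1L, 1 / (cfg$intron_len_mean - cfg$intron_len_min + 1))
}

force_ends <- function(seq) {
  n <- nchar(seq)
  paste0("GT", substr(seq, 3L, n - 2L), "AG")
}

# ---- per-mechanism gain sequence generators ------------------------------

# pad with one random nt before the terminal AG until the intron would
# survive the annotation-error filter (non-3n length or an in-frame stop)
qc_safe_pad <- function(seq, cds_offset, at = 0.5) {
  while (nchar(seq) %% 3L == 0L && !has_ptc(seq, cds_offset)) {
    n <- nchar(seq)
    seq <- paste0(substr(seq, 1L, n - 2L), rand_dna(1L, at), "AG")
  }
  seq
}

gen_gain_plain <- function(cfg, cds_offset) {
  if (runif(1) < cfg$gain_3n_ptc_frac) {
    len <- 3L * round(draw_intron_len(cfg) / 3)
    seq <- force_ends(rand_dna(len, cfg$intron_at))
    if (!has_ptc(seq, cds_offset)) {
      # plant an in-frame stop mid-intron
      i0 <- intron_frame(cds_offset)
      starts <- seq.int(i0 + 1L, len - 2L, by = 3L)
      starts <- starts[starts > 2L & starts + 2L < len - 1L]
      s <- sample(starts, 1L)
      seq <- paste0(substr(seq, 1L, s - 1L), "TAA", substring(seq, s + 3L))
    }
  } else {
    len <- draw_intron_len(cfg)
    if (len %% 3L == 0L) len <- len + 1L
    seq <- force_ends(rand_dna(len, cfg$intron_at))
  }
  list(seq = seq, mechanism = "plain", tsd = NA_character_,
       repeat_seq = NA_character_)
}

gen_gain_transposon <- function(cfg, cds, cds_offset, transposons) {
  # target site = the first tsd_len nt of the downstream exon; the site was
  # chosen to start with GT so the duplicated copy doubles as the donor site
  t_site <- substr(cds, cds_offset + 1L, cds_offset + cfg$tsd_len)
  elem <- transposons[[sample(length(transposons), 1L)]]
  if (runif(1) < 0.5) elem <- revcomp(elem)
  seq <- paste0(t_site, substr(elem, 1L, nchar(elem) - 2L), "AG")
  seq <- qc_safe_pad(seq, cds_offset, cfg$intron_at)
  list(seq = seq, mechanism = "transposon_tsd", tsd = t_site,
       repeat_seq = NA_character_)
}

gen_gain_mito <- function(cfg, cds, cds_offset, mito) {
  len <- max(60L, round(rnorm(1L, cfg$mito_slice_mean, cfg$mito_slice_sd)))
  text <- if (runif(1) < 0.5) mito else revcomp(mito)
  rep_seq <- NA_character_
  start <- NA_integer_
  if (runif(1) < cfg$repeat_prob) {
    # microhomology-selected junction: pick a filler slice whose 5' end
    # duplicates the upstream exon terminus
    for (rl in seq(max(cfg$repeat_len), min(cfg$repeat_len))) {
      r <- substr(cds, cds_offset - rl + 1L, cds_offset)
      hits <- gregexpr(r, text, fixed = TRUE)[[1]]
      hits <- hits[hits > 0 & hits + len - 1L <= nchar(text)]
      if (length(hits)) {
        start <- hits[[sample.int(length(hits), 1L)]]
        rep_seq <- r
        break
      }
    }
  }
  if (is.na(start)) start <- sample.int(nchar(text) - len + 1L, 1L)
  slice <- substr(text, start, start + len - 1L)
  seq <- paste0("GT", slice, "AG")
  seq <- qc_safe_pad(seq, cds_offset, cfg$mito_at)
  list(seq = seq, mechanism = "mito_filler", tsd = NA_character_,
       repeat_seq = rep_seq)
}

# annotation-error pseudo-intron: length 3n, canonical ends, and stop-free
# in the reading frame set by its position (what the quality filter rejects)
gen_annot_error <- function(cfg, cds_offset) {
  n_cod <- sample(20:40, 1L)
  len <- 3L * n_cod
  i0 <- intron_frame(cds_offset)
  v <- chars(rand_dna(len, cfg$intron_at))
  starts <- seq.int(i0 + 1L, len - 2L, by = 3L)
  for (s in starts) v[s:(s + 2L)] <- chars(sample(SENSE_CODONS, 1L))
  v[1:2] <- c("G", "T")
  v[(len - 1L):len] <- c("A", "G")
  # re-fix codons corrupted by the forced ends
  for (s in starts[starts <= 3L | starts + 2L >= len - 1L]) {
    cod <- paste(v[s:(s + 2L)], collapse = "")
    if (cod %in% STOP_CODONS) {
      fixed <- which(s:(s + 2L) %in% c(1L, 2L, len - 1L, len))
      cand <- SENSE_CODONS
      for (f in fixed) cand <- cand[substr(cand, f, f) == v[s + f - 1L]]
      v[s:(s + 2L)] <- chars(sample(cand, 1L))
    }
  }
  seq <- paste(v, collapse = "")
  stopifnot(nchar(seq) %% 3L == 0L, !has_ptc(seq, cds_offset))
  seq
}

# ---- root gene -----------------------------------------------------------

sim_root_gene <- function(cfg) {
  n_cod <- sample(seq(cfg$cds_codons[1], cfg$cds_codons[2]), 1L)
  cds <- paste0("ATG",
                paste(sample(SENSE_CODONS, n_cod - 2L, replace = TRUE),
                      collapse = ""),
                sample(STOP_CODONS, 1L))
  L <- nchar(cds)
  sp <- cfg$min_intron_spacing
  n_int <- rpois(1L, cfg$root_introns_mean)
  max_feasible <- max(0L, (L - 2L * sp) %/% sp + 1L)
  n_int <- min(n_int, max_feasible)
  offs <- integer(0)
  if (n_int > 0L) {
    # spacing-constrained uniform placement: lay down minimal gaps, then
    # distribute the slack
    slack <- L - 2L * sp - (n_int - 1L) * sp
    if (slack < 0L)
      stop("could not place ", n_int, " introns with spacing ", sp,
           " in a ", L, " nt CDS")
    u <- sort(sample.int(slack + 1L, n_int, replace = TRUE) - 1L)
    offs <- sp + (seq_len(n_int) - 1L) * sp + u
  }
  seqs <- vapply(offs, function(o) {
    force_ends(rand_dna(draw_intron_len(cfg), cfg$intron_at))
  }, character(1))
  list(cds = cds,
       introns = data.frame(column = sprintf("c%02d", seq_along(offs)),
                            cds_offset = offs, seq = seqs,
                            stringsAsFactors = FALSE)[seq_along(offs), ,
                                                      drop = FALSE])
}

#' Simulate the ancestral (root) gene of a family
#'
#' The CDS is a single open reading frame (ATG start, one terminal stop, no
#' internal stop) carrying a Poisson number of ancestral introns with
#' canonical GT..AG ends at mutually well-separated positions.
#'
#' @param config a [sim_config()]
#' @return a [gene_model()] for the root gene
#' @export
simulate_root_gene <- function(config) {
  set.seed(config$seed)
  parts <- sim_root_gene(config)
  gene_model_from_parts("root_gene", "root", "root_scaf", parts$cds,
                        make_intron_df(parts$introns$cds_offset,
                                       parts$introns$seq))
}

# ---- consistency validation ---------------------------------------------

# would the event set of this column still be recovered exactly by Dollo
# parsimony from the final leaf pattern?  `col` is a list(root, gain,
# losses) with branch child labels; events are interpreted on the ingroup
# tree.
column_consistent <- function(ingroup, col) {
  n <- length(ingroup$tip.label)
  present <- if (col$root) rep(TRUE, n) else {
    p <- rep(FALSE, n)
    p[tips_below(ingroup, node_id(ingroup, col$gain))] <- TRUE
    p
  }
  for (l in col$losses) present[tips_below(ingroup, node_id(ingroup, l))] <- FALSE
  states <- setNames(as.integer(present), ingroup$tip.label)
  rec <- dollo_reconstruct(ingroup, states, root_state = as.integer(col$root))
  truth_gain <- if (col$root) NA_integer_ else node_id(ingroup, col$gain)
  truth_losses <- sort(vapply(col$losses, node_id, integer(1),
                              tree = ingroup, USE.NAMES = FALSE))
  identical(rec$gain_node, truth_gain) &&
    identical(sort(rec$loss_nodes), truth_losses) &&
    (col$root || length(rec$loss_nodes) > 0L || length(col$losses) == 0L)
}

# ---- substitutions -------------------------------------------------------

mutate_seq <- function(seq, p, protect = integer(0)) {
  n <- nchar(seq)
  if (n == 0L || p <= 0) return(seq)
  hit <- which(runif(n) < p)
  hit <- setdiff(hit, protect)
  if (!length(hit)) return(seq)
  v <- chars(seq)
  bases <- c("A", "C", "G", "T")
  v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1L),
                   character(1))
  paste(v, collapse = "")
}

# ---- the family walk -----------------------------------------------------

#' Evolve gene families over a species tree with mechanism-labelled events
#'
#' Forward-simulates `n_genes` families from the root of the configured
#' tree.  Per ingroup branch, gain/loss/slide counts are Poisson in the
#' branch length; each event carries a mechanism drawn from the configured
#' mix, with at most one event per intron position per branch, and is
#' retained only if the column's leaf pattern stays Dollo-consistent with
#' the truth log.  Substitutions are applied after events and never touch
#' donor/acceptor dinucleotides.  The outgroup lineage accumulates
#' substitutions but no structural events: it serves as the polarization
#' reference.
#'
#' @param config a [sim_config()]
#' @return an `intron_sim` object: leaf gene states, the truth log,
#'   per-leaf intron-to-column map, germline expression flags, transposon
#'   and organelle libraries, and the tree
#' @export
evolve_family <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  tree <- cfg$tree %||% default_sim_tree(cfg)
  outg <- attr(tree, "outgroup") %||% cfg$outgroup
  if (!outg %in% tree$tip.label)
    stop("outgroup leaf ", outg, " missing from tree")
  ingroup <- ape::drop.tip(tree, outg)
  attr(ingroup, "outgroup") <- NULL
  ing_tips <- ingroup$tip.label

  transposons <- setNames(
    lapply(seq_len(cfg$n_transposons), function(i)
      rand_dna(sample(seq(cfg$transposon_len[1], cfg$transposon_len[2]), 1L),
               at = 0.55)),
    sprintf("TE%02d", seq_len(cfg$n_transposons)))
  mito <- rand_dna(cfg$mito_len, at = cfg$mito_at)

  # ids of edges on which structural events may occur: strictly inside the
  # ingroup subtree of the full tree
  full_root <- root_id(tree)
  root_kids <- tree_children(tree, full_root)
  out_id <- node_id(tree, outg)
  ing_root <- setdiff(root_kids, out_id)
  if (length(ing_root) != 1L)
    stop("tree root must split the outgroup from the ingroup")
  event_edges <- edges_below(tree, ing_root)
  # drop the edge leading into the ingroup root itself
  event_edges <- event_edges[tree$edge[event_edges, 1] != full_root]

  truth <- list(); truth_n <- 0L
  cols_reg <- list()
  leaf_states <- list()
  for (sp in tree$tip.label) leaf_states[[sp]] <- list()

  gene_ids <- sprintf("g%03d", seq_len(cfg$n_genes))
  for (g in gene_ids) {
    root <- sim_root_gene(cfg)
    if (nrow(root$introns))
      root$introns$column <- paste0(g, "_", root$introns$column)
    col_info <- list()
    for (cc in root$introns$column)
      col_info[[cc]] <- list(root = TRUE, gain = NA_character_,
                             losses = character(0))
    gain_counter <- nrow(root$introns)

    # family-wide register of column positions, kept in the root
    # coordinate frame: new gains keep their distance from every position
    # ever used in any lineage, so two independent gains can never collide
    # into (or be snapped by the aligner into) one column class.  Each
    # lineage state carries its insertion history (`shifts`) so current
    # coordinates can be mapped to the root frame and back.
    family_offsets <- root$introns$cds_offset

    to_root <- function(o, shifts) {
      cumk <- 0L
      for (r in seq_len(nrow(shifts))) {
        cur <- shifts$root_pos[r] + cumk
        if (o > cur) cumk <- cumk + shifts$k[r] else break
      }
      o - cumk
    }
    to_cur <- function(o_root, shifts) {
      cumk <- 0L
      for (r in seq_len(nrow(shifts))) {
        if (shifts$root_pos[r] < o_root) cumk <- cumk + shifts$k[r]
        else break
      }
      o_root + cumk
    }

    add_truth <- function(column, branch, type, mechanism, seq,
                          repeat_seq = NA_character_, tsd = NA_character_,
                          detail = NA_character_) {
      truth_n <<- truth_n + 1L
      truth[[truth_n]] <<- data.frame(
        gene = g, column = column, branch = branch, type = type,
        mechanism = mechanism, seq = seq, repeat_seq = repeat_seq,
        tsd = tsd, detail = detail, stringsAsFactors = FALSE)
    }

    apply_edge_events <- function(state, edge_idx) {
      clab <- node_label(tree, tree$edge[edge_idx, 2])
      len <- tree$edge.length[edge_idx]
      ev <- c(rep("gain", rpois(1L, cfg$gain_rate * len)),
              rep("loss", rpois(1L, cfg$loss_rate * len)),
              rep("slide", rpois(1L, cfg$slide_rate * len)))
      if (length(ev) > 1L) ev <- sample(ev)
      used <- character(0)
      for (e in ev) {
        if (e == "gain") {
          res <- try_gain(state, clab)
        } else if (e == "loss") {
          res <- try_loss(state, clab, used)
        } else {
          res <- try_slide(state, clab, used)
        }
        if (!is.null(res)) {
          state <- res$state
          used <- c(used, res$used)
        }
      }
      state
    }

    allowed_offsets <- function(state, need_gt = FALSE, exclude = integer(0)) {
      L <- nchar(state$cds)
      sp <- cfg$min_intron_spacing
      pos <- seq(sp, L - sp)
      fam_cur <- vapply(family_offsets, to_cur, numeric(1),
                        shifts = state$shifts)
      offs <- setdiff(union(state$introns$cds_offset, fam_cur), exclude)
      for (o in offs) pos <- pos[abs(pos - o) >= sp]
      if (need_gt && length(pos))
        pos <- pos[substring(state$cds, pos + 1L, pos + 2L) == "GT"]
      pos
    }

    try_gain <- function(state, clab) {
      mech <- sample(names(cfg$gain_mix), 1L, prob = cfg$gain_mix)
      pos <- allowed_offsets(state, need_gt = mech == "transposon_tsd")
      if (!length(pos)) return(NULL)
      o <- if (length(pos) == 1L) pos else sample(pos, 1L)
      gain_counter <<- gain_counter + 1L
      cc <- sprintf("%s_c%02d", g, gain_counter)
      cand <- list(root = FALSE, gain = clab, losses = character(0))
      if (!column_consistent(ingroup, cand)) { gain_counter <<- gain_counter - 1L; return(NULL) }
      gen <- switch(mech,
                    plain = gen_gain_plain(cfg, o),
                    transposon_tsd = gen_gain_transposon(cfg, state$cds, o, transposons),
                    mito_filler = gen_gain_mito(cfg, state$cds, o, mito))
      col_info[[cc]] <<- cand
      add_truth(cc, clab, "gain", gen$mechanism, gen$seq,
                repeat_seq = gen$repeat_seq, tsd = gen$tsd)
      ins <- data.frame(column = cc, cds_offset = o, seq = gen$seq,
                        stringsAsFactors = FALSE)
      state$introns <- rbind(state$introns, ins)
      state$introns <- state$introns[order(state$introns$cds_offset), ,
                                     drop = FALSE]
      family_offsets <<- c(family_offsets, to_root(o, state$shifts))
      list(state = state, used = cc)
    }

    try_loss <- function(state, clab, used) {
      cand_cols <- setdiff(state$introns$column, used)
      if (!length(cand_cols)) return(NULL)
      cc <- if (length(cand_cols) == 1L) cand_cols else sample(cand_cols, 1L)
      info <- col_info[[cc]]
      info$losses <- c(info$losses, clab)
      if (!column_consistent(ingroup, info)) return(NULL)
      i <- match(cc, state$introns$column)
      iseq <- state$introns$seq[i]
      o <- state$introns$cds_offset[i]
      mech <- sample(names(cfg$loss_mix), 1L, prob = cfg$loss_mix)
      residues <- NULL
      if (mech == "nhej_imprecise") {
        combos <- expand.grid(k = cfg$nhej_k, side = c("5", "3"),
                              stringsAsFactors = FALSE)
        combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
        for (j in seq_len(nrow(combos))) {
          k <- combos$k[j]
          if (k >= nchar(iseq)) next
          r <- if (combos$side[j] == "5") substr(iseq, 1L, k)
               else substring(iseq, nchar(iseq) - k + 1L)
          new_cds <- insert_str(state$cds, o, r)
          if (is_orf(new_cds)) { residues <- r; break }
        }
        if (is.null(residues)) mech <- "precise"
      }
      col_info[[cc]] <<- info
      state$introns <- state$introns[-i, , drop = FALSE]
      if (!is.null(residues)) {
        state$cds <- insert_str(state$cds, o, residues)
        k <- nchar(residues)
        state$shifts <- rbind(state$shifts,
                              data.frame(root_pos = to_root(o, state$shifts),
                                         k = k))
        state$shifts <- state$shifts[order(state$shifts$root_pos), ,
                                     drop = FALSE]
        shift <- state$introns$cds_offset > o
        state$introns$cds_offset[shift] <- state$introns$cds_offset[shift] + k
        add_truth(cc, clab, "loss", "nhej_imprecise", iseq, detail = residues)
      } else {
        add_truth(cc, clab, "loss", "precise", iseq)
      }
      list(state = state, used = cc)
    }

    try_slide <- function(state, clab, used) {
      cand_cols <- setdiff(state$introns$column, used)
      if (!length(cand_cols)) return(NULL)
      cc <- if (length(cand_cols) == 1L) cand_cols else sample(cand_cols, 1L)
      i <- match(cc, state$introns$column)
      o <- state$introns$cds_offset[i]
      d <- sample(40:55, 1L) * sample(c(-1L, 1L), 1L)
      newo <- o + d
      ok <- allowed_offsets(state, exclude = o)
      if (!newo %in% ok) return(NULL)
      old <- col_info[[cc]]
      old$losses <- c(old$losses, clab)
      gain_counter <<- gain_counter + 1L
      cc2 <- sprintf("%s_c%02d", g, gain_counter)
      new <- list(root = FALSE, gain = clab, losses = character(0))
      if (!column_consistent(ingroup, old) || !column_consistent(ingroup, new)) {
        gain_counter <<- gain_counter - 1L
        return(NULL)
      }
      col_info[[cc]] <<- old
      col_info[[cc2]] <<- new
      family_offsets <<- c(family_offsets, to_root(newo, state$shifts))
      state$introns$column[i] <- cc2
      state$introns$cds_offset[i] <- newo
      state$introns <- state$introns[order(state$introns$cds_offset), ,
                                     drop = FALSE]
      add_truth(cc, clab, "slide", "sliding", state$introns$seq[match(cc2, state$introns$column)],
                detail = sprintf("%+d", d))
      list(state = state, used = c(cc, cc2))
    }

    walk <- function(node, state) {
      kids_idx <- which(tree$edge[, 1] == node)
      for (ei in kids_idx) {
        child <- tree$edge[ei, 2]
        st <- state
        if (ei %in% event_edges) st <- apply_edge_events(st, ei)
        # neutral substitutions, sparing splice dinucleotides
        p <- cfg$subst_rate * tree$edge.length[ei]
        if (p > 0) {
          st$cds <- mutate_seq(st$cds, p)
          if (nrow(st$introns)) {
            st$introns$seq <- vapply(st$introns$seq, function(s)
              mutate_seq(s, p, protect = c(1L, 2L, nchar(s) - 1L, nchar(s))),
              character(1), USE.NAMES = FALSE)
          }
        }
        if (child <= length(tree$tip.label)) {
          sp_name <- tree$tip.label[child]
          if (sp_name != outg && runif(1) < cfg$annot_error_rate) {
            pos <- allowed_offsets(st)
            if (length(pos)) {
              o <- if (length(pos) == 1L) pos else sample(pos, 1L)
              gain_counter <<- gain_counter + 1L
              cc <- sprintf("%s_c%02d", g, gain_counter)
              col_info[[cc]] <<- list(root = FALSE, gain = sp_name,
                                      losses = character(0))
              family_offsets <<- c(family_offsets, to_root(o, st$shifts))
              seq <- gen_annot_error(cfg, o)
              add_truth(cc, sp_name, "gain", "annotation_error", seq)
              st$introns <- rbind(st$introns,
                                  data.frame(column = cc, cds_offset = o,
                                             seq = seq, stringsAsFactors = FALSE))
              st$introns <- st$introns[order(st$introns$cds_offset), ,
                                       drop = FALSE]
            }
          }
          st$strand <- sample(c("+", "-"), 1L)
          st$flank1 <- rand_dna(cfg$flank_len, 0.55)
          st$flank2 <- rand_dna(cfg$flank_len, 0.55)
          leaf_states[[sp_name]][[g]] <<- st
        } else {
          walk(child, st)
        }
      }
    }
    walk(full_root, list(cds = root$cds, introns = root$introns,
                         shifts = data.frame(root_pos = integer(),
                                             k = integer())))
  }

  truth_df <- if (truth_n) do.call(rbind, truth) else
    data.frame(gene = character(), column = character(), branch = character(),
               type = character(), mechanism = character(), seq = character(),
               repeat_seq = character(), tsd = character(),
               detail = character(), stringsAsFactors = FALSE)

  # germline flags: one per family, biased by real event occurrence
  real <- truth_df[truth_df$mechanism != "annotation_error", , drop = FALSE]
  has_event <- gene_ids %in% real$gene
  germline <- data.frame(
    gene = gene_ids,
    has_event = has_event,
    germline = rbinom(length(gene_ids), 1L,
                      ifelse(has_event, cfg$germline_prob_event,
                             cfg$germline_prob_background)),
    stringsAsFactors = FALSE)

  # per-leaf intron-index-to-column map
  maps <- list(); mi <- 0L
  for (sp in tree$tip.label) {
    for (g in names(leaf_states[[sp]])) {
      intr <- leaf_states[[sp]][[g]]$introns
      if (!nrow(intr)) next
      mi <- mi + 1L
      maps[[mi]] <- data.frame(species = sp, gene = g,
                               intron_index = seq_len(nrow(intr)) - 1L,
                               column = intr$column,
                               cds_offset = intr$cds_offset,
                               stringsAsFactors = FALSE)
    }
  }
  intron_map <- if (mi) do.call(rbind, maps) else
    data.frame(species = character(), gene = character(),
               intron_index = integer(), column = character(),
               cds_offset = integer(), stringsAsFactors = FALSE)

  structure(list(config = cfg, tree = tree, ingroup = ingroup,
                 outgroup = outg, genes = leaf_states, truth = truth_df,
                 intron_map = intron_map, germline = germline,
                 transposons = unlist(transposons), mito = mito),
            class = "intron_sim")
}

#' @export
print.intron_sim <- function(x, ...) {
  tt <- table(factor(x$truth$type, levels = c("gain", "loss", "slide")))
  cat(sprintf(paste0("<intron_sim> %d families, %d ingroup species + ",
                     "outgroup; %d gains, %d losses, %d slides (seed %d)\n"),
              x$config$n_genes, length(x$ingroup$tip.label),
              tt[["gain"]], tt[["loss"]], tt[["slide"]], x$config$seed))
  invisible(x)
}
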