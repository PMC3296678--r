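#' Configuration for the gene-family evolution simulator
#'
#' Defaults describe a Drosophila-like study setting: a clade of closely
#' related ingroup species plus one distant outgroup used only to polarize
#' ancestral states, genes of a few hundred codons with a handful of
#' ancestral introns, AT-rich intron sequence, and intron turnover split
#' between gains (transposon insertion with target-site duplication,
#' double-strand-break filler copied from an AT-rich organelle genome, and
#' plain insertions) and losses (precise deletion, and imprecise NHEJ
#' deletion that leaves frame-preserving junction residues).
#'
#' @param seed integer seed; the same seed reproduces the dataset exactly
#' @param n_taxa number of ingroup species
#' @param n_genes number of gene families
#' @param tree optional `phylo` for the full tree (ingroup + outgroup leaf);
#'   when NULL a random coalescent ingroup tree is drawn from the seed
#' @param outgroup outgroup leaf name
#' @param cds_codons range of CDS lengths in codons (start/stop included)
#' @param root_introns_mean mean number of ancestral introns per gene
#' @param intron_len_min,intron_len_mean ancestral intron length model
#'   (minimum plus geometric tail)
#' @param intron_at AT fraction of simulated intron sequence
#' @param subst_rate expected substitutions per site per unit branch length
#' @param gain_rate,loss_rate expected gain/loss events per gene per unit
#'   branch length
#' @param gain_mix,loss_mix mechanism probabilities (must each sum to 1)
#' @param slide_rate expected intron sliding events per gene per unit branch
#'   length (off by default)
#' @param annot_error_rate probability that a leaf gene acquires one fake
#'   annotation-error intron (length 3n, stop-free, canonical ends)
#' @param gain_3n_ptc_frac fraction of plain gains forced to length 3n with
#'   an in-frame stop codon, exercising the annotation-error filter's
#'   retention side
#' @param tsd_len target-site duplication length for transposon gains
#' @param mito_len,mito_at simulated organelle genome size and AT fraction
#' @param mito_slice_mean,mito_slice_sd filler slice length model
#' @param repeat_prob probability that an organelle filler junction is
#'   selected at a microhomology (direct repeat) with the upstream exon
#' @param repeat_len direct repeat length range
#' @param nhej_k candidate junction residue lengths for imprecise NHEJ loss
#'   (frame-preserving multiples of 3)
#' @param n_transposons,transposon_len transposon library size and element
#'   length range
#' @param flank_len genomic flank written around each gene
#' @param min_intron_spacing minimum distance between intron positions and
#'   from CDS ends, in nt
#' @param germline_prob_event,germline_prob_background probability that a
#'   family is flagged germline-expressed given that it did/did not
#'   experience at least one event
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       n_taxa = 8L,
                       n_genes = 50L,
                       tree = NULL,
                       outgroup = "outgroup",
                       cds_codons = c(150L, 450L),
                       root_introns_mean = 4,
                       intron_len_min = 60L,
                       intron_len_mean = 400,
                       intron_at = 0.6,
                       subst_rate = 0.01,
                       gain_rate = 0.20,
                       loss_rate = 0.30,
                       gain_mix = c(transposon_tsd = 0.25, mito_filler = 0.25,
                                    plain = 0.5),
                       loss_mix = c(precise = 0.8, nhej_imprecise = 0.2),
                       slide_rate = 0,
                       annot_error_rate = 0,
                       gain_3n_ptc_frac = 0.2,
                       tsd_len = 8L,
                       mito_len = 16000L,
                       mito_at = 0.8,
                       mito_slice_mean = 113,
                       mito_slice_sd = 20,
                       repeat_prob = 0.3,
                       repeat_len = c(5L, 7L),
                       nhej_k = c(12L, 15L, 18L, 21L, 24L),
                       n_transposons = 8L,
                       transposon_len = c(300L, 800L),
                       flank_len = 150L,
                       min_intron_spacing = 60L,
                       germline_prob_event = 0.68,
                       germline_prob_background = 0.52) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(cfg$seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_taxa >= 2L, cfg$n_genes >= 0L)
  for (nm in c("gain_mix", "loss_mix")) {
    if (abs(sum(cfg[[nm]]) - 1) > 1e-8)
      stop(nm, " probabilities must sum to 1")
    if (any(cfg[[nm]] < 0)) stop(nm, " probabilities must be nonnegative")
  }
  if (!all(names(cfg$gain_mix) %in%
           c("transposon_tsd", "mito_filler", "plain")))
    stop("unknown gain mechanism in gain_mix")
  if (!all(names(cfg$loss_mix) %in% c("precise", "nhej_imprecise")))
    stop("unknown loss mechanism in loss_mix")
  rates <- c(cfg$subst_rate, cfg$gain_rate, cfg$loss_rate, cfg$slide_rate)
  if (any(rates < 0)) stop("rates must be nonnegative")
  probs <- c(cfg$germline_prob_event, cfg$germline_prob_background,
             cfg$repeat_prob, cfg$annot_error_rate, cfg$gain_3n_ptc_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(cfg$nhej_k %% 3L != 0L))
    stop("nhej_k residue lengths must be multiples of 3")
  if (cfg$intron_len_min < 30L)
    stop("intron_len_min below 30 nt is not a plausible spliceable intron")
  if (cfg$cds_codons[1] * 3L < 6L * cfg$min_intron_spacing)
    stop("CDS too short for the configured intron spacing")
  invisible(cfg)
}

# default full tree: random coalescent ingroup scaled to unit depth, with a
# distant outgroup attached at the root
default_sim_tree <- function(cfg) {
  ing <- ape::rcoal(cfg$n_taxa, tip.label = sprintf("sp%02d", seq_len(cfg$n_taxa)))
  depth <- max(ape::node.depth.edgelength(ing))
  ing$edge.length <- ing$edge.length / depth
  ing$node.label <- paste0("n", seq_len(ing$Nnode))
  ingroup_nwk <- ape::write.tree(ing)
  ingroup_nwk <- sub(";$", "", ingroup_nwk)
  nwk <- sprintf("(%s:0.3,%s:1.0)root;", ingroup_nwk, cfg$outgroup)
  species_tree(ape::read.tree(text = nwk), outgroup = cfg$outgroup)
}
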