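# Writing a simulated dataset to standard flat formats, and reading any
# such dataset (simulated or otherwise) back into analysis objects.

#' Gene models for every leaf of a simulation
#'
#' Embeds each leaf gene in its genomic context (random flanks, random
#' strand drawn at simulation time) and returns per-species lists of
#' [gene_model()] objects, exactly as [read_gff_genes()] would reconstruct
#' them from the emitted files.
#'
#' @param sim an `intron_sim`
#' @return named list: species -> named list of gene models
#' @export
as_gene_models <- function(sim) {
  out <- list()
  for (sp in names(sim$genes)) {
    models <- list()
    for (g in names(sim$genes[[sp]])) {
      st <- sim$genes[[sp]][[g]]
      gid <- paste0(sp, "_", g)
      region <- paste0(gid, "_scaf")
      introns <- make_intron_df(st$introns$cds_offset, st$introns$seq)
      sense <- paste0(st$flank1, gene_sense_seq(st$cds, introns), st$flank2)
      gm <- gene_model_from_parts(gid, sp, region, st$cds, introns,
                                  offset = nchar(st$flank1),
                                  strand = st$strand,
                                  contig_len = nchar(sense))
      attr(gm, "contig") <- if (st$strand == "+") sense else revcomp(sense)
      models[[gid]] <- gm
    }
    out[[sp]] <- models
  }
  out
}

#' Write a simulated dataset to a directory of standard flat files
#'
#' Emits per-species genome FASTA and GFF3 annotation, the full species
#' tree (Newick, labelled nodes), the transposon library and organelle
#' genome FASTA, a germline-expression flag table, and the simulation truth
#' log (events, per-leaf intron-to-column map).  Reading the files back
#' through [read_dataset()] reproduces every gene model exactly.
#'
#' @param sim an `intron_sim`
#' @param outdir output directory (created if needed)
#' @return `outdir`, invisibly
#' @export
write_dataset <- function(sim, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  hash <- config_hash(unclass(sim$config)[setdiff(names(sim$config), "tree")])
  dir.create(file.path(outdir, "genomes"), showWarnings = FALSE)
  dir.create(file.path(outdir, "annotations"), showWarnings = FALSE)
  models <- as_gene_models(sim)
  for (sp in names(models)) {
    contigs <- vapply(models[[sp]], function(gm) attr(gm, "contig"),
                      character(1))
    names(contigs) <- vapply(models[[sp]], function(gm) gm$seq_region,
                             character(1))
    write_fasta(contigs, file.path(outdir, "genomes", paste0(sp, ".fa")))
    write_gff3(models[[sp]], file.path(outdir, "annotations",
                                       paste0(sp, ".gff3")), hash = hash)
  }
  ape::write.tree(sim$tree, file.path(outdir, "tree.nwk"))
  write_fasta(sim$transposons, file.path(outdir, "transposons.fa"))
  write_fasta(c(mito = sim$mito), file.path(outdir, "mito.fa"))
  write_tsv_stamped(sim$germline, file.path(outdir, "expression.tsv"), hash)
  write_tsv_stamped(sim$truth, file.path(outdir, "truth.tsv"), hash)
  write_tsv_stamped(sim$intron_map, file.path(outdir, "intron_map.tsv"), hash)
  cfg <- unclass(sim$config)
  cfg$tree <- NULL
  cfg$outgroup_name <- sim$outgroup
  cfg$config_hash <- hash
  writeLines(yaml::as.yaml(cfg), file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' Read a dataset directory into analysis objects
#'
#' Expects the layout written by [write_dataset()]: `genomes/<species>.fa`,
#' `annotations/<species>.gff3`, `tree.nwk`, and optionally
#' `transposons.fa`, `mito.fa`, `expression.tsv` and the simulation truth
#' files.
#'
#' @param dir dataset directory
#' @param outgroup outgroup leaf name; defaults to the name recorded in
#'   `config.yaml` when present
#' @return an `intron_dataset` object
#' @export
read_dataset <- function(dir, outgroup = NULL) {
  if (!dir.exists(dir)) stop("dataset directory not found: ", dir)
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else list()
  outgroup <- outgroup %||% cfg$outgroup_name
  fa <- list.files(file.path(dir, "genomes"), pattern = "\\.fa$",
                   full.names = TRUE)
  if (!length(fa)) stop("no genome FASTA files under ", dir)
  species <- sub("\\.fa$", "", basename(fa))
  models <- list()
  for (i in seq_along(fa)) {
    if (file.size(fa[i]) == 0) {       # valid empty dataset
      models[[species[i]]] <- list()
      next
    }
    genome <- read_fasta(fa[i])
    gms <- read_gff_genes(file.path(dir, "annotations",
                                    paste0(species[i], ".gff3")), genome)
    for (j in seq_along(gms)) gms[[j]]$species <- species[i]
    models[[species[i]]] <- gms
  }
  tree <- read_newick(file.path(dir, "tree.nwk"), outgroup = outgroup)
  opt_fasta <- function(p) if (file.exists(p)) read_fasta(p) else NULL
  opt_tsv <- function(p) if (file.exists(p)) read_tsv_stamped(p) else NULL
  mito <- opt_fasta(file.path(dir, "mito.fa"))
  structure(list(dir = dir, species = species, models = models, tree = tree,
                 outgroup = outgroup,
                 transposons = opt_fasta(file.path(dir, "transposons.fa")),
                 mito = if (!is.null(mito)) mito[[1]] else NULL,
                 expression = opt_tsv(file.path(dir, "expression.tsv")),
                 truth = opt_tsv(file.path(dir, "truth.tsv")),
                 intron_map = opt_tsv(file.path(dir, "intron_map.tsv")),
                 config = cfg),
            class = "intron_dataset")
}

#' @export
print.intron_dataset <- function(x, ...) {
  cat(sprintf("<intron_dataset> %d species, %d genes (%s)\n",
              length(x$species), sum(lengths(x$models)), x$dir))
  invisible(x)
}
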