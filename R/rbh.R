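#' Ortholog groups from reciprocal best hits
#'
#' A cross-species gene pair is kept when each gene is the other's unique
#' best-scoring hit in the partner species and both directions pass the
#' e-value, identity and query-coverage thresholds.  Kept pairs are joined
#' into connected components; any component containing two genes from the
#' same species is discarded as unresolved paralogy.
#'
#' @param hits data.frame as produced by [all_vs_all_hits()]
#' @param species named character vector mapping gene id to species
#' @param min_identity,min_coverage,max_e acceptance thresholds
#' @return list of ortholog groups, each a named character vector
#'   (species -> gene id) with >= 2 members
#' @export
reciprocal_best_hits <- function(hits, species, min_identity = 70,
                                 min_coverage = 80, max_e = 1e-30) {
  if (nrow(hits) == 0L) return(list())
  hits$query_species <- unname(species[hits$query_id])
  hits$target_species <- unname(species[hits$target_id])
  ok <- hits$identity_pct >= min_identity &
    hits$query_coverage_pct >= min_coverage & hits$e_value <= max_e
  pass_keys <- paste(hits$query_id[ok], hits$target_id[ok], sep = "\r")
  if (!length(pass_keys)) return(list())

  # unique best hit per (query gene, target species) over ALL hits; score
  # ties disqualify the pair
  key <- paste(hits$query_id, hits$target_species, sep = "\r")
  best <- character(0)
  for (k in unique(key)) {
    sub <- hits[key == k, , drop = FALSE]
    mx <- max(sub$score)
    top <- sub[sub$score == mx, , drop = FALSE]
    if (nrow(top) == 1L) best[k] <- top$target_id
  }
  a <- character(0); b <- character(0)
  for (k in names(best)) {
    q <- sub("\r.*$", "", k)
    t <- best[[k]]
    back <- best[paste(t, species[[q]], sep = "\r")]
    if (!is.na(back) && identical(unname(back), q) && q < t &&
        paste(q, t, sep = "\r") %in% pass_keys &&
        paste(t, q, sep = "\r") %in% pass_keys) {
      a <- c(a, q); b <- c(b, t)
    }
  }
  if (!length(a)) return(list())
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  out <- list()
  for (memb in groups) {
    sp <- unname(species[memb])
    if (anyDuplicated(sp)) next      # within-species duplicate: discard
    if (length(memb) < 2L) next
    grp <- setNames(memb, sp)
    out[[length(out) + 1L]] <- grp[order(names(grp))]
  }
  # stable ordering: by the lexicographically first member
  if (length(out))
    out <- out[order(vapply(out, function(m) sort(m)[1], character(1)))]
  names(out) <- sprintf("og%03d", seq_along(out))
  out
}
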