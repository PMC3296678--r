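# Independent oracles and shared fixtures for the test suite.

# plain-matrix Gotoh local alignment (scores only), written directly from
# the recurrence: first gap position costs `open`, further ones `ext`,
# transitions between opposite gap states allowed, ambiguity never matches
sw_oracle <- function(q, t, match = 5, mis = -4, open = 16, ext = 8) {
  qv <- strsplit(q, "")[[1]]; tv <- strsplit(t, "")[[1]]
  n <- length(qv); m <- length(tv)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      Ix[i, j] <- max(M[i - 1, j] - open, Iy[i - 1, j] - open,
                      Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open, Ix[i, j - 1] - open,
                      Iy[i, j - 1] - ext)
      s <- if (qv[i - 1] == tv[j - 1] &&
               qv[i - 1] %in% c("A", "C", "G", "T")) match else mis
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + s)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Pearson chi-square on a 2x2 from first principles
chi22_oracle <- function(a, na_, b, nb) {
  tab <- matrix(c(a, na_ - a, b, nb - b), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x <- sum((tab - E)^2 / E)
  c(stat = x, p = pchisq(x, 1, lower.tail = FALSE))
}

# KS-uniform oracle using the conjugate theta-function representation of
# the Kolmogorov distribution (the package uses the alternating series)
ks_oracle <- function(x) {
  x <- sort(x); n <- length(x); i <- seq_len(n)
  D <- max(pmax(i / n - x, x - (i - 1) / n))
  lam <- sqrt(n) * D
  k <- seq_len(500)
  p <- 1 - sqrt(2 * pi) / lam * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * lam^2)))
  c(D = D, p = min(1, max(0, p)))
}

# brute-force maximal common substrings of length >= min_len
substr_oracle <- function(a, b, min_len = 5L) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  out <- character(0)
  for (i in seq_along(va)) {
    for (j in seq_along(vb)) {
      l <- 0L
      while (i + l <= length(va) && j + l <= length(vb) &&
             va[i + l] == vb[j + l] && va[i + l] %in% c("A", "C", "G", "T"))
        l <- l + 1L
      maximal <- l >= min_len &&
        (i == 1L || j == 1L || va[i - 1] != vb[j - 1] ||
           !va[i - 1] %in% c("A", "C", "G", "T"))
      if (maximal) out <- c(out, substr(a, i, i + l - 1L))
    }
  }
  unique(out)
}

# exhaustive Dollo oracle: minimal loss count over all internal-state
# assignments with the given root state and at most one 0->1 edge
# (none when the root already carries the intron)
dollo_min_losses_oracle <- function(tree, states, root_state) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  combos <- as.matrix(expand.grid(rep(list(0:1), m)))
  ST <- cbind(matrix(rep(unname(states[tree$tip.label]),
                         each = nrow(combos)), nrow(combos), n), combos)
  P <- ST[, tree$edge[, 1], drop = FALSE]
  C <- ST[, tree$edge[, 2], drop = FALSE]
  gains <- rowSums(P == 0 & C == 1)
  losses <- rowSums(P == 1 & C == 0)
  root <- combos[, 1]
  ok <- if (root_state == 1L) {
    # intron ancestral: present at the root, never re-gained
    root == 1 & gains == 0
  } else {
    # intron absent above the root: either one gain inside, or the gain
    # sits on the (virtual) edge into the root itself
    (root == 0 & gains <= 1) | (root == 1 & gains == 0)
  }
  if (!any(ok)) return(Inf)
  min(losses[ok])
}

# sweep: for every rooted (binary) tree shape with up to `max_leaves`
# labelled leaves and every binary leaf-state vector and root state,
# check that the package reconstruction (a) reproduces the leaf pattern
# and (b) attains the exhaustive minimal loss count
dollo_oracle_sweep <- function(max_leaves = 6L) {
  n_cases <- 0L
  all_equal <- TRUE
  for (n in 2:max_leaves) {
    trees <- phangorn::allTrees(n, rooted = TRUE,
                                tip.label = LETTERS[seq_len(n)])
    vecs <- as.matrix(expand.grid(rep(list(0:1), n)))
    colnames(vecs) <- LETTERS[seq_len(n)]
    for (ti in seq_along(trees)) {
      tr <- trees[[ti]]   # [[ restores the shared tip labels of multiPhylo
      tr$node.label <- paste0("i", seq_len(tr$Nnode))
      for (v in seq_len(nrow(vecs))) {
        states <- vecs[v, ]
        for (root_state in 0:1) {
          rec <- intronevo:::dollo_reconstruct(tr, states, root_state)
          n_cases <- n_cases + 1L
          if (!any(states == 1)) {
            if (!(is.na(rec$gain_node) && length(rec$loss_nodes) == 0L))
              all_equal <- FALSE
            next
          }
          # (a) replay the events: leaves below the gain node (or all, if
          # ancestral) minus leaves below loss edges must equal the pattern
          present <- rep(root_state == 1L, n)
          if (!is.na(rec$gain_node))
            present[intronevo:::tips_below(tr, rec$gain_node)] <- TRUE
          for (l in rec$loss_nodes)
            present[intronevo:::tips_below(tr, l)] <- FALSE
          if (!identical(as.integer(present), unname(states)))
            all_equal <- FALSE
          # (b) loss count must equal the exhaustive minimum
          omin <- dollo_min_losses_oracle(tr, states, root_state)
          if (root_state == 0L && is.na(rec$gain_node)) {
            # package treats an all-absent column as eventless
            next
          }
          if (length(rec$loss_nodes) != omin) all_equal <- FALSE
        }
      }
    }
  }
  list(all_equal = all_equal, n_cases = n_cases)
}

# memoised small end-to-end fixture: 10 genes x 6 taxa, no divergence
.fixture <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture$small)) {
    cfg <- sim_config(seed = 7, n_taxa = 6, n_genes = 10, subst_rate = 0,
                      annot_error_rate = 0.1)
    sim <- evolve_family(cfg)
    dir <- file.path(tempdir(), "intronevo-small-fixture")
    write_dataset(sim, dir)
    ds <- read_dataset(dir)
    fit <- intron_events(ds)
    .fixture$small <- list(cfg = cfg, sim = sim, dir = dir, ds = ds,
                           fit = fit)
  }
  .fixture$small
}
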