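# Direct-repeat and target-site-duplication scans at intron-exon junctions.

# all maximal exact common substrings of length >= min_len between a and b,
# with 1-based positions; longest first, ties by leftmost occurrence in a
maximal_common_substrings <- function(a, b, min_len = 5L) {
  va <- chars(a); vb <- chars(b)
  n <- length(va); m <- length(vb)
  empty <- data.frame(seq = character(), len = integer(), pos_a = integer(),
                      pos_b = integer(), stringsAsFactors = FALSE)
  if (n < min_len || m < min_len) return(empty)
  eq <- outer(va, vb, "==") & matrix(va %in% c("A", "C", "G", "T"), n, m)
  L <- matrix(0L, n, m)
  L[1, ] <- as.integer(eq[1, ])
  if (n > 1) {
    for (i in 2:n) {
      L[i, 1] <- as.integer(eq[i, 1])
      j <- 2:m
      L[i, j] <- ifelse(eq[i, j], L[i - 1, j - 1] + 1L, 0L)
    }
  }
  # maximal runs end where the run cannot be extended
  ext <- matrix(FALSE, n, m)
  ext[-n, -m] <- eq[-1, -1]
  hit <- which(L >= min_len & !ext, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  len <- L[hit]
  out <- data.frame(seq = substring(a, hit[, 1] - len + 1L, hit[, 1]),
                    len = len, pos_a = hit[, 1] - len + 1L,
                    pos_b = hit[, 2] - len + 1L, stringsAsFactors = FALSE)
  out <- out[order(-out$len, out$pos_a, out$pos_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Direct repeats at intron-exon junctions
#'
#' Scans for exact repeats of length >= `min_len` occurring both in the
#' terminal `window` nt of an exon flank and the adjacent terminal
#' `window` nt of the intron, at either junction.  Repeats are reported
#' longest first, ties by leftmost position.
#'
#' @param left_exon_flank,intron_seq,right_exon_flank junction sequences
#' @param min_len minimum repeat length (bp)
#' @param window junction window (nt); flanks shorter than the window are
#'   used in full
#' @return data.frame: `seq`, `len`, `side` ("5prime"/"3prime"),
#'   `pos_exon`, `pos_intron` (1-based within the scanned windows)
#' @export
find_direct_repeats <- function(left_exon_flank, intron_seq,
                                right_exon_flank, min_len = 5L,
                                window = 30L) {
  lw <- substring(left_exon_flank,
                  max(1L, nchar(left_exon_flank) - window + 1L))
  rw <- substr(right_exon_flank, 1L, window)
  i5 <- substr(intron_seq, 1L, window)
  i3 <- substring(intron_seq, max(1L, nchar(intron_seq) - window + 1L))
  five <- maximal_common_substrings(lw, i5, min_len)
  three <- maximal_common_substrings(rw, i3, min_len)
  out <- rbind(
    if (nrow(five)) data.frame(seq = five$seq, len = five$len,
                               side = "5prime", pos_exon = five$pos_a,
                               pos_intron = five$pos_b,
                               stringsAsFactors = FALSE),
    if (nrow(three)) data.frame(seq = three$seq, len = three$len,
                                side = "3prime", pos_exon = three$pos_a,
                                pos_intron = three$pos_b,
                                stringsAsFactors = FALSE))
  if (is.null(out)) {
    return(data.frame(seq = character(), len = integer(), side = character(),
                      pos_exon = integer(), pos_intron = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(-out$len, out$pos_exon, out$pos_intron), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of introns flanked by a direct repeat
#'
#' @param junctions list of junction triples, each
#'   `list(left, intron, right)`
#' @param min_len minimum repeat length
#' @param window junction window
#' @param background optional second list of junction triples; when given,
#'   a Pearson chi-square compares the two fractions
#' @return list: `fraction`, `n`, per-intron logical `flanked`, and
#'   optionally `background_fraction` and `chisq` (a `bias_report`)
#' @export
repeat_flanking_rate <- function(junctions, min_len = 5L, window = 30L,
                                 background = NULL) {
  stopifnot(length(junctions) >= 1L)
  flanked <- vapply(junctions, function(j)
    nrow(find_direct_repeats(j[[1]], j[[2]], j[[3]], min_len, window)) > 0L,
    logical(1))
  out <- list(fraction = mean(flanked), n = length(junctions),
              flanked = flanked)
  if (!is.null(background) && length(background)) {
    bg <- vapply(background, function(j)
      nrow(find_direct_repeats(j[[1]], j[[2]], j[[3]], min_len, window)) > 0L,
      logical(1))
    out$background_fraction <- mean(bg)
    tab <- matrix(c(sum(flanked), sum(!flanked), sum(bg), sum(!bg)),
                  nrow = 2, byrow = TRUE)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    out$chisq <- bias_report("direct-repeat rate vs background",
                             ct$statistic, ct$p.value, counts = tab,
                             n = length(junctions) + length(background))
  }
  out
}

#' Target-site duplication at a gained intron
#'
#' Looks for the longest string of length `min_len`..`max_len` that opens
#' the intron's 5' end and recurs, with at most `max_mismatch`
#' mismatches, within `max_len` nt around the 3' intron-exon junction
#' (late in the intron or early in the downstream exon) - the classic
#' footprint of transposon insertion.
#'
#' @param upstream_exon_flank,intron_seq,downstream_exon_flank sequences
#'   around the gained intron
#' @param min_len,max_len candidate TSD length range
#' @param max_mismatch tolerated mismatches in the downstream copy
#' @return list(`tsd`, `len`, `offset`, `mismatches`) or NULL; `offset` is
#'   the 0-based position of the copy relative to the 3' junction
#'   (negative = begins inside the intron)
#' @export
detect_tsd <- function(upstream_exon_flank, intron_seq,
                       downstream_exon_flank, min_len = 4L, max_len = 15L,
                       max_mismatch = 1L) {
  ni <- nchar(intron_seq)
  if (ni < min_len) return(NULL)
  tailw <- substring(intron_seq, max(1L, ni - max_len + 1L))
  junction <- paste0(tailw, substr(downstream_exon_flank, 1L,
                                   max_len + max_len))
  off0 <- nchar(tailw)   # position of the junction within `junction`
  for (l in seq(min(max_len, ni), min_len)) {
    pat <- chars(substr(intron_seq, 1L, l))
    limit <- nchar(junction) - l + 1L
    if (limit < 1L) next
    for (s in seq_len(limit)) {
      cand <- chars(substr(junction, s, s + l - 1L))
      mm <- sum(pat != cand | !(pat %in% c("A", "C", "G", "T")))
      if (mm <= max_mismatch) {
        return(list(tsd = paste(pat, collapse = ""), len = l,
                    offset = s - 1L - off0, mismatches = mm))
      }
    }
  }
  NULL
}
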