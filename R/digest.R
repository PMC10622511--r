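#' In-silico restriction digest
#'
#' Splits a linear sequence at every occurrence of each recognition site
#' (searched on both strands) and returns the fragment lengths. Cut
#' positions are taken at the midpoint of each site occurrence, which for a
#' palindromic recognition sequence makes fragment arithmetic symmetric: a
#' chromosome carrying a symmetric inverted duplication whose nearest site
#' midpoint lies `d` bp from the duplication center yields a center-spanning
#' fragment of length `2 d`.
#'
#' @param seq A DNA string (a derivative chromosome, typically).
#' @param sites Character vector of recognition sequences (A/C/G/T only).
#' @return A tibble with `fragment` (index along the molecule), `start`,
#'   `end` (0-based half-open) and `length`.
#' @export
predict_restriction_fragments <- function(seq, sites) {
  if (length(sites) == 0) stopf("no recognition sites given")
  if (any(grepl("[^ACGTacgt]", sites))) {
    stopf("recognition sites must contain only A/C/G/T")
  }
  L <- nchar(seq)
  cuts <- integer(0)
  for (site in sites) {
    hits <- locate_motif(seq, site)
    rc <- revcomp(site)
    if (rc != site) hits <- c(hits, locate_motif(seq, rc))
    cuts <- c(cuts, hits + nchar(site) %/% 2L)
  }
  cuts <- sort(unique(cuts))
  bounds <- c(0L, cuts, L)
  tibble(fragment = seq_len(length(bounds) - 1L),
         start = bounds[-length(bounds)],
         end = bounds[-1],
         length = diff(bounds))
}

#' Center-spanning fragment length for a symmetric inverted duplication
#'
#' For an inverted duplication with the nearest restriction-site midpoint
#' `d` bp from the duplication center on each arm, the fragment spanning the
#' center has length `2 d` — the diagnostic doubling used to confirm
#' inverted duplications on Southern blots.
#'
#' @param d Distance (bp) from the site midpoint to the duplication center.
#' @return Fragment length `2 d`.
#' @export
center_fragment_rule <- function(d) {
  stopifnot(all(d >= 0))
  2 * d
}
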