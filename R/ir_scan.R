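#' Scan a sequence for inverted repeats
#'
#' Reports maximal (non-extendable) inverted repeats: pairs of arms that are
#' reverse complements of each other up to `max_mismatch` substitutions,
#' separated by a spacer of at most `max_spacer` bp. For every candidate
#' (left-arm end, right-arm start) placement the arms are extended outward to
#' the longest length whose mismatch count stays within budget; arms are
#' trimmed so that both their innermost and outermost positions match
#' (an IR whose innermost positions mismatch is reported at the wider-spacer
#' placement instead). One IR is reported per placement; results are sorted
#' by position (leftmost first), ties broken by longer arm.
#'
#' Coordinates are 0-based half-open within `seq`. Mismatch offsets are
#' 0-based positions within the arm, counted from the arm's inner
#' (spacer-proximal) end of the left arm.
#'
#' @param seq A DNA string.
#' @param min_arm Minimum arm length (bp).
#' @param max_spacer Maximum spacer length (bp).
#' @param max_mismatch Maximum number of substitution mismatches between the
#'   left arm and the reverse complement of the right arm.
#' @return A tibble with columns `left_start`, `left_end`, `right_start`,
#'   `right_end`, `arm_len`, `spacer_len`, `n_mismatch`, `mismatch_offsets`
#'   (list of integer vectors), `center`.
#' @export
find_inverted_repeats <- function(seq, min_arm = 5L, max_spacer = 50L,
                                  max_mismatch = 0L) {
  L <- nchar(seq)
  if (L < 2L * min_arm) {
    return(empty_ir_tibble())
  }
  s <- strsplit(toupper(seq), "")[[1]]
  comp <- chartr("ACGT", "TGCA", s)
  out <- vector("list", 64L)
  n_out <- 0L
  for (i in seq(min_arm, L - min_arm)) {        # left arm end (0-based excl.)
    for (g in 0:max_spacer) {                   # spacer length
      j <- i + g                                # right arm start
      if (j + min_arm > L) break
      ## innermost positions must match
      if (s[i] != comp[j + 1L]) next
      kmax <- min(i, L - j)
      mism <- integer(0)
      k <- 0L
      best <- 0L
      while (k < kmax) {
        k <- k + 1L
        if (s[i - k + 1L] != comp[j + k]) {
          mism <- c(mism, k - 1L)
          if (length(mism) > max_mismatch) {
            k <- k - 1L
            break
          }
        } else {
          best <- k
        }
      }
      ## trim trailing mismatches: arm ends at the outermost matching position
      arm <- best
      mm <- mism[mism < arm]
      if (arm < min_arm) next
      ## maximality: extendable placements are still reported at their own
      ## (i, j); this one is maximal for (i, j) by construction
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- tibble(
        left_start = i - arm, left_end = i,
        right_start = j, right_end = j + arm,
        arm_len = arm, spacer_len = g,
        n_mismatch = length(mm), mismatch_offsets = list(mm),
        center = (i + j) %/% 2L
      )
    }
  }
  if (n_out == 0L) return(empty_ir_tibble())
  bind_rows(out[seq_len(n_out)]) |>
    arrange(.data$left_start, dplyr::desc(.data$arm_len), .data$right_start)
}

empty_ir_tibble <- function() {
  tibble(left_start = integer(0), left_end = integer(0),
         right_start = integer(0), right_end = integer(0),
         arm_len = integer(0), spacer_len = integer(0),
         n_mismatch = integer(0), mismatch_offsets = list(),
         center = integer(0))
}
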