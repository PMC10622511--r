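#' @keywords internal
"_PACKAGE"

#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join row_number n lag lead across if_else first last pull
#'   rename distinct slice count transmute bind_cols case_when
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data %||% abort
#' @importFrom purrr map map_chr map_dbl map_int map2 pmap imap list_rbind
#' @importFrom stats rnorm runif rbinom setNames median p.adjust fisher.test
#'   t.test sd
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' Derive a module seed from a global seed
#'
#' One global seed deterministically derives every module-level seed, keeping
#' the whole pipeline reproducible while decoupling the random streams of
#' independent stages. Result always fits a 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param label Character tag naming the consumer stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131L)
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647) + 1L
}

## random DNA of length n under the current RNG state
random_dna <- function(n, rng = NULL) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## substitute bases at given 1-based positions with a different base
substitute_bases <- function(seq, pos) {
  s <- strsplit(seq, "")[[1]]
  for (p in pos) {
    s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
  }
  paste(s, collapse = "")
}

## mutate a sequence by per-base substitution at the given rate
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  substitute_bases(seq, sample.int(n, k))
}

## 0-based half-open slice of a character sequence
slice0 <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1, end)
}

## count occurrences of motif on both strands
count_motif <- function(seq, motif) {
  n <- Biostrings::countPattern(motif, Biostrings::DNAString(seq))
  rcm <- revcomp(motif)
  if (rcm != motif) {
    n <- n + Biostrings::countPattern(rcm, Biostrings::DNAString(seq))
  }
  n
}

## 0-based start positions of exact motif matches on the plus strand
locate_motif <- function(seq, motif) {
  Biostrings::start(Biostrings::matchPattern(motif, Biostrings::DNAString(seq))) - 1L
}

stopf <- function(fmt, ...) {
  abort(sprintf(fmt, ...))
}
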