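#' Simulate paired-end reads with truth alignments
#'
#' Samples fragments uniformly along each chromosome of a genome (reference
#' or derivative), with truncated-normal fragment lengths and optional
#' per-base substitution errors, and returns both the read sequences and
#' their truth alignments against the source genome. The expected number of
#' pairs per chromosome is `depth * L / (2 * read_len)`.
#'
#' @param genome A `reference_model`, `derivative_genome`, or named character
#'   vector of chromosome sequences.
#' @param params A [readsim_params()].
#' @param with_seq Keep read sequences in the alignment table (needed for
#'   FASTQ output and junction assembly; drop for depth-only work).
#' @param seed RNG seed (defaults to the seed in `params`).
#' @return An object of class `read_sim`: list with `alignments` (tibble,
#'   two rows per pair: `qname`, `mate`, `chrom`, `pos`, `strand`,
#'   `read_len`, `aln_len`, `clip5`, `clip3`, and `seq` if requested) and
#'   `params`.
#' @export
simulate_reads <- function(genome, params = readsim_params(),
                           with_seq = TRUE, seed = params$seed) {
  seqs <- if (is.character(genome)) genome else genome$seq
  if (length(seqs) == 0 || any(nchar(seqs) == 0)) stopf("empty genome")
  set.seed(derive_seed(seed, "reads"))
  rl <- params$read_len
  per_chrom <- map(names(seqs), function(ch) {
    L <- nchar(seqs[[ch]])
    if (params$frag_mean > L) {
      stopf("fragment mean (%g) exceeds length of %s (%d)", params$frag_mean, ch, L)
    }
    n <- round(params$depth * L / (2 * rl))
    if (n == 0) return(NULL)
    flen <- pmin(pmax(round(rnorm(n, params$frag_mean, params$frag_sd)), rl), L)
    s <- floor(runif(n, 0, L - flen + 1))
    e <- s + flen
    qn <- sprintf("%s_%06d", ch, seq_len(n))
    aln <- tibble(
      qname = rep(qn, 2L),
      mate = rep(c(1L, 2L), each = n),
      chrom = ch,
      pos = as.integer(c(s, e - rl)),
      strand = rep(c("+", "-"), each = n),
      read_len = rl, aln_len = rl, clip5 = 0L, clip3 = 0L
    )
    if (with_seq) {
      fwd <- substring(seqs[[ch]], c(s, e - rl) + 1, c(s, e - rl) + rl)
      fwd[(n + 1):(2 * n)] <- revcomp(fwd[(n + 1):(2 * n)])
      aln$seq <- fwd
    }
    aln
  })
  aln <- bind_rows(per_chrom)
  if (with_seq && params$error_rate > 0 && nrow(aln) > 0) {
    n_err <- rbinom(1, nrow(aln) * rl, params$error_rate)
    if (n_err > 0) {
      idx <- sample.int(nrow(aln), n_err, replace = TRUE)
      posn <- sample.int(rl, n_err, replace = TRUE)
      for (k in seq_len(n_err)) {
        old <- substr(aln$seq[idx[k]], posn[k], posn[k])
        substr(aln$seq[idx[k]], posn[k], posn[k]) <-
          sample(setdiff(DNA_BASES, old), 1)
      }
    }
  }
  structure(list(alignments = aln, params = params,
                 chrom_lengths = setNames(nchar(seqs), names(seqs))),
            class = "read_sim")
}

#' Project derivative truth alignments onto the reference
#'
#' Maps each read's placement on a derivative chromosome through the
#' derivative's block map to reference coordinates. Reads wholly inside an
#' unrearranged block map collinearly; junction-spanning reads keep their
#' longest block-consistent segment aligned and the remainder soft-clipped;
#' reads on the inverted half of a foldback flip strand, so pairs straddling
#' the foldback center become same-strand on the reference.
#'
#' @param sim A `read_sim` from [simulate_reads()] run on a derivative.
#' @param derivative The `derivative_genome` the reads came from.
#' @param model The `reference_model`.
#' @return A tibble of reference alignments with the same columns as the
#'   input plus `mate_chrom`, `mate_pos`, `mate_strand`; reads that fall
#'   entirely within novel insertions are dropped.
#' @export
project_to_reference <- function(sim, derivative, model) {
  aln <- sim$alignments
  out <- map(split(aln, aln$chrom), function(a) {
    ch <- a$chrom[1]
    blocks <- derivative$blocks[[ch]]
    if (is.null(blocks)) stopf("no block map for chromosome '%s'", ch)
    project_records(a, blocks)
  }) |> bind_rows()
  mates <- out |>
    select("qname", "mate", m_chrom = "chrom", m_pos = "pos", m_strand = "strand") |>
    mutate(mate = 3L - .data$mate)
  out |>
    left_join(mates, by = c("qname", "mate")) |>
    rename(mate_chrom = "m_chrom", mate_pos = "m_pos", mate_strand = "m_strand")
}

## vectorized block lookup: each record keeps the block it overlaps most
project_records <- function(a, blocks) {
  s <- a$pos
  e <- a$pos + a$aln_len
  i1 <- findInterval(s, blocks$d_start)
  i2 <- findInterval(e - 1L, blocks$d_start)
  ov1 <- pmin(e, blocks$d_end[i1]) - pmax(s, blocks$d_start[i1])
  ov2 <- pmin(e, blocks$d_end[i2]) - pmax(s, blocks$d_start[i2])
  bi <- if_else(ov2 > ov1, i2, i1)   # ties favour the lower-coordinate block
  ms <- pmax(s, blocks$d_start[bi])
  me <- pmin(e, blocks$d_end[bi])
  keep <- !is.na(blocks$ref_chrom[bi]) & me > ms
  a <- a[keep, ]
  bi <- bi[keep]; ms <- ms[keep]; me <- me[keep]; s <- s[keep]; e <- e[keep]
  minus <- blocks$strand[bi] == "-"
  ref_pos <- if_else(minus,
                     blocks$ref_start[bi] + (blocks$d_end[bi] - me),
                     blocks$ref_start[bi] + (ms - blocks$d_start[bi]))
  new_strand <- if_else(minus,
                        if_else(a$strand == "+", "-", "+"),
                        a$strand)
  ## clips in reference orientation: low-coordinate side first
  c_lo <- if_else(minus, e - me, ms - s)
  c_hi <- if_else(minus, ms - s, e - me)
  a$chrom <- blocks$ref_chrom[bi]
  a$pos <- as.integer(ref_pos)
  a$strand <- new_strand
  a$aln_len <- as.integer(me - ms)
  a$clip5 <- as.integer(c_lo)
  a$clip3 <- as.integer(c_hi)
  a
}

#' Per-position read depth
#'
#' Coverage at each position is the number of aligned read bases overlapping
#' it (soft-clipped bases do not count).
#'
#' @param alignments Alignment tibble (`chrom`, `pos`, `aln_len`).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return An object of class `depth_track`: list with `depth` (named list
#'   of numeric vectors), `n_records`, `total_aligned`.
#' @export
depth_track <- function(alignments, chrom_lengths) {
  bad <- !(alignments$chrom %in% names(chrom_lengths))
  if (any(bad)) {
    stopf("records on unknown chromosome: %s",
          paste(unique(alignments$chrom[bad]), collapse = ", "))
  }
  depth <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    a <- alignments[alignments$chrom == ch, ]
    d <- numeric(L + 1L)
    if (nrow(a) > 0) {
      if (any(a$pos < 0 | a$pos + a$aln_len > L)) {
        stopf("alignment outside %s bounds", ch)
      }
      starts <- a$pos + 1L
      ends <- a$pos + a$aln_len + 1L
      add <- tabulate(starts, nbins = L + 1L) - tabulate(ends, nbins = L + 1L)
      d <- cumsum(add)
    }
    d[seq_len(L)]
  })
  structure(list(depth = setNames(depth, names(chrom_lengths)),
                 n_records = nrow(alignments),
                 total_aligned = sum(as.numeric(alignments$aln_len))),
            class = "depth_track")
}

#' Write paired reads as FASTQ
#'
#' @param sim A `read_sim` (with sequences).
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with `/1`, `/2` read-name suffixes and fixed quality.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(sim, prefix) {
  aln <- sim$alignments
  if (is.null(aln$seq)) stopf("read sequences were not retained")
  paths <- character(2)
  for (m in 1:2) {
    a <- aln[aln$mate == m, ]
    qual <- strrep("I", a$read_len[1] %||% 0)
    lines <- as.vector(rbind(paste0("@", a$qname, "/", m), a$seq, "+",
                             rep(qual, nrow(a))))
    paths[m] <- paste0(prefix, "_", m, ".fastq")
    readr::write_lines(lines, paths[m])
  }
  invisible(paths)
}

#' Write alignments as SAM
#'
#' Emits a headered SAM file (1-based POS, proper paired-end flag bits,
#' soft clips in CIGAR, mate fields).
#'
#' @param alignments Alignment tibble (projected or source-space), with
#'   `mate_chrom`/`mate_pos`/`mate_strand` columns if available.
#' @param chrom_lengths Named integer vector for the `@SQ` header lines.
#' @param path Output path.
#' @param sort Sort by chromosome and position.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, chrom_lengths, path, sort = TRUE) {
  a <- alignments
  if (!"mate_chrom" %in% names(a)) {
    mates <- a |> select("qname", "mate", m_chrom = "chrom", m_pos = "pos",
                         m_strand = "strand") |>
      mutate(mate = 3L - .data$mate)
    a <- a |> left_join(mates, by = c("qname", "mate")) |>
      rename(mate_chrom = "m_chrom", mate_pos = "m_pos", mate_strand = "m_strand")
  }
  if (sort) a <- a |> arrange(match(.data$chrom, names(chrom_lengths)), .data$pos)
  flag <- 1L + 2L +
    if_else(a$strand == "-", 16L, 0L) +
    if_else(!is.na(a$mate_strand) & a$mate_strand == "-", 32L, 0L) +
    if_else(a$mate == 1L, 64L, 128L)
  cigar <- paste0(if_else(a$clip5 > 0, paste0(a$clip5, "S"), ""),
                  a$aln_len, "M",
                  if_else(a$clip3 > 0, paste0(a$clip3, "S"), ""))
  rnext <- if_else(is.na(a$mate_chrom), "*",
                   if_else(a$mate_chrom == a$chrom, "=", a$mate_chrom))
  seqf <- if (!is.null(a$seq)) a$seq else "*"
  qualf <- if (!is.null(a$seq)) strrep("I", nchar(a$seq)) else "*"
  tlen <- if_else(!is.na(a$mate_pos) & a$mate_chrom == a$chrom,
                  if_else(a$pos <= a$mate_pos,
                          a$mate_pos + a$aln_len - a$pos,
                          -(a$pos + a$aln_len - a$mate_pos)),
                  0L)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  body <- paste(a$qname, flag, a$chrom, a$pos + 1L, 60L, cigar, rnext,
                if_else(is.na(a$mate_pos), 0L, a$mate_pos + 1L), tlen,
                seqf, qualf, sep = "\t")
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a SAM/BAM file into an alignment tibble
#'
#' Convenience importer (via Rsamtools) producing the package's alignment
#' tibble format from standard SAM/BAM.
#'
#' @param path SAM or BAM path.
#' @return Alignment tibble.
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stopf("reading SAM/BAM requires the Rsamtools package")
  }
  bam <- path
  if (grepl("\\.sam$", path)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar",
             "mrnm", "mpos", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  cig <- x$cigar
  clip5 <- as.integer(stringr::str_match(cig, "^(\\d+)S")[, 2])
  clip3 <- as.integer(stringr::str_match(cig, "(\\d+)S$")[, 2])
  m_len <- map_int(stringr::str_match_all(cig, "(\\d+)M"), function(m) {
    sum(as.integer(m[, 2]))
  })
  flag <- x$flag
  tibble(
    qname = x$qname,
    mate = if_else(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    chrom = as.character(x$rname),
    pos = x$pos - 1L,
    strand = as.character(x$strand),
    read_len = nchar(as.character(x$seq)),
    aln_len = m_len,
    clip5 = dplyr::coalesce(clip5, 0L),
    clip3 = dplyr::coalesce(clip3, 0L),
    seq = as.character(x$seq),
    mate_chrom = as.character(x$mrnm),
    mate_pos = x$mpos - 1L,
    mate_strand = if_else(bitwAnd(flag, 32L) > 0L, "-", "+")
  )
}
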