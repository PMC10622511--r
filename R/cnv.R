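#' Normalize a depth track and average it in fixed bins
#'
#' Per-position coverage is first normalized to the total number of mapped
#' reads, then averaged in fixed windows anchored at position 0 of each
#' chromosome. Terminal partial bins are kept only if at least
#' `min_bin_fraction` of a full bin.
#'
#' @param track A `depth_track`.
#' @param config A [cnv_config()].
#' @return A tibble with `chrom`, `start`, `end`, `value` (mean normalized
#'   coverage per position).
#' @export
normalize_and_bin <- function(track, config = cnv_config()) {
  if (track$n_records <= 0) stopf("empty depth track: no mapped reads")
  bw <- config$bin_width
  out <- imap(track$depth, function(d, ch) {
    L <- length(d)
    if (L == 0) return(NULL)
    n_full <- L %/% bw
    rem <- L - n_full * bw
    keep_partial <- rem >= config$min_bin_fraction * bw
    n_bins <- n_full + as.integer(keep_partial)
    if (n_bins == 0) return(NULL)
    cs <- c(0, cumsum(d))
    starts <- (seq_len(n_bins) - 1L) * bw
    ends <- pmin(starts + bw, L)
    sums <- cs[ends + 1L] - cs[starts + 1L]
    tibble(chrom = ch, start = as.integer(starts), end = as.integer(ends),
           value = sums / (ends - starts) / track$n_records)
  })
  bind_rows(out)
}

#' Binned log2 copy-number ratio
#'
#' For each bin, the relative copy number is the ratio of the normalized
#' sample value to the normalized parental value; a constant pseudocount
#' (0.0625) is added to each ratio to allow log2 transformation. Bins with
#' zero parental signal are masked (flagged and excluded from testing)
#' rather than assigned infinite ratios.
#'
#' @param sample_bins,parental_bins Bin tibbles from [normalize_and_bin()]
#'   on matching grids.
#' @param config A [cnv_config()].
#' @return A tibble with `chrom`, `start`, `end`, `sample_value`,
#'   `parental_value`, `ratio`, `log2`, `masked`.
#' @export
log2_ratio <- function(sample_bins, parental_bins, config = cnv_config()) {
  if (nrow(sample_bins) != nrow(parental_bins) ||
      !all(sample_bins$chrom == parental_bins$chrom &
           sample_bins$start == parental_bins$start &
           sample_bins$end == parental_bins$end)) {
    stopf("sample and parental bin grids do not match")
  }
  masked <- parental_bins$value == 0
  ratio <- if_else(masked, NA_real_, sample_bins$value / parental_bins$value)
  tibble(chrom = sample_bins$chrom, start = sample_bins$start,
         end = sample_bins$end,
         sample_value = sample_bins$value, parental_value = parental_bins$value,
         ratio = ratio,
         log2 = log2(ratio + config$pseudocount),
         masked = masked)
}

#' Remove PCR-duplicate read pairs
#'
#' Drops all but the first read pair sharing both mates' exact placements
#' (chromosome, position, strand), the standard fragment-level duplicate
#' criterion. The packaged read simulator does not generate duplicates, so
#' on simulated data this is a no-op pathway; it is applied ahead of depth
#' counting when working from external alignments.
#'
#' @param alignments Alignment tibble with mate information (or plain
#'   per-mate records, which are paired internally).
#' @return The deduplicated alignment tibble.
#' @export
remove_duplicates <- function(alignments) {
  a1 <- alignments[alignments$mate == 1L, ]
  a2 <- alignments[alignments$mate == 2L, ]
  a2m <- a2[match(a1$qname, a2$qname), ]
  key <- paste(a1$chrom, a1$pos, a1$strand, a2m$chrom, a2m$pos, a2m$strand)
  keep <- a1$qname[!duplicated(key)]
  ## unpaired records are kept as-is
  unpaired <- setdiff(alignments$qname, a1$qname[a1$qname %in% a2$qname])
  alignments[alignments$qname %in% c(keep, unpaired), ]
}

## split read pairs into two halves by a fair coin (by pair, not by mate)
split_pairs <- function(alignments, seed) {
  set.seed(seed)
  qn <- unique(alignments$qname)
  if (length(qn) < 2) stopf("too few read pairs to split")
  in_a <- setNames(rbinom(length(qn), 1, 0.5) == 1, qn)
  a <- alignments[in_a[alignments$qname], ]
  b <- alignments[!in_a[alignments$qname], ]
  if (nrow(a) == 0 || nrow(b) == 0) stopf("degenerate split: one half is empty")
  list(a = a, b = b)
}

#' Split-parental empirical null
#'
#' Builds the empirical null distribution of per-bin log2 values by
#' repeatedly splitting the parental read pairs into two random halves and
#' running the full binning/ratio pipeline on the halves. The pooled per-bin
#' values form the null sample against which observed bins are tested.
#'
#' @param parental_alignments Alignment tibble for the parental clone.
#' @param chrom_lengths Named chromosome lengths.
#' @param config A [cnv_config()] (uses `n_null_splits`, `seed`).
#' @param seed RNG seed (defaults to the config seed).
#' @return A tibble with `split`, `chrom`, `start`, `end`, `log2`, `masked`.
#' @export
split_parental_null <- function(parental_alignments, chrom_lengths,
                                config = cnv_config(), seed = config$seed) {
  if (nrow(parental_alignments) == 0) stopf("empty parental read set")
  map(seq_len(config$n_null_splits), function(k) {
    halves <- split_pairs(parental_alignments, derive_seed(seed, paste0("split", k)))
    ta <- depth_track(halves$a, chrom_lengths)
    tb <- depth_track(halves$b, chrom_lengths)
    log2_ratio(normalize_and_bin(ta, config), normalize_and_bin(tb, config),
               config) |>
      mutate(split = k, .before = 1) |>
      select("split", "chrom", "start", "end", "log2", "masked")
  }) |> bind_rows()
}

#' Empirical two-sided p-values against a null sample
#'
#' Extremeness is measured as absolute deviation from the null median; the
#' p-value uses the add-one estimator `(1 + r) / (N + 1)` where `r` counts
#' null values at least as extreme as the observation, so p is never zero.
#'
#' @param observed Numeric vector of observed bin values.
#' @param null_values Numeric vector of null bin values.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
empirical_pvalues <- function(observed, null_values) {
  null_values <- null_values[!is.na(null_values)]
  N <- length(null_values)
  if (N == 0) stopf("empty null distribution")
  if (N < 100) warning("null distribution has fewer than 100 values")
  med <- median(null_values)
  ext_null <- abs(null_values - med)
  vapply(observed, function(x) {
    if (is.na(x)) return(NA_real_)
    (1 + sum(ext_null >= abs(x - med))) / (N + 1)
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]); `NA` p-values
#' (masked bins) stay `NA` and do not enter the correction.
#'
#' @param p Numeric vector of p-values.
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Merge significant bins into CNV segments
#'
#' Bins with `q < alpha` are flagged and maximal runs of same-direction
#' flagged bins merged into segments.
#'
#' @param bins A bin tibble carrying `log2`, `q`, `masked` columns plus a
#'   `null_median` attribute (as produced inside [cnv_scan()]), or with
#'   `null_median` supplied explicitly.
#' @param config A [cnv_config()].
#' @param null_median Center of the null distribution, used to orient
#'   gain/loss.
#' @return A tibble of segments: `chrom`, `start`, `end`, `direction`,
#'   `n_bins`, `mean_log2`, `first_bin`, `last_bin`.
#' @export
call_segments <- function(bins, config = cnv_config(),
                          null_median = attr(bins, "null_median")) {
  if (is.null(null_median)) null_median <- log2(1 + config$pseudocount)
  b <- bins |>
    mutate(.bin_id = row_number(),
           sig = !.data$masked & !is.na(.data$q) & .data$q < config$alpha,
           dir = if_else(.data$sig,
                         if_else(.data$log2 > null_median, "gain", "loss"),
                         "none"))
  b <- b |>
    group_by(.data$chrom) |>
    mutate(.run = cumsum(.data$dir != lag(.data$dir, default = "__"))) |>
    ungroup() |>
    filter(.data$dir != "none")
  if (nrow(b) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  direction = character(0), n_bins = integer(0),
                  mean_log2 = numeric(0), first_bin = integer(0),
                  last_bin = integer(0)))
  }
  segs <- b |>
    group_by(.data$chrom, .data$.run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              direction = first(.data$dir), n_bins = n(),
              mean_log2 = mean(.data$log2),
              first_bin = min(.data$.bin_id), last_bin = max(.data$.bin_id),
              .groups = "drop") |>
    select(-".run") |>
    arrange(.data$chrom, .data$start)
  segs
}

#' Run the full CNV-calling procedure
#'
#' Per-position depth for sample and parental, total-read normalization,
#' fixed-width binning, per-bin sample/parental ratio with a 0.0625
#' pseudocount, log2 transformation, split-parental empirical null,
#' two-sided empirical p-values, BH FDR, and segmentation at q < 0.001.
#'
#' @param sample_alignments,parental_alignments Alignment tibbles.
#' @param chrom_lengths Named chromosome lengths.
#' @param config A [cnv_config()].
#' @return An object of class `cnv_scan`: list with `bins` (tibble including
#'   `p`, `q`, `sig`), `segments`, `null_median`, `n_null`, `config`.
#' @export
cnv_scan <- function(sample_alignments, parental_alignments, chrom_lengths,
                     config = cnv_config()) {
  ts <- depth_track(sample_alignments, chrom_lengths)
  tp <- depth_track(parental_alignments, chrom_lengths)
  bins <- log2_ratio(normalize_and_bin(ts, config),
                     normalize_and_bin(tp, config), config)
  null <- split_parental_null(parental_alignments, chrom_lengths, config)
  if (config$pool == "genome") {
    nv <- null$log2[!null$masked]
    bins$p <- empirical_pvalues(bins$log2, nv)
    null_median <- median(nv)
  } else {
    bins$p <- NA_real_
    null_median <- numeric(0)
    for (ch in unique(bins$chrom)) {
      nv <- null$log2[!null$masked & null$chrom == ch]
      sel <- bins$chrom == ch
      bins$p[sel] <- empirical_pvalues(bins$log2[sel], nv)
      null_median[ch] <- median(nv)
    }
    null_median <- median(null$log2[!null$masked])
  }
  bins$q <- bh_fdr(bins$p)
  bins$sig <- !bins$masked & !is.na(bins$q) & bins$q < config$alpha
  attr(bins, "null_median") <- null_median
  segments <- call_segments(bins, config, null_median)
  structure(list(bins = bins, segments = segments,
                 null_median = null_median,
                 n_null = sum(!null$masked), config = config),
            class = "cnv_scan")
}

#' @export
print.cnv_scan <- function(x, ...) {
  cat("<cnv_scan>", nrow(x$bins), "bins,", sum(x$bins$sig), "significant,",
      nrow(x$segments), "segments\n")
  invisible(x)
}

#' Tidy a CNV scan into its per-bin table
#'
#' @param x A `cnv_scan`.
#' @param ... Unused.
#' @return The per-bin tibble (`chrom`, `start`, `end`, `log2`, `p`, `q`,
#'   `sig`, ...).
#' @exportS3Method generics::tidy
tidy.cnv_scan <- function(x, ...) {
  as_tibble(x$bins)
}

#' One-row summary of a CNV scan
#'
#' @param x A `cnv_scan`.
#' @param ... Unused.
#' @return A one-row tibble: bin and segment counts, flagged fraction,
#'   null size.
#' @exportS3Method generics::glance
glance.cnv_scan <- function(x, ...) {
  tibble(n_bins = nrow(x$bins),
         n_masked = sum(x$bins$masked),
         n_sig = sum(x$bins$sig),
         frac_sig = mean(x$bins$sig[!x$bins$masked]),
         n_segments = nrow(x$segments),
         n_gain = sum(x$segments$direction == "gain"),
         n_loss = sum(x$segments$direction == "loss"),
         n_null = x$n_null,
         alpha = x$config$alpha)
}

#' Plot a CNV scan as per-bin log2 tracks
#'
#' @param object A `cnv_scan`.
#' @param chroms Optional subset of chromosomes.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cnv_scan <- function(object, chroms = NULL, ...) {
  b <- object$bins
  if (!is.null(chroms)) b <- b[b$chrom %in% chroms, ]
  ggplot2::ggplot(b, ggplot2::aes(x = (.data$start + .data$end) / 2e3,
                                  y = .data$log2, colour = .data$sig)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_hline(yintercept = object$null_median, linetype = 2,
                        colour = "grey40") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "significant") +
    ggplot2::labs(x = "position (kb)", y = "log2 copy-number ratio")
}

#' Write CNV results as TSV / BED
#'
#' @param scan A `cnv_scan`.
#' @param prefix Output path prefix; writes `<prefix>_bins.tsv` and
#'   `<prefix>_segments.bed`.
#' @return Paths, invisibly.
#' @export
write_cnv <- function(scan, prefix) {
  bins_path <- paste0(prefix, "_bins.tsv")
  readr::write_tsv(scan$bins |> select("chrom", "start", "end", "log2",
                                       "p", "q", "sig", "masked"), bins_path)
  bed_path <- paste0(prefix, "_segments.bed")
  segs <- scan$segments |>
    transmute(.data$chrom, .data$start, .data$end,
              name = paste0(.data$direction, ":", round(.data$mean_log2, 3)))
  readr::write_tsv(segs, bed_path, col_names = FALSE)
  invisible(c(bins = bins_path, segments = bed_path))
}
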