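#' Full-null calibration of the CNV procedure
#'
#' Measures the false-flagging rate of the whole CNV pipeline when there is
#' no signal at all: a parental read set is simulated at uniform coverage,
#' and for each replicate one random half-split plays the role of
#' sample-vs-parental while further independent splits provide the
#' split-parental empirical null. The fraction of bins called significant
#' (BH q below the configured threshold) should not exceed that threshold.
#'
#' @param seed Integer seed governing every random draw.
#' @param n_reps Number of replicate observed splits.
#' @param genome_len Length (bp) of the single synthetic chromosome.
#' @param depth Parental sequencing depth (x).
#' @param read_len Read length (nt).
#' @param config A [cnv_config()]; its `alpha`, `bin_width` and
#'   `n_null_splits` drive the procedure.
#' @return A list with `mean_fraction` (mean flagged-bin fraction across
#'   replicates), `per_rep` (numeric vector), `n_bins`, and `alpha`.
#' @export
full_null_calibration <- function(seed = 1L,
                                  n_reps = 20L,
                                  genome_len = 500000L,
                                  depth = 20,
                                  read_len = 75L,
                                  config = cnv_config(bin_width = 1000L,
                                                      n_null_splits = 10L)) {
  set.seed(derive_seed(seed, "calibration_genome"))
  genome <- setNames(random_dna(genome_len), "chr_null")
  sim <- simulate_reads(genome, readsim_params(depth = depth,
                                               read_len = read_len),
                        with_seq = FALSE,
                        seed = derive_seed(seed, "calibration_reads"))
  cl <- setNames(as.integer(genome_len), "chr_null")
  per_rep <- vapply(seq_len(n_reps), function(r) {
    ## observed comparison: one fresh random half-split
    obs_halves <- split_pairs(sim$alignments,
                              derive_seed(seed, paste0("obs_split_", r)))
    obs <- log2_ratio(
      normalize_and_bin(depth_track(obs_halves$a, cl), config),
      normalize_and_bin(depth_track(obs_halves$b, cl), config),
      config)
    ## null from independent splits of the same parental read set
    null <- split_parental_null(sim$alignments, cl, config,
                                seed = derive_seed(seed, paste0("null_", r)))
    p <- empirical_pvalues(obs$log2, null$log2[!null$masked])
    q <- bh_fdr(p)
    mean(!is.na(q) & q < config$alpha)
  }, numeric(1))
  list(mean_fraction = mean(per_rep), per_rep = per_rep,
       n_bins = genome_len %/% config$bin_width, alpha = config$alpha)
}
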