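#' Genome configuration for the synthetic reference
#'
#' Describes the synthetic genome the package builds: a focal chromosome
#' carrying the DSB locus (an imperfect 11-bp target inverted repeat with two
#' mismatches and a 6-bp spacer inside a CAN1-like gene, a 5-bp
#' PAM-overlapping IR with a 35-bp spacer, alternate IRs telomeric and
#' centromeric to the target, delta and PAU repeat elements at their
#' characteristic distances from the centromere), a donor chromosome with a
#' homeologous gene (~61.6% identity), and optional ballast chromosomes that
#' keep total genome length stable under rearrangement.
#'
#' All coordinates are 0-based half-open.
#'
#' @param chr_v_len Length (bp) of the focal chromosome.
#' @param donor_len Length (bp) of the donor chromosome.
#' @param ballast_lens Integer vector of ballast chromosome lengths (bp); use
#'   `integer(0)` (or `compact = TRUE`) for a minimal two-chromosome genome.
#' @param compact If `TRUE`, drop ballast chromosomes.
#' @param target_ir List with `arm_len`, `mismatches`, `spacer` (bp) for the
#'   target inverted repeat.
#' @param pam_ir List with `arm_len`, `spacer` (bp) for the PAM-overlapping IR.
#' @param homeolog_identity Target global-alignment identity between the
#'   CAN1-like gene and its donor homeolog (fraction).
#' @param homeolog_sub_rate Per-base substitution rate used to generate the
#'   homeolog (calibrated so alignment identity lands on `homeolog_identity`).
#' @param telomere_seed Telomeric repeat unit appended by de novo telomere
#'   addition and used to seed chromosome ends.
#' @param ho_site If `TRUE`, replace the gRNA-17 protospacer with a 36-bp HO
#'   cleavage site whose cut point is 20 bp from the target IR.
#' @param seed RNG seed; the same config and seed give byte-identical genomes.
#' @return An object of class `genome_config`.
#' @export
genome_config <- function(chr_v_len = 200000L,
                          donor_len = 100000L,
                          ballast_lens = c(500000L, 400000L),
                          compact = FALSE,
                          target_ir = list(arm_len = 11L, mismatches = 2L, spacer = 6L),
                          pam_ir = list(arm_len = 5L, spacer = 35L),
                          homeolog_identity = 0.616,
                          homeolog_sub_rate = 0.425,
                          telomere_seed = "TGTGGGTGTGGTG",
                          ho_site = FALSE,
                          seed = 1L) {
  if (compact) ballast_lens <- integer(0)
  cfg <- list(
    chr_v_len = as.integer(chr_v_len),
    donor_len = as.integer(donor_len),
    ballast_lens = as.integer(ballast_lens),
    target_ir = target_ir,
    pam_ir = pam_ir,
    ## fixed locus geometry on the focal chromosome (0-based)
    ir_start = 40000L,            # left edge of the target IR's telomeric arm
    gene = c(39500L, 41000L),     # CAN1-like gene, also the conversion tract
    cen_v = 150000L,              # centromere start on the focal chromosome
    cen_len = 120L,
    delta_cluster_cen_offset = 14000L,  # cluster of delta elements, ~14 kb from CEN
    delta_short_cen_offset = 50000L,    # single short (174 bp) delta, 50 kb from CEN
    delta_len = 330L,
    delta_short_len = 174L,
    pau_len = 350L,
    pau_copies = 21L,
    trna_len = 75L,
    homeolog_identity = homeolog_identity,
    homeolog_sub_rate = homeolog_sub_rate,
    telomere_seed = telomere_seed,
    telomere_len = 300L,
    essential_boundary = 41000L,
    ho_site = isTRUE(ho_site),
    ho_len = 36L,
    ho_cut_offset = 18L,
    seed = as.integer(seed)
  )
  validate_genome_config(cfg)
  structure(cfg, class = "genome_config")
}

validate_genome_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      chr_v_len > cen_v + cen_len + 10000L,
      donor_len >= 60000L,
      target_ir$arm_len > 0, target_ir$mismatches >= 0, target_ir$spacer >= 0,
      pam_ir$arm_len > 0, pam_ir$spacer >= 0,
      homeolog_sub_rate >= 0, homeolog_sub_rate < 1,
      nchar(telomere_seed) >= 6
    )
  })
  invisible(cfg)
}

#' Foldback event-engine parameters
#'
#' Governs the mechanistic rearrangement simulator: which repair outcome each
#' survivor takes, which inverted repeat primes the foldback, where the
#' dicentric breaks, and how the broken chromosome is stabilized.
#'
#' @param event_weights Named numeric weights over primary repair outcomes
#'   (`foldback`, `nhej`, `homeologous_gc`, `interstitial_deletion`,
#'   `telomere_addition`, `cas9_inactivated`); normalized internally.
#' @param ir_lambda Decay length (nt) of the IR-choice weight
#'   `exp(-flap / ir_lambda)`; foldback frequency falls with DSB-to-IR
#'   distance but the functional form is a modeling choice.
#' @param max_flap Maximum heterologous flap length (nt) an IR may require.
#' @param ir_candidates Optional character vector of IR ids eligible for
#'   foldback priming (default: all catalog IRs on the cut chromosome).
#' @param correct_mismatches If `TRUE` (default), foldback events correct arm
#'   mismatches toward the centromere-proximal arm, yielding a perfect
#'   palindromic duplication.
#' @param break_window Offsets (bp) from the retained centromere, toward the
#'   palindrome center, within which the dicentric breaks. Default 5-30 kb;
#'   the narrower classic 25-30 kb window is available as
#'   `break_window = c(25000, 30000)`.
#' @param stabilization_weights Named weights over `repeat_translocation`,
#'   `centromere_deletion`, `telomere_addition`.
#' @param element_choice `"nearest"` picks the repeat element closest to the
#'   break for translocation; `"random"` samples uniformly among available
#'   elements (with matching donor copies).
#' @param cen_del_flank_range Range (bp) from which centromere-deletion flank
#'   lengths are drawn log-uniformly (clamped to valid geometry).
#' @param refold_prob Probability that a broken dicentric, instead of being
#'   stabilized directly, primes a second foldback at an inverted repeat
#'   near the broken end — the route to triplications/quadruplications.
#'   Off by default.
#' @param seed RNG seed for the event engine.
#' @return An object of class `foldback_params`.
#' @export
foldback_params <- function(event_weights = c(foldback = 1),
                            ir_lambda = 10,
                            max_flap = 600,
                            ir_candidates = NULL,
                            correct_mismatches = TRUE,
                            break_window = c(5000, 30000),
                            stabilization_weights = c(repeat_translocation = 0.5,
                                                      centromere_deletion = 0.2,
                                                      telomere_addition = 0.3),
                            element_choice = c("nearest", "random"),
                            cen_del_flank_range = c(1000, 150000),
                            refold_prob = 0,
                            seed = 1L) {
  element_choice <- match.arg(element_choice)
  kinds <- c("foldback", "nhej", "homeologous_gc", "interstitial_deletion",
             "telomere_addition", "cas9_inactivated")
  if (is.null(names(event_weights)) || !all(names(event_weights) %in% kinds)) {
    stopf("event_weights must be named with a subset of: %s",
          paste(kinds, collapse = ", "))
  }
  if (any(event_weights < 0) || sum(event_weights) <= 0) {
    stopf("event_weights must be non-negative with positive sum")
  }
  if (any(stabilization_weights < 0) || sum(stabilization_weights) <= 0) {
    stopf("stabilization_weights must be non-negative with positive sum")
  }
  stopifnot(length(break_window) == 2, break_window[1] <= break_window[2],
            break_window[1] >= 0,
            length(cen_del_flank_range) == 2,
            cen_del_flank_range[1] > 0,
            cen_del_flank_range[1] <= cen_del_flank_range[2],
            ir_lambda > 0, max_flap >= 0,
            refold_prob >= 0, refold_prob <= 1)
  structure(list(
    event_weights = event_weights / sum(event_weights),
    ir_lambda = ir_lambda,
    max_flap = max_flap,
    ir_candidates = ir_candidates,
    correct_mismatches = isTRUE(correct_mismatches),
    break_window = break_window,
    stabilization_weights = stabilization_weights / sum(stabilization_weights),
    element_choice = element_choice,
    cen_del_flank_range = cen_del_flank_range,
    refold_prob = refold_prob,
    seed = as.integer(seed)
  ), class = "foldback_params")
}

#' Paired-end read simulation parameters
#'
#' @param depth Target mean depth (x coverage).
#' @param read_len Read length (nt).
#' @param frag_mean,frag_sd Fragment length mean and SD (nt); lengths are
#'   truncated-normal with minimum `read_len`.
#' @param error_rate Per-base substitution error rate in `[0, 1)`.
#' @param seed RNG seed.
#' @return An object of class `readsim_params`.
#' @export
readsim_params <- function(depth = 30,
                           read_len = 75L,
                           frag_mean = 300,
                           frag_sd = 30,
                           error_rate = 0,
                           seed = 1L) {
  stopifnot(depth >= 0, read_len > 0, read_len <= frag_mean,
            frag_sd >= 0, error_rate >= 0, error_rate < 1)
  structure(list(depth = depth, read_len = as.integer(read_len),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "readsim_params")
}

#' CNV-calling configuration
#'
#' Parameters of the binned log2 read-depth procedure: per-position depth is
#' normalized to total mapped reads, averaged in fixed windows, the
#' sample/parental ratio is offset by a pseudocount of 0.0625 before log2
#' transformation, per-bin p-values come from a split-parental empirical
#' null, and significance is controlled by Benjamini-Hochberg FDR at 0.001.
#'
#' @param bin_width Bin width (bp); 5000 by default, 1000 for fine tracks.
#' @param pseudocount Constant added to each ratio before log2 (0.0625).
#' @param alpha FDR significance threshold (0.001).
#' @param n_null_splits Number of random half-splits of the parental reads
#'   pooled into the empirical null.
#' @param pool `"genome"` pools null values genome-wide (default);
#'   `"chromosome"` pools per chromosome.
#' @param min_bin_fraction Terminal partial bins are kept iff their width is
#'   at least this fraction of `bin_width`.
#' @param seed RNG seed for the null splits.
#' @return An object of class `cnv_config`.
#' @export
cnv_config <- function(bin_width = 5000L,
                       pseudocount = 0.0625,
                       alpha = 0.001,
                       n_null_splits = 10L,
                       pool = c("genome", "chromosome"),
                       min_bin_fraction = 0.5,
                       seed = 1L) {
  pool <- match.arg(pool)
  stopifnot(bin_width > 0, pseudocount > 0, alpha > 0, alpha < 1,
            n_null_splits >= 1, min_bin_fraction >= 0, min_bin_fraction <= 1)
  structure(list(bin_width = as.integer(bin_width), pseudocount = pseudocount,
                 alpha = alpha, n_null_splits = as.integer(n_null_splits),
                 pool = pool, min_bin_fraction = min_bin_fraction,
                 seed = as.integer(seed)),
            class = "cnv_config")
}

#' Survivor-screening configuration
#'
#' @param gain_threshold qPCR copy-number ratio at or above which a clone is
#'   scored as carrying a duplication (the clusters sit near 1 and 2; 1.5
#'   splits them).
#' @param e_target,e_ref Primer efficiencies for the duplication-region and
#'   reference amplicons, in `(1, 2]`.
#' @param cq_noise_sd SD of normal noise added to each simulated Cq replicate.
#' @param max_product Maximum in-silico PCR product length (bp).
#' @param seed RNG seed for simulated screens.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(gain_threshold = 1.5,
                          e_target = 2.0,
                          e_ref = 2.0,
                          cq_noise_sd = 0,
                          max_product = 5000L,
                          seed = 1L) {
  stopifnot(gain_threshold > 1,
            e_target > 1, e_target <= 2, e_ref > 1, e_ref <= 2,
            cq_noise_sd >= 0, max_product > 0)
  structure(list(gain_threshold = gain_threshold, e_target = e_target,
                 e_ref = e_ref, cq_noise_sd = cq_noise_sd,
                 max_product = as.integer(max_product), seed = as.integer(seed)),
            class = "screen_config")
}

#' Whole-pipeline configuration
#'
#' Bundles all stage configurations; one global seed deterministically
#' derives every stage seed via [derive_seed()].
#'
#' @param genome [genome_config()].
#' @param foldback [foldback_params()].
#' @param reads [readsim_params()].
#' @param cnv [cnv_config()].
#' @param screen [screen_config()].
#' @param n_clones Number of survivors to simulate.
#' @param seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome = genome_config(),
                            foldback = foldback_params(),
                            reads = readsim_params(),
                            cnv = cnv_config(),
                            screen = screen_config(),
                            n_clones = 10L,
                            seed = 1L) {
  seed <- as.integer(seed)
  genome$seed <- derive_seed(seed, "genome")
  foldback$seed <- derive_seed(seed, "events")
  reads$seed <- derive_seed(seed, "reads")
  cnv$seed <- derive_seed(seed, "cnv")
  screen$seed <- derive_seed(seed, "screen")
  structure(list(genome = genome, foldback = foldback, reads = reads,
                 cnv = cnv, screen = screen,
                 n_clones = as.integer(n_clones), seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys match the arguments
#'   of the stage constructors (`genome`, `foldback`, `reads`, `cnv`,
#'   `screen`, `n_clones`, `seed`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$genome)) args$genome <- do.call(genome_config, y$genome)
  if (!is.null(y$foldback)) {
    fb <- y$foldback
    for (f in c("event_weights", "stabilization_weights")) {
      if (!is.null(fb[[f]])) fb[[f]] <- unlist(fb[[f]])
    }
    for (f in c("break_window", "cen_del_flank_range")) {
      if (!is.null(fb[[f]])) fb[[f]] <- as.numeric(unlist(fb[[f]]))
    }
    args$foldback <- do.call(foldback_params, fb)
  }
  if (!is.null(y$reads)) args$reads <- do.call(readsim_params, y$reads)
  if (!is.null(y$cnv)) args$cnv <- do.call(cnv_config, y$cnv)
  if (!is.null(y$screen)) args$screen <- do.call(screen_config, y$screen)
  if (!is.null(y$n_clones)) args$n_clones <- y$n_clones
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  }
  y <- list(
    genome = list(chr_v_len = config$genome$chr_v_len,
                  donor_len = config$genome$donor_len,
                  ballast_lens = config$genome$ballast_lens,
                  ho_site = config$genome$ho_site,
                  seed = config$genome$seed),
    foldback = strip(config$foldback),
    reads = strip(config$reads),
    cnv = strip(config$cnv),
    screen = strip(config$screen),
    n_clones = config$n_clones,
    seed = config$seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
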