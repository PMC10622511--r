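#' In-silico PCR for one primer pair
#'
#' A product is reported for every pair of exact, convergent primer binding
#' sites (one primer annealing to each strand) separated by at most
#' `max_product` bp; all qualifying site pairs are enumerated, so a
#' duplicated locus yields multiple products.
#'
#' @param genome Named character vector of chromosome sequences (or a
#'   `reference_model` / `derivative_genome`).
#' @param fwd,rev Primer sequences (>= 15 nt, A/C/G/T only).
#' @param max_product Maximum product length (bp).
#' @return A tibble of products: `chrom`, `start`, `end`, `length`,
#'   `orientation` (which primer served as the forward primer).
#' @export
insilico_pcr <- function(genome, fwd, rev, max_product = 5000L) {
  seqs <- if (is.character(genome)) genome else genome$seq
  if (nchar(fwd) < 15 || nchar(rev) < 15) stopf("primers must be >= 15 nt")
  if (grepl("[^ACGTacgt]", paste0(fwd, rev))) {
    stopf("degenerate or non-ACGT primer bases are not supported")
  }
  out <- list()
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    combos <- list(c(fwd, rev, "fwd/rev"), c(rev, fwd, "rev/fwd"))
    for (cb in combos) {
      p_f <- cb[1]; p_r <- cb[2]
      f_hits <- locate_motif(s, p_f)                 # primer on plus strand
      r_hits <- locate_motif(s, revcomp(p_r))        # primer on minus strand
      if (length(f_hits) == 0 || length(r_hits) == 0) next
      for (f in f_hits) {
        ends <- r_hits + nchar(p_r)
        ok <- r_hits >= f + nchar(p_f) & ends - f <= max_product
        for (e in ends[ok]) {
          out[[length(out) + 1L]] <- tibble(chrom = ch, start = f,
                                            end = as.integer(e),
                                            length = as.integer(e - f),
                                            orientation = cb[3])
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  length = integer(0), orientation = character(0)))
  }
  bind_rows(out) |> distinct(.data$chrom, .data$start, .data$end,
                             .keep_all = TRUE) |>
    arrange(.data$chrom, .data$start)
}

#' Run the full diagnostic PCR panel on a genome
#'
#' @param genome A genome (see [insilico_pcr()]).
#' @param model A `reference_model` supplying the primer catalog.
#' @param max_product Maximum product length (bp).
#' @return A tibble with one row per primer pair: `pair`, `present`,
#'   `n_products`, `product_length` (first product).
#' @export
pcr_screen <- function(genome, model, max_product = 5000L) {
  purrr::pmap(model$primers, function(pair, fwd_seq, rev_seq, ...) {
    prod <- insilico_pcr(genome, fwd_seq, rev_seq, max_product)
    tibble(pair = pair, present = nrow(prod) > 0,
           n_products = nrow(prod),
           product_length = if (nrow(prod) > 0) prod$length[1] else NA_integer_)
  }) |> bind_rows()
}

#' Efficiency-corrected qPCR copy number
#'
#' Relative copy number of the target amplicon versus a reference amplicon,
#' each normalized to a parental control:
#' `E_target^dCq_target(P-S) / E_ref^dCq_ref(P-S)`, where `dCq(P-S)` is the
#' mean parental Cq minus the mean sample Cq of the triplicates. Equals 1
#' when nothing changed. A triplicate-propagated spread is attached as the
#' `spread` attribute.
#'
#' @param cq_target_sample,cq_target_parental Numeric Cq triplicates for the
#'   duplication-region amplicon.
#' @param cq_ref_sample,cq_ref_parental Numeric Cq triplicates for the
#'   reference amplicon.
#' @param e_target,e_ref Primer efficiencies in `(1, 2]`.
#' @return Copy number (fold change vs parental), with attribute `spread`.
#' @export
qpcr_copy_number <- function(cq_target_sample, cq_target_parental,
                             cq_ref_sample, cq_ref_parental,
                             e_target = 2.0, e_ref = 2.0) {
  if (length(cq_target_parental) == 0 || length(cq_ref_parental) == 0 ||
      anyNA(cq_target_parental) || anyNA(cq_ref_parental)) {
    stopf("parental control Cq values are required for normalization")
  }
  stopifnot(e_target > 1, e_target <= 2, e_ref > 1, e_ref <= 2)
  d_t <- mean(cq_target_parental) - mean(cq_target_sample)
  d_r <- mean(cq_ref_parental) - mean(cq_ref_sample)
  cn <- e_target^d_t / e_ref^d_r
  ## per-replicate copy numbers give the spread
  n <- min(length(cq_target_sample), length(cq_ref_sample))
  reps <- vapply(seq_len(n), function(i) {
    e_target^(mean(cq_target_parental) - cq_target_sample[i]) /
      e_ref^(mean(cq_ref_parental) - cq_ref_sample[i])
  }, numeric(1))
  attr(cn, "spread") <- if (n > 1) sd(reps) else NA_real_
  cn
}

#' Survival frequency from plating counts
#'
#' `(colonies on inducing medium x fold dilution) / (colonies on plain
#' medium x fold dilution)`. Colonies attributable to inactivation of the
#' nuclease cassette are excluded from the inducing-plate count before the
#' ratio is formed.
#'
#' @param colonies_induced,colonies_plain Colony counts.
#' @param dilution_induced,dilution_plain Fold dilutions (>= 1).
#' @param excluded_induced Colonies on the inducing plate excluded as
#'   cassette-inactivated.
#' @return Survival frequency (fraction).
#' @export
survival_frequency <- function(colonies_induced, dilution_induced,
                               colonies_plain, dilution_plain,
                               excluded_induced = 0) {
  stopifnot(colonies_induced >= 0, colonies_plain >= 0,
            dilution_induced >= 1, dilution_plain >= 1,
            excluded_induced >= 0, excluded_induced <= colonies_induced)
  if (colonies_plain == 0) stopf("zero colonies on the non-inducing plate")
  ((colonies_induced - excluded_induced) * dilution_induced) /
    (colonies_plain * dilution_plain)
}

#' Classify one survivor from screening evidence
#'
#' The decision tree over the PCR panel and qPCR copy number:
#' cassette-inactivated clones are excluded upstream; a P3/P4 product means
#' NHEJ; otherwise P1/P2 plus a P7/P8 (donor-diagnostic) product means
#' homeologous gene conversion; otherwise a copy number at or above the gain
#' threshold means an inverted duplication, sub-classified by the
#' P11/P12 x P13/P14 table (negative/positive = target IR, both positive =
#' IR telomeric to the target, both negative = IR centromeric to the
#' target); anything else is terminal sequence loss (interstitial deletion
#' or telomere addition).
#'
#' @param pcr A [pcr_screen()] tibble (needs pairs `control`, `P1/P2`,
#'   `P3/P4`, `P7/P8`, `P11/P12`, `P13/P14`).
#' @param copy_number qPCR copy number from [qpcr_copy_number()].
#' @param config A [screen_config()] (uses `gain_threshold`).
#' @param cassette_inverted `TRUE` when the upstream cassette-orientation
#'   screen showed the nuclease cassette inverted (no cutting).
#' @return A one-row tibble: `category`, `copy_number`, plus the evidence
#'   columns.
#' @export
classify_survivor <- function(pcr, copy_number, config = screen_config(),
                              cassette_inverted = FALSE) {
  pres <- setNames(pcr$present, pcr$pair)
  need <- c("control", "P1/P2", "P3/P4", "P7/P8", "P11/P12", "P13/P14")
  if (!all(need %in% names(pres))) {
    stopf("PCR panel is missing pairs: %s",
          paste(setdiff(need, names(pres)), collapse = ", "))
  }
  if (!pres[["control"]]) {
    stopf("control amplicon absent: invalid reaction, no call")
  }
  category <- if (isTRUE(cassette_inverted)) {
    "cas9_inactivated"
  } else if (pres[["P3/P4"]]) {
    "NHEJ"
  } else if (pres[["P1/P2"]] && pres[["P7/P8"]]) {
    "homeologous_GC"
  } else if (!is.na(copy_number) && copy_number >= config$gain_threshold) {
    if (!pres[["P11/P12"]] && pres[["P13/P14"]]) {
      "inverted_duplication_targetIR"
    } else if (pres[["P11/P12"]]) {
      "inverted_duplication_telomericIR"
    } else {
      "inverted_duplication_centromericIR"
    }
  } else {
    "terminal_loss_other"
  }
  tibble(category = category, copy_number = as.numeric(copy_number),
         p12 = pres[["P1/P2"]], p34 = pres[["P3/P4"]], p78 = pres[["P7/P8"]],
         p1112 = pres[["P11/P12"]], p1314 = pres[["P13/P14"]])
}

#' Simulate the full screening panel for a cohort
#'
#' Runs the in-silico PCR panel on each derivative genome, simulates
#' triplicate qPCR measurements (Cq values derived from the true amplicon
#' copy numbers with the configured efficiencies, plus normal Cq noise),
#' and records the cassette-orientation flag.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param model A `reference_model`.
#' @param config A [screen_config()].
#' @param seed RNG seed (defaults to the config seed).
#' @return A tibble, one row per clone: PCR presence columns, Cq
#'   triplicates, and `cassette_inverted`.
#' @export
simulate_screens <- function(cohort, model, config = screen_config(),
                             seed = config$seed) {
  set.seed(derive_seed(seed, "screens"))
  target <- model$primers[model$primers$pair == "P5/P6", ]
  refp <- model$primers[model$primers$pair == "qpcr_ref", ]
  cq_t0 <- 21; cq_r0 <- 19          # arbitrary parental quantification cycles
  rows <- map(seq_along(cohort$derivatives), function(k) {
    d <- cohort$derivatives[[k]]
    pcr <- pcr_screen(d, model, config$max_product)
    n_t <- max(nrow(insilico_pcr(d, target$fwd_seq, target$rev_seq,
                                 config$max_product)), 0L)
    n_r <- max(nrow(insilico_pcr(d, refp$fwd_seq, refp$rev_seq,
                                 config$max_product)), 0L)
    noise <- function(base) base + rnorm(3, 0, config$cq_noise_sd)
    ## more template -> proportionally lower Cq at the configured efficiency
    cq_ts <- noise(if (n_t > 0) cq_t0 - log(n_t) / log(config$e_target) else 40)
    cq_rs <- noise(if (n_r > 0) cq_r0 - log(n_r) / log(config$e_ref) else 40)
    tibble(clone_id = cohort$truth$clone_id[k],
           cassette_inverted = cohort$truth$event[k] == "cas9_inactivated",
           !!!setNames(as.list(pcr$present), pcr$pair),
           cq_target_s = list(cq_ts),
           cq_target_p = list(noise(cq_t0)),
           cq_ref_s = list(cq_rs),
           cq_ref_p = list(noise(cq_r0)))
  })
  bind_rows(rows)
}

#' Classify every clone in a screening table
#'
#' @param screens Output of [simulate_screens()] (or a table of the same
#'   shape).
#' @param config A [screen_config()].
#' @return A tibble with `clone_id`, `category`, `copy_number`, evidence
#'   columns.
#' @export
classify_cohort <- function(screens, config = screen_config()) {
  map(seq_len(nrow(screens)), function(k) {
    r <- screens[k, ]
    cn <- qpcr_copy_number(r$cq_target_s[[1]], r$cq_target_p[[1]],
                           r$cq_ref_s[[1]], r$cq_ref_p[[1]],
                           config$e_target, config$e_ref)
    pairs <- c("control", "P1/P2", "P3/P4", "P5/P6", "P7/P8", "P11/P12",
               "P13/P14", "qpcr_ref")
    pcr <- tibble(pair = pairs,
                  present = map_dbl(pairs, function(p) as.numeric(r[[p]])) > 0)
    classify_survivor(pcr, cn, config, r$cassette_inverted) |>
      mutate(clone_id = r$clone_id, .before = 1)
  }) |> bind_rows()
}

#' Map a truth event-log row to the expected screen category
#'
#' @param truth The truth tibble from [simulate_cohort()].
#' @return Character vector of expected categories.
#' @export
truth_category <- function(truth) {
  dplyr::case_when(
    truth$event == "nhej" ~ "NHEJ",
    truth$event == "homeologous_gc" ~ "homeologous_GC",
    truth$event == "cas9_inactivated" ~ "cas9_inactivated",
    truth$event %in% c("interstitial_deletion", "telomere_addition") ~
      "terminal_loss_other",
    truth$event == "foldback" & truth$ir_side == "target" ~
      "inverted_duplication_targetIR",
    truth$event == "foldback" & truth$ir_side == "telomeric" ~
      "inverted_duplication_telomericIR",
    truth$event == "foldback" & truth$ir_side == "centromeric" ~
      "inverted_duplication_centromericIR",
    TRUE ~ NA_character_
  )
}

#' Summarize survivor calls, optionally against truth
#'
#' Produces the category distribution, an optional cross-tabulation of IR
#' class by secondary-event repeat family (the survivor-table layout used
#' for cohort reporting), a confusion matrix against truth when truth is
#' supplied, and Fisher's exact tests for configured 2x2 contrasts.
#'
#' @param calls Classification tibble from [classify_cohort()] (optionally
#'   carrying `ir_side` / `secondary_family` columns from junction calls or
#'   truth).
#' @param truth Optional truth tibble from [simulate_cohort()].
#' @param contrasts Optional named list of 2x2 matrices to test with
#'   Fisher's exact test.
#' @return A list with `counts`, `ir_by_family` (or `NULL`), `confusion`
#'   (or `NULL`), `accuracy` (or `NA`), `fisher` (tibble or `NULL`).
#' @export
summarize_cohort <- function(calls, truth = NULL, contrasts = NULL) {
  if (nrow(calls) == 0) stopf("no calls to summarize")
  counts <- calls |> count(.data$category) |>
    mutate(fraction = .data$n / sum(.data$n))
  ir_by_family <- NULL
  if (all(c("ir_side", "secondary_family") %in% names(calls))) {
    ir_by_family <- calls |>
      filter(!is.na(.data$ir_side)) |>
      count(.data$ir_side, .data$secondary_family) |>
      tidyr::pivot_wider(names_from = "secondary_family", values_from = "n",
                         values_fill = 0L)
  }
  confusion <- NULL
  accuracy <- NA_real_
  if (!is.null(truth)) {
    expected <- tibble(clone_id = truth$clone_id,
                       expected = truth_category(truth))
    joined <- calls |> left_join(expected, by = "clone_id")
    confusion <- joined |> count(.data$expected, .data$category)
    accuracy <- mean(joined$category == joined$expected)
  }
  fisher <- NULL
  if (!is.null(contrasts)) {
    fisher <- imap(contrasts, function(m, nm) {
      tibble(contrast = nm, p = fisher_exact_2x2(m))
    }) |> bind_rows()
  }
  list(counts = counts, ir_by_family = ir_by_family,
       confusion = confusion, accuracy = accuracy, fisher = fisher)
}

#' Two-tailed t test between survival-frequency groups
#'
#' Comparison of survival frequencies between two sets of independent
#' cultures (delegates to [stats::t.test()], two-sided).
#'
#' @param freq_a,freq_b Numeric vectors of per-culture survival frequencies.
#' @return The two-sided p-value.
#' @export
survival_t_test <- function(freq_a, freq_b) {
  stopifnot(length(freq_a) >= 2, length(freq_b) >= 2)
  t.test(freq_a, freq_b, alternative = "two.sided")$p.value
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test (delegates to [stats::fisher.test()]).
#'
#' @param m A 2x2 matrix of counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(2, 2)), all(m >= 0))
  fisher.test(m)$p.value
}
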