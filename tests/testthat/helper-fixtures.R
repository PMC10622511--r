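## Shared fixtures, built once per test run and memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

## compact two-chromosome reference (focal + donor)
fb_model <- function() {
  memo("model_compact", build_reference(genome_config(compact = TRUE)))
}

## full default reference with ballast chromosomes
fb_model_full <- function() {
  memo("model_full", build_reference(genome_config()))
}

fb_chrom_lengths <- function(model) {
  setNames(model$chroms$length, model$chroms$chrom)
}

## mixed-event cohort used by several screening tests
fb_mixed_params <- function() {
  foldback_params(
    event_weights = c(foldback = 0.5, nhej = 0.15, homeologous_gc = 0.1,
                      interstitial_deletion = 0.1, telomere_addition = 0.1,
                      cas9_inactivated = 0.05),
    ir_candidates = c("IR_target", "IR_alt_tel", "IR_alt_cen"),
    ir_lambda = 200,
    stabilization_weights = c(repeat_translocation = 0.5,
                              centromere_deletion = 0.2,
                              telomere_addition = 0.3),
    element_choice = "random")
}

fb_mixed_cohort <- function() {
  memo("mixed_cohort",
       simulate_cohort(fb_model(), 40, fb_mixed_params(),
                       guide = "gRNA-48", seed = 11))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## ---------------------------------------------------------------------------
## Independent oracles
## ---------------------------------------------------------------------------

## brute-force inverted-repeat enumeration: for every (left-arm end, spacer)
## placement, the longest arm whose left arm matches the reverse complement
## of the right arm with at most max_mismatch substitutions and matching
## innermost/outermost positions
bf_find_irs <- function(seq, min_arm, max_spacer, max_mismatch) {
  L <- nchar(seq)
  comp <- function(x) chartr("ACGT", "TGCA", x)
  ch <- strsplit(seq, "")[[1]]
  rows <- list()
  for (i in seq_len(L)) {
    if (i < min_arm || i + min_arm > L) next
    for (g in 0:max_spacer) {
      j <- i + g
      if (j + min_arm > L) next
      kmax <- min(i, L - j)
      ## innermost positions must pair
      if (ch[i] != comp(ch[j + 1])) next
      best <- NA
      for (k in seq_len(kmax)) {
        left <- ch[(i - k + 1):i]
        right <- ch[(j + 1):(j + k)]
        mism <- sum(left != rev(comp(right)))
        outer_ok <- ch[i - k + 1] == comp(ch[j + k])
        if (mism <= max_mismatch && outer_ok) best <- k
      }
      if (!is.na(best) && best >= min_arm) {
        left <- ch[(i - best + 1):i]
        right <- ch[(j + 1):(j + best)]
        mm <- which(rev(left) != comp(right)) - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          left_start = i - best, left_end = i, right_start = j,
          right_end = j + best, arm_len = best, spacer_len = g,
          n_mismatch = length(mm))
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      arm_len = integer(0), spacer_len = integer(0),
                      n_mismatch = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$left_start, -out$arm_len, out$right_start), , drop = FALSE]
}

## closed-form Benjamini-Hochberg step-up: q(i) = min_{j >= i} p(j) * m / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) qs[i] <- min(qs[i], qs[i + 1])
  qs <- pmin(qs, 1)
  q <- numeric(m)
  q[o] <- qs
  q
}

## two-sided Fisher exact p by full hypergeometric enumeration over all
## tables with the observed margins
bf_fisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    dhyper(a, c1, n - c1, r1)
  }, numeric(1))
  p_obs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## rank-counting empirical p oracle
bf_empirical_p <- function(obs, null) {
  med <- stats::median(null)
  vapply(obs, function(x) {
    (1 + sum(abs(null - med) >= abs(x - med))) / (length(null) + 1)
  }, numeric(1))
}
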