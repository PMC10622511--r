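test_that("event-type sampling follows the configured distribution", {
  p1 <- foldback_params(event_weights = c(foldback = 1))
  set.seed(1)
  expect_true(all(sample_event_type(p1, 50) == "foldback"))

  p2 <- foldback_params(event_weights = c(foldback = 0.6, nhej = 0.4,
                                          homeologous_gc = 0))
  set.seed(2)
  draws <- sample_event_type(p2, 1e4)
  expect_false("homeologous_gc" %in% draws)
  ## empirical frequencies within 3 binomial SDs of the weights
  for (kind in c("foldback", "nhej")) {
    w <- p2$event_weights[[kind]]
    se <- sqrt(w * (1 - w) / 1e4)
    expect_lt(abs(mean(draws == kind) - w), 3 * se)
  }
  expect_error(foldback_params(event_weights = c(foldback = -1, nhej = 2)),
               "non-negative")
})

test_that("NHEJ edits are small, near the cut, and destroy the target", {
  m <- fb_model()
  cut <- locate_cut_site(m, "gRNA-17")
  L <- nchar(m$seq[["chrV"]])
  set.seed(33)
  for (k in 1:60) {
    d <- apply_nhej(m, cut)
    ev <- d$event
    ## length change equals the logged indel size
    delta <- nchar(d$seq[["chrV_der"]]) - L
    expected <- switch(ev$nhej_kind, insertion = ev$nhej_size,
                       deletion = -ev$nhej_size, substitution = 0L)
    expect_equal(delta, expected)
    expect_lte(abs(ev$nhej_pos - cut$cut), 2L)
    expect_false(has_protospacer(d, m, "gRNA-17"))
    expect_identical(replay_blocks(d$blocks[["chrV_der"]], m),
                     d$seq[["chrV_der"]])
  }
})

test_that("homeologous gene conversion swaps the tract and keeps the ends", {
  m <- fb_model()
  cut <- locate_cut_site(m, "gRNA-17")
  set.seed(34)
  d <- apply_homeologous_gc(m, cut)
  s <- d$seq[["chrV_der"]]
  expect_equal(nchar(s), nchar(m$seq[["chrV"]]))
  ## tract interior identical to the donor slice
  g <- m$genes
  don <- substr(m$seq[["chrXIV"]], g$start[g$gene == "LYP1_like"] + 1,
                g$end[g$gene == "LYP1_like"])
  expect_identical(substr(s, g$start[g$gene == "CAN1_like"] + 1,
                          g$end[g$gene == "CAN1_like"]), don)
  ## screening signature: P3/P4 lost, P1/P2 retained, P7/P8 gained
  pcr <- pcr_screen(d, m)
  expect_false(pcr$present[pcr$pair == "P3/P4"])
  expect_true(pcr$present[pcr$pair == "P1/P2"])
  expect_true(pcr$present[pcr$pair == "P7/P8"])
  expect_false(has_protospacer(d, m, "gRNA-17"))
})

test_that("foldback hairpin is the reference slice from the IR center", {
  m <- fb_model()
  cut <- locate_cut_site(m, "gRNA-17")
  tir <- m$irs[m$irs$class == "target", ]
  hp <- apply_foldback(m, cut, tir, foldback_params())
  L <- nchar(m$seq[["chrV"]])
  expect_identical(hp$seq, substr(m$seq[["chrV"]], tir$center + 1, L))

  ## correction off: the arm position carries the reverse complement of the
  ## telomeric (DSB-proximal) arm instead of the resident sequence
  hp0 <- apply_foldback(m, cut, tir,
                        foldback_params(correct_mismatches = FALSE))
  expect_equal(nchar(hp0$seq), nchar(hp$seq))
  arm_off <- tir$right_start - tir$center   # arm offset within the hairpin
  left <- substr(m$seq[["chrV"]], tir$left_start + 1, tir$left_end)
  expect_identical(substr(hp0$seq, arm_off + 1, arm_off + tir$arm_len),
                   revcomp(left))
  expect_false(identical(hp0$seq, hp$seq))

  ## a perfect IR has nothing to correct
  pam <- m$irs[m$irs$class == "pam", ]
  hp_p1 <- apply_foldback(m, cut, pam, foldback_params())
  hp_p2 <- apply_foldback(m, cut, pam,
                          foldback_params(correct_mismatches = FALSE))
  expect_identical(hp_p1$seq, hp_p2$seq)

  ## an IR centromeric to the essential boundary is lethal
  bad <- tir
  bad$center <- 50000L
  expect_error(apply_foldback(m, cut, bad, foldback_params()), "lethal")
})

test_that("dicentric replication is revcomp(S) + S with two centromeres", {
  set.seed(35)
  s <- random_seq(1000)
  dic <- replicate_to_dicentric(s)
  expect_equal(nchar(dic), 2000L)
  expect_identical(dic, paste0(revcomp(s), s))

  m <- fb_model()
  cut <- locate_cut_site(m, "gRNA-17")
  tir <- m$irs[m$irs$class == "target", ]
  hp <- apply_foldback(m, cut, tir, foldback_params())
  dic2 <- replicate_to_dicentric(hp, m)
  expect_identical(dic2$seq, paste0(revcomp(hp$seq), hp$seq))
  cens <- foldbackr:::find_centromeres(dic2$seq, m$cen_core)
  expect_equal(nrow(cens), 2L)
  expect_setequal(cens$strand, c("+", "-"))
  expect_identical(replay_blocks(dic2$blocks, m), dic2$seq)

  ## corrected foldback: perfect palindrome about the center over at least
  ## the arm span
  ctr <- dic2$center
  w <- 2L * (tir$arm_len + tir$spacer_len)
  lefts <- substr(dic2$seq, ctr - w + 1, ctr)
  rights <- substr(dic2$seq, ctr + 1, ctr + w)
  expect_identical(lefts, revcomp(rights))
})

test_that("dicentric breakage lands in the window and keeps one centromere", {
  m <- fb_model()
  cut <- locate_cut_site(m, "gRNA-17")
  tir <- m$irs[m$irs$class == "target", ]
  dic <- replicate_to_dicentric(apply_foldback(m, cut, tir, foldback_params()), m)

  ## zero-width window: deterministic offset
  p0 <- foldback_params(break_window = c(10000, 10000))
  set.seed(36)
  b1 <- break_dicentric(dic, m, p0)
  cens <- foldbackr:::find_centromeres(dic$seq, m$cen_core)
  off1 <- min(abs(b1$break_pos - cens$end[1]), abs(cens$start[2] - b1$break_pos))
  expect_equal(off1, 10000L)

  set.seed(37)
  p <- foldback_params(break_window = c(5000, 30000))
  offs <- numeric(100)
  for (k in 1:100) {
    b <- break_dicentric(dic, m, p)
    expect_equal(nrow(foldbackr:::find_centromeres(b$seq, m$cen_core)), 1L)
    offs[k] <- min(abs(b$break_pos - cens$end[1]),
                   abs(cens$start[2] - b$break_pos))
  }
  expect_true(all(offs >= 5000 & offs <= 30000))
  ## positions consistent with uniform over the window
  gof <- stats::chisq.test(table(cut(offs, breaks = seq(5000, 30000, length.out = 6))))
  expect_gt(gof$p.value, 0.01)

  ## window beyond the centromere-to-center span errors
  expect_error(break_dicentric(dic, m,
                               foldback_params(break_window = c(3e6, 4e6))),
               "window")
})

test_that("stabilization routes produce the advertised junction structures", {
  m <- fb_model()
  cut <- locate_cut_site(m, "gRNA-48")
  tir <- m$irs[m$irs$class == "target", ]
  params <- foldback_params()
  dic <- replicate_to_dicentric(apply_foldback(m, cut, tir, params), m)

  set.seed(38)
  broken <- break_dicentric(dic, m, params)

  ## repeat translocation: junction inside a repeat element on both sides
  tr <- stabilize(broken, "repeat_translocation", m, params)
  ev <- tr$event
  expect_equal(ev$stabilization, "repeat_translocation")
  elem <- m$repeats[m$repeats$id == ev$secondary_element, ]
  expect_true(ev$junction_pos >= elem$start && ev$junction_pos < elem$end)
  don <- m$repeats[m$repeats$chrom == ev$donor_chrom &
                   m$repeats$family == ev$secondary_family, ]
  expect_true(any(ev$donor_pos >= don$start & ev$donor_pos < don$end))
  expect_equal(foldbackr:::count_motif(tr$seq[["chrV_der"]], m$cen_core), 1)
  expect_identical(replay_blocks(tr$blocks[["chrV_der"]], m),
                   tr$seq[["chrV_der"]])

  ## telomere addition: the broken end is capped with telomere repeats
  ta <- stabilize(broken, "telomere_addition", m, params)
  s <- ta$seq[["chrV_der"]]
  expect_identical(substr(s, 1, 100),
                   revcomp(substr(strrep(m$telomere_seed, 10), 1, 100)))
  expect_equal(foldbackr:::count_motif(s, m$cen_core), 1)

  ## centromere deletion acts on the dicentric: one centromere left and a
  ## near-doubled chromosome
  set.seed(39)
  cd <- stabilize(dic, "centromere_deletion", m, params)
  scd <- cd$seq[["chrV_der"]]
  expect_equal(foldbackr:::count_motif(scd, m$cen_core), 1)
  evd <- cd$event
  expect_equal(nchar(scd),
               2L * nchar(substr(m$seq[["chrV"]], tir$center + 1,
                                 nchar(m$seq[["chrV"]]))) -
                 (evd$del_end - evd$del_start))
  fr <- params$cen_del_flank_range
  cens <- foldbackr:::find_centromeres(dic$seq, m$cen_core)
  del_span <- evd$del_end - evd$del_start
  expect_gte(del_span, 120)
  expect_lte(del_span, 2 * fr[2] + 120)
  expect_error(stabilize(broken, "centromere_deletion", m, params),
               "un-broken")
})

test_that("cohorts are deterministic, survivor-consistent and replayable", {
  m <- fb_model()
  params <- fb_mixed_params()
  co <- simulate_cohort(m, 25, params, guide = "gRNA-48", seed = 42)
  co2 <- simulate_cohort(m, 25, params, guide = "gRNA-48", seed = 42)
  expect_identical(co$truth, co2$truth)
  expect_identical(lapply(co$derivatives, `[[`, "seq"),
                   lapply(co2$derivatives, `[[`, "seq"))

  for (k in seq_along(co$derivatives)) {
    d <- co$derivatives[[k]]
    ev <- co$truth[k, ]
    ## survivor condition: no remaining protospacer except Cas9-off clones
    if (ev$event != "cas9_inactivated") {
      expect_false(has_protospacer(d, m, "gRNA-48"))
    } else {
      expect_true(has_protospacer(d, m, "gRNA-48"))
    }
    ## exactly one centromere in the rearranged chromosome
    der <- setdiff(names(d$seq), c("chrXIV"))[1]
    expect_equal(foldbackr:::count_motif(d$seq[[der]], m$cen_core), 1)
    ## byte-identical replay from the block map
    expect_identical(replay_blocks(d$blocks[[der]], m), d$seq[[der]])
  }

  ## foldback derivatives with correction on contain a perfect palindrome
  ## about the IR center of length >= 2 * arm_len
  fb <- which(co$truth$event == "foldback")
  for (k in fb) {
    d <- co$derivatives[[k]]
    ev <- co$truth[k, ]
    s <- d$seq[["chrV_der"]]
    ir <- m$irs[m$irs$id == ev$ir_id, ]
    pat <- substr(m$seq[["chrV"]], ir$center + 1, ir$center + 200)
    hit <- foldbackr:::locate_motif(s, pat)
    expect_equal(length(hit), 1L)
    ctr <- hit[1]   # derivative position of the palindrome center
    w <- 2L * ir$arm_len
    expect_identical(substr(s, ctr - w + 1, ctr),
                     revcomp(substr(s, ctr + 1, ctr + w)))
  }

  ## single-survivor degenerate cohort
  co1 <- simulate_cohort(m, 1, foldback_params(event_weights = c(foldback = 1)),
                         guide = "gRNA-48", seed = 5)
  expect_equal(nrow(co1$truth), 1L)
  expect_equal(co1$truth$event, "foldback")
  expect_false(is.na(co1$truth$stabilization))

  ## event-kind frequencies across a larger cohort match the weights
  big <- simulate_cohort(m, 400, params, guide = "gRNA-48", seed = 77)
  for (kind in names(params$event_weights)) {
    w <- params$event_weights[[kind]]
    se <- sqrt(w * (1 - w) / 400)
    expect_lt(abs(mean(big$truth$event == kind) - w), 3.5 * se + 1e-9)
  }
})

test_that("cohort export writes multi-FASTA plus a truth table", {
  m <- fb_model()
  co <- simulate_cohort(m, 2, foldback_params(event_weights = c(foldback = 1)),
                        guide = "gRNA-48", seed = 9)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "clone_001.fa"))
  expect_equal(sort(names(fa)), sort(names(co$derivatives[[1]]$seq)))
  tt <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  expect_equal(nrow(tt), 2L)
  expect_true(all(c("clone_id", "event", "ir_id", "stabilization") %in% names(tt)))
})

test_that("the optional refold mode yields complex higher-order duplications", {
  m <- fb_model()
  p <- foldback_params(refold_prob = 1,
                       stabilization_weights = c(telomere_addition = 1),
                       ir_candidates = "IR_target")
  set.seed(46)
  co <- simulate_cohort(m, 4, p, guide = "gRNA-48", seed = 46)
  complex <- which(co$truth$complex)
  expect_gt(length(complex), 0)
  for (k in complex) {
    d <- co$derivatives[[k]]
    ev <- co$truth[k, ]
    expect_equal(ev$n_foldbacks, 2L)
    s <- d$seq[["chrV_der"]]
    expect_equal(foldbackr:::count_motif(s, m$cen_core), 1)
    expect_false(has_protospacer(d, m, "gRNA-48"))
    expect_identical(replay_blocks(d$blocks[["chrV_der"]], m), s)
    ## triplication signature: some reference segment inside the first
    ## duplication appears at least three times in the derivative
    grid <- seq(ev$ir_center + 500L, 120000L, by = 5000L)
    copies <- vapply(grid, function(p) {
      probe <- substr(m$seq[["chrV"]], p + 1, p + 200)
      foldbackr:::count_motif(s, probe)
    }, numeric(1))
    expect_gte(max(copies), 3)
  }
  ## default-off: no complex events
  expect_false(any(fb_mixed_cohort()$truth$complex))
})
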