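test_that("reference construction is deterministic and embodies the locus design", {
  m <- fb_model()
  m2 <- build_reference(genome_config(compact = TRUE))
  expect_identical(m$seq, m2$seq)
  expect_identical(m$irs, m2$irs)

  ## target IR: 11-bp arms, 2 substitution mismatches, 6-bp spacer
  tir <- m$irs[m$irs$class == "target", ]
  expect_equal(tir$arm_len, 11L)
  expect_equal(tir$spacer_len, 6L)
  expect_equal(tir$n_mismatch, 2L)
  left <- substr(m$seq[["chrV"]], tir$left_start + 1, tir$left_end)
  right <- substr(m$seq[["chrV"]], tir$right_start + 1, tir$right_end)
  expect_equal(sum(strsplit(left, "")[[1]] !=
                   strsplit(revcomp(right), "")[[1]]), 2L)

  ## PAM-overlapping IR: 5-bp perfect arms, 35-bp spacer
  pam <- m$irs[m$irs$class == "pam", ]
  expect_equal(pam$arm_len, 5L)
  expect_equal(pam$spacer_len, 35L)
  expect_equal(pam$n_mismatch, 0L)

  ## one centromere per chromosome, sequence slice matches the core motif
  expect_equal(nrow(m$centromeres), length(m$seq))
  for (k in seq_len(nrow(m$centromeres))) {
    cen <- m$centromeres[k, ]
    expect_identical(substr(m$seq[[cen$chrom]], cen$start + 1, cen$end),
                     m$cen_core)
  }
})

test_that("repeat families have the expected sizes and placement", {
  m <- fb_model_full()
  deltas <- m$repeats[m$repeats$family == "delta" & m$repeats$chrom == "chrV", ]
  lens <- deltas$end - deltas$start
  expect_equal(sum(lens == 174L), 1L)
  expect_true(all(lens[lens != 174L] >= 300 & lens[lens != 174L] <= 360))
  ## delta cluster ~14 kb from the centromere, short delta 50 kb away
  cen <- m$centromeres[m$centromeres$chrom == "chrV", ]
  cl <- deltas[grepl("cluster", deltas$id), ]
  expect_true(all(abs(cen$start - cl$end - 14000) < 2000))
  short <- deltas[lens == 174L, ]
  expect_equal(cen$start - short$start, 50000L)

  ## ~21 PAU copies, high pairwise identity, subtelomeric placement mostly
  pau <- m$repeats[m$repeats$family == "PAU", ]
  expect_equal(nrow(pau), 21L)
  expect_true(all(pau$end - pau$start == 350L))
  d <- utils::adist(pau$seq[1], pau$seq[-1])
  expect_true(all(d / 350 < 0.1))
})

test_that("homeolog pair identity is near 61.6% by global alignment", {
  m <- fb_model_full()
  g <- m$genes
  nat <- substr(m$seq[["chrV"]], g$start[g$gene == "CAN1_like"] + 1,
                g$end[g$gene == "CAN1_like"])
  don <- substr(m$seq[["chrXIV"]], g$start[g$gene == "LYP1_like"] + 1,
                g$end[g$gene == "LYP1_like"])
  pid <- Biostrings::pid(Biostrings::pairwiseAlignment(nat, don, type = "global"))
  expect_lt(abs(pid - 61.6), 1)
})

test_that("cut-site location reproduces the guide geometry", {
  m <- fb_model()
  cs17 <- locate_cut_site(m, "gRNA-17")
  expect_equal(cs17$distance_to_target_ir, 20L)
  cs48 <- locate_cut_site(m, "gRNA-48")
  expect_equal(cs48$distance_to_target_ir, 51L)
  ## custom protospacer sequence resolves to the same cut
  g <- m$guides[m$guides$guide == "gRNA-17", ]
  expect_equal(locate_cut_site(m, g$seq)$cut, cs17$cut)
  ## ambiguous or absent sequences error
  expect_error(locate_cut_site(m, strrep("A", 20)), "matches")
  ## HO variant: designed cleavage point 20 bp from the IR
  mh <- build_reference(genome_config(compact = TRUE, ho_site = TRUE))
  csho <- locate_cut_site(mh, "HO")
  expect_equal(csho$source, "HO_site")
  expect_equal(csho$distance_to_target_ir, 20L)
})

test_that("flap length matches cut-to-arm geometry", {
  m <- fb_model()
  cs <- locate_cut_site(m, "gRNA-17")
  expect_equal(flap_length(cs, m$irs[m$irs$class == "target", ]), 20L)
  expect_equal(flap_length(cs, m$irs[m$irs$class == "pam", ]), 1L)
  ## flush cut
  tir <- m$irs[m$irs$class == "target", ]
  flush <- cs; flush$cut <- tir$left_start
  expect_equal(flap_length(flush, tir), 0L)
  ## cut centromeric to the IR is a geometry error
  inside <- cs; inside$cut <- tir$left_start + 5L
  expect_error(flap_length(inside, tir), "centromeric")
  ## consistency with locate_cut_site distance for the target IR
  cs48 <- locate_cut_site(m, "gRNA-48")
  expect_equal(flap_length(cs48, tir), cs48$distance_to_target_ir)
})

test_that("IR scanner finds designed repeats and nothing in poly-A", {
  expect_equal(nrow(find_inverted_repeats(strrep("A", 100), min_arm = 5)), 0L)

  ## constructed imperfect IR: 11-bp arm, 2 substitutions, 6-bp spacer
  set.seed(402)
  arm <- random_seq(11)
  spacer <- random_seq(6)
  right <- revcomp(arm)
  substr(right, 3, 3) <- if (substr(right, 3, 3) == "A") "C" else "A"
  substr(right, 9, 9) <- if (substr(right, 9, 9) == "A") "C" else "A"
  seqs <- paste0(random_seq(10), arm, spacer, right, random_seq(10))
  hits <- find_inverted_repeats(seqs, min_arm = 11, max_spacer = 6,
                                max_mismatch = 2)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$arm_len, 11L)
  expect_equal(hits$spacer_len, 6L)
  expect_equal(hits$n_mismatch, 2L)

  ## 5-bp perfect arms with a 35-bp spacer
  set.seed(403)
  arm5 <- "ACGTC"
  sp35 <- strrep("G", 35)
  s2 <- paste0(strrep("T", 12), arm5, sp35, revcomp(arm5), strrep("T", 12))
  hits2 <- find_inverted_repeats(s2, min_arm = 5, max_spacer = 35,
                                 max_mismatch = 0)
  hit5 <- hits2[hits2$arm_len == 5 & hits2$spacer_len == 35, ]
  expect_equal(nrow(hit5), 1L)
})

test_that("IR scanner agrees with brute-force enumeration", {
  set.seed(77)
  for (rep in 1:20) {
    L <- sample(60:300, 1)
    s <- random_seq(L)
    min_arm <- sample(4:6, 1)
    max_spacer <- sample(c(0, 5, 12), 1)
    max_mm <- sample(0:1, 1)
    got <- find_inverted_repeats(s, min_arm, max_spacer, max_mm)
    want <- bf_find_irs(s, min_arm, max_spacer, max_mm)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$left_start, want$left_start)
    expect_equal(got$arm_len, want$arm_len)
    expect_equal(got$spacer_len, want$spacer_len)
    expect_equal(got$n_mismatch, want$n_mismatch)
  }
})

test_that("every catalog IR is re-discovered by the scanner", {
  m <- fb_model()
  for (k in seq_len(nrow(m$irs))) {
    ir <- m$irs[k, ]
    win_lo <- ir$left_start - 10L
    win <- substr(m$seq[[ir$chrom]], win_lo + 1, ir$right_end + 10L)
    hits <- find_inverted_repeats(win, min_arm = ir$arm_len,
                                  max_spacer = ir$spacer_len,
                                  max_mismatch = ir$n_mismatch)
    found <- any(hits$left_start + win_lo <= ir$left_start &
                 hits$left_end + win_lo >= ir$left_end &
                 hits$right_start + win_lo <= ir$right_start &
                 hits$right_end + win_lo >= ir$right_end)
    expect_true(found, label = paste("IR", ir$id, "re-discovered"))
  }
})

test_that("restriction digest obeys the center-doubling rule", {
  expect_equal(center_fragment_rule(4000), 8000)

  ## no recognition site: one fragment, the whole molecule
  set.seed(88)
  s <- gsub("GAATTC", "GAATTA", random_seq(5000))
  expect_equal(predict_restriction_fragments(s, "GAATTC")$length, nchar(s))

  ## symmetric inverted duplication: site midpoint d from the center on
  ## each arm gives a 2d center fragment
  half <- gsub("GAATTC", "GAATTA", random_seq(6000))
  d <- 4000L
  site_start <- d - 3L   # site midpoint d bp from the junction at position 0
  substr(half, site_start + 1, site_start + 6) <- "GAATTC"
  der <- paste0(revcomp(half), half)
  frags <- predict_restriction_fragments(der, "GAATTC")
  center_frag <- frags[frags$start < nchar(half) & frags$end > nchar(half), ]
  expect_equal(center_frag$length, 2L * d)

  ## multiset equality with a direct string-splitting oracle, three enzymes
  set.seed(89)
  s3 <- random_seq(20000)
  sites <- c("GAATTC", "GGATCC", "AAGCTT")
  frags3 <- predict_restriction_fragments(s3, sites)
  cuts <- sort(unique(unlist(lapply(sites, function(z) {
    hits <- c(gregexpr(z, s3, fixed = TRUE)[[1]],
              gregexpr(revcomp(z), s3, fixed = TRUE)[[1]])
    hits <- hits[hits > 0]
    hits - 1L + nchar(z) %/% 2L
  }))))
  oracle <- diff(c(0L, cuts, nchar(s3)))
  expect_equal(sort(frags3$length), sort(oracle))
  expect_equal(sum(frags3$length), nchar(s3))
})

test_that("reference export round-trips as FASTA and BED", {
  m <- fb_model()
  dir <- withr::local_tempdir()
  paths <- write_reference(m, dir)
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_equal(sort(names(fa)), sort(names(m$seq)))
  expect_equal(as.character(fa[["chrV"]]), m$seq[["chrV"]])
  bed <- readr::read_tsv(paths[["bed"]], col_names = c("chrom", "start", "end", "name"),
                         show_col_types = FALSE)
  expect_true(all(bed$start < bed$end))
  expect_true(any(grepl("ir_target", bed$name)))
})
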