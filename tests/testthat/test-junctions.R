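mk_pair <- function(qname, c1, p1, s1, c2, p2, s2, len = 75L) {
  tibble::tibble(qname = qname, mate = c(1L, 2L), chrom = c(c1, c2),
                 pos = as.integer(c(p1, p2)), strand = c(s1, s2),
                 read_len = len, aln_len = len, clip5 = 0L, clip3 = 0L)
}

test_that("pair classification is exhaustive and matches the definitions", {
  aln <- dplyr::bind_rows(
    mk_pair("in_mu", "chr1", 1000, "+", "chr1", 1225, "-"),     # span = 300
    mk_pair("far", "chr1", 1000, "+", "chr1", 9000, "-"),       # too long
    mk_pair("outward", "chr1", 1225, "-", "chr1", 1000, "+"),
    mk_pair("inv", "chr1", 1000, "+", "chr1", 1200, "+"),
    mk_pair("inter", "chr1", 1000, "+", "chr2", 5000, "-"))
  ## outward pair: minus mate leftmost
  aln$pos[aln$qname == "outward"] <- c(1000L, 1225L)
  aln$strand[aln$qname == "outward"] <- c("-", "+")

  cls <- classify_pairs(pair_table(aln), list(mu = 300, sigma = 30))
  got <- setNames(cls$class, cls$qname)
  expect_equal(got[["in_mu"]], "concordant")
  expect_equal(got[["far"]], "distance_discordant")
  expect_equal(got[["outward"]], "distance_discordant")
  expect_equal(got[["inv"]], "inverted_same_strand")
  expect_equal(got[["inter"]], "interchromosomal")
  ## exhaustive partition
  expect_true(all(cls$class %in% c("concordant", "inverted_same_strand",
                                   "interchromosomal", "distance_discordant")))

  ## unpaired records are skipped with a count
  solo <- aln[1:9, ]
  pt <- pair_table(solo)
  expect_equal(nrow(pt), 4L)
  expect_equal(attr(pt, "n_unpaired"), 1L)
})

test_that("discordant clustering groups by proximity per class", {
  one <- classify_pairs(pair_table(
    mk_pair("a", "chr1", 1000, "+", "chr1", 1200, "+")),
    list(mu = 300, sigma = 30))
  cl1 <- cluster_discordant(one, window = 1000)
  expect_equal(nrow(cl1), 1L)
  expect_equal(cl1$support, 1L)

  two <- classify_pairs(pair_table(dplyr::bind_rows(
    mk_pair("a", "chr1", 1000, "+", "chr1", 1200, "+"),
    mk_pair("b", "chr1", 11000, "+", "chr1", 11200, "+"))),
    list(mu = 300, sigma = 30))
  cl2 <- cluster_discordant(two, window = 1000)
  expect_equal(nrow(cl2), 2L)

  near <- classify_pairs(pair_table(dplyr::bind_rows(
    mk_pair("a", "chr1", 1000, "+", "chr1", 1200, "+"),
    mk_pair("b", "chr1", 1400, "+", "chr1", 1500, "+"))),
    list(mu = 300, sigma = 30))
  cl3 <- cluster_discordant(near, window = 1000)
  expect_equal(nrow(cl3), 1L)
  expect_equal(cl3$support, 2L)
  expect_setequal(cl3$members[[1]], c("a", "b"))
})

test_that("boundary-read extraction respects the margin", {
  aln <- dplyr::bind_rows(
    mk_pair("at", "chr1", 5000, "+", "chr1", 5200, "+"),
    mk_pair("far", "chr1", 9000, "+", "chr1", 9200, "+"))
  pairs <- classify_pairs(pair_table(aln), list(mu = 300, sigma = 30))
  got0 <- extract_boundary_reads(aln, pairs, "chr1", 5000, 5275, margin = 0)
  expect_setequal(unique(got0$qname), "at")
  gotw <- extract_boundary_reads(aln, pairs, "chr1", 5000, 5275, margin = 5000)
  expect_setequal(unique(gotw$qname), c("at", "far"))
  ## a read two margins away stays excluded
  got1 <- extract_boundary_reads(aln, pairs, "chr1", 5000, 5275, margin = 1800)
  expect_setequal(unique(got1$qname), "at")
})

test_that("greedy overlap assembly merges and stays deterministic", {
  set.seed(71)
  src <- random_seq(130)
  r1 <- substr(src, 1, 75)
  r2 <- substr(src, 56, 130)      # exact 20-nt overlap
  out <- assemble_overlap(c(a = r1, b = r2), min_overlap = 15)
  expect_equal(nrow(out), 1L)
  expect_equal(out$length, 75L + 75L - 20L)
  expect_identical(out$contig, src)

  ## disjoint reads stay singletons
  out2 <- assemble_overlap(c(a = r1, b = revcomp(substr(random_seq(200), 1, 75))),
                           min_overlap = 15)
  expect_equal(nrow(out2), 2L)
  expect_equal(out2$n_reads, c(1L, 1L))

  ## reverse-complement overlaps merge too
  out3 <- assemble_overlap(c(a = r1, b = revcomp(r2)), min_overlap = 15)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$length, 130L)

  ## error-free reads tiling a junction: contig contains the truth sequence
  set.seed(72)
  jnc <- random_seq(600)
  starts <- seq(1, 525, by = 10)
  reads <- vapply(starts, function(s) substr(jnc, s, s + 74), character(1))
  names(reads) <- sprintf("t%03d", seq_along(reads))
  flip <- seq(2, length(reads), by = 3)
  reads[flip] <- revcomp(reads[flip])
  perm <- sample(seq_along(reads))
  out4 <- assemble_overlap(reads[perm], min_overlap = 15)
  expect_equal(nrow(out4), 1L)
  ## reads tile positions 1..595 of the junction; the contig reconstructs
  ## exactly that stretch (in either orientation)
  expect_equal(out4$length, 595L)
  expect_true(grepl(out4$contig, jnc, fixed = TRUE) ||
                grepl(revcomp(out4$contig), jnc, fixed = TRUE))

  ## identical input multiset in any order gives identical contigs
  out5 <- assemble_overlap(reads, min_overlap = 15)
  expect_setequal(out4$contig, out5$contig)
})

test_that("foldback-center finding recovers constructed and simulated centers", {
  m <- fb_model()
  ref <- m$seq
  ## constructed case: contig = revcomp(T) + T about a known position
  c0 <- 70000L
  T_ <- substr(ref[["chrV"]], c0 + 1, c0 + 400)
  contig <- paste0(revcomp(T_), T_)
  cc <- find_foldback_center(contig, ref)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$chrom, "chrV")
  expect_lte(abs(cc$center - c0), 5)
  expect_gte(cc$pal_len, 390)

  ## collinear contig: no center
  lin <- substr(ref[["chrV"]], 70001, 70600)
  expect_equal(nrow(find_foldback_center(lin, ref)), 0L)

  ## simulated corrected foldback at the target IR
  cut <- locate_cut_site(m, "gRNA-48")
  tir <- m$irs[m$irs$class == "target", ]
  hp <- apply_foldback(m, cut, tir, foldback_params())
  dic <- replicate_to_dicentric(hp, m)
  ctr <- dic$center
  contig2 <- substr(dic$seq, ctr - 350, ctr + 350)
  cc2 <- find_foldback_center(contig2, ref)
  expect_equal(nrow(cc2), 1L)
  expect_lte(abs(cc2$center - tir$center), tir$spacer_len %/% 2 + 1)
  ann <- annotate_ir_usage(cc2, m)
  expect_equal(ann$ir_id, "IR_target")
  expect_equal(ann$ir_class, "target")
  expect_true(ann$corrected)

  ## uncorrected foldback: center still found, corrected flag off
  hp0 <- apply_foldback(m, cut, tir, foldback_params(correct_mismatches = FALSE))
  dic0 <- replicate_to_dicentric(hp0, m)
  contig0 <- substr(dic0$seq, dic0$center - 350, dic0$center + 350)
  cc0 <- find_foldback_center(contig0, ref)
  expect_equal(nrow(cc0), 1L)
  expect_lte(abs(cc0$center - tir$center), tir$spacer_len %/% 2 + 2)
  expect_false(annotate_ir_usage(cc0, m)$corrected)
})

test_that("IR and repeat-family annotation follow the catalogs", {
  m <- fb_model()
  pam <- m$irs[m$irs$class == "pam", ]
  fake <- tibble::tibble(chrom = "chrV", center = pam$center, pal_len = 100L,
                         exact_gap = 0L)
  expect_equal(annotate_ir_usage(fake, m)$ir_class, "pam")

  ## far from any catalog IR: other, sided relative to the target
  far <- tibble::tibble(chrom = "chrV", center = 45000L, pal_len = 30L,
                        exact_gap = 0L)
  annf <- annotate_ir_usage(far, m)
  expect_equal(annf$ir_class, "other")
  expect_equal(annf$ir_side, "centromeric")

  delta <- m$repeats[m$repeats$id == "delta_cluster_1", ]
  expect_equal(annotate_secondary("chrV", delta$start + 50L, m)$family, "delta")
  pau <- m$repeats[m$repeats$id == "pau_v1", ]
  expect_equal(annotate_secondary("chrV", pau$start + 10L, m)$family, "PAU")
  expect_equal(annotate_secondary("chrV", 130000L, m)$family, "none")
})

test_that("per-clone junction calling recovers foldback and secondary events", {
  m <- fb_model()
  p <- foldback_params(stabilization_weights = c(repeat_translocation = 1),
                       ir_candidates = "IR_target")
  co <- simulate_cohort(m, 1, p, guide = "gRNA-48", seed = 31)
  d <- co$derivatives[[1]]
  sim <- simulate_reads(d, readsim_params(depth = 30), seed = 32)
  proj <- project_to_reference(sim, d, m)
  jc <- call_junctions(proj, m)
  fb <- jc[jc$kind == "foldback_center", ]
  expect_equal(nrow(fb), 1L)
  tir <- m$irs[m$irs$class == "target", ]
  expect_lte(abs(fb$center - tir$center), tir$spacer_len %/% 2 + 1)
  expect_true(fb$corrected)
  tr <- jc[jc$kind == "translocation", ]
  expect_gte(nrow(tr), 1L)
  expect_equal(unique(tr$family), co$truth$secondary_family)
})
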