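#' Build the synthetic reference genome
#'
#' Deterministically constructs the genome described by a [genome_config()]:
#' a focal chromosome with the DSB locus and its inverted-repeat
#' neighbourhood, repeat-element catalog and centromere; a donor chromosome
#' with the homeologous gene and family-matched repeat elements; and optional
#' ballast chromosomes. The same config and seed give byte-identical output.
#'
#' The focal locus layout (0-based, telomere at coordinate 0, centromere at
#' high coordinates) places the target IR's telomeric arm at `ir_start`, the
#' gRNA-17 protospacer so that its cut falls 20 bp telomeric of the IR, the
#' gRNA-48 protospacer so that its cut falls 51 bp from the IR, and a 5-bp
#' PAM-overlapping IR whose telomeric arm sits 1 bp from the gRNA-17 cut and
#' whose spacer straddles the target IR.
#'
#' @param config A [genome_config()].
#' @return An object of class `reference_model` with elements `seq` (named
#'   character vector of chromosome sequences), `chroms`, `centromeres`,
#'   `irs`, `repeats`, `primers`, `guides`, `genes` (tibbles), `cen_core`,
#'   `telomere_seed`, `essential_boundary`, and `config`.
#' @export
build_reference <- function(config = genome_config()) {
  set.seed(derive_seed(config$seed, "reference"))
  tel <- config$telomere_seed
  tel_block <- substr(strrep(tel, ceiling(config$telomere_len / nchar(tel))),
                      1, config$telomere_len)
  cen_core <- random_dna(config$cen_len)

  ## consensus sequences for the repeat families
  delta_cons <- random_dna(config$delta_len)
  pau_cons <- random_dna(config$pau_len)
  trna_cons <- random_dna(config$trna_len)

  new_chrom <- function(len) strsplit(random_dna(len), "")[[1]]
  write_seg <- function(chars, start, s) {
    chars[(start + 1):(start + nchar(s))] <- strsplit(s, "")[[1]]
    chars
  }
  add_telomeres <- function(chars) {
    chars <- write_seg(chars, 0L, revcomp(tel_block))
    write_seg(chars, length(chars) - nchar(tel_block), tel_block)
  }

  irs <- list(); repeats <- list(); cens <- list(); genes <- list()
  guides <- list(); primers <- list()

  ## ---- focal chromosome -------------------------------------------------
  v <- new_chrom(config$chr_v_len)
  v <- add_telomeres(v)
  cens[["chrV"]] <- tibble(chrom = "chrV", start = config$cen_v,
                           end = config$cen_v + config$cen_len)
  v <- write_seg(v, config$cen_v, cen_core)

  ## target IR: left (telomeric) arm, spacer, right (centromeric) arm
  al <- config$target_ir$arm_len
  sp <- config$target_ir$spacer
  nm <- config$target_ir$mismatches
  i0 <- config$ir_start
  left_arm <- random_dna(al)
  if (al >= 7) {
    ## bases whose complements later provide the PAM's GG (default geometry)
    substr(left_arm, 6, 7) <- "GG"
  }
  right_arm <- revcomp(left_arm)
  mm_off <- if (nm > 0) sort(sample(setdiff(seq_len(al) - 1L, c(4L, 5L)), nm)) else integer(0)
  if (nm > 0) right_arm <- substitute_bases(right_arm, mm_off + 1L)
  v <- write_seg(v, i0, left_arm)
  v <- write_seg(v, i0 + al + sp, right_arm)
  ir_row <- function(id, class, chrom, ls, le, rs, re, mm) {
    tibble(id = id, class = class, chrom = chrom,
           left_start = ls, left_end = le, right_start = rs, right_end = re,
           arm_len = le - ls, spacer_len = rs - le,
           n_mismatch = length(mm), mismatch_offsets = list(mm),
           center = (le + rs) %/% 2L)
  }
  irs[["target"]] <- ir_row("IR_target", "target", "chrV",
                            i0, i0 + al, i0 + al + sp, i0 + 2L * al + sp, mm_off)

  ## cut geometry: gRNA-17 cut 20 bp from the IR, gRNA-48 cut 51 bp from it
  ## (Cas9 cuts 3 bp from each protospacer's 3' end)
  cut17 <- i0 - 20L
  cut48 <- i0 - 51L

  if (config$ho_site) {
    ## HO variant: the gRNA-17 binding site is replaced by a 36-bp HO
    ## cleavage site whose designed cut point is also 20 bp from the IR.
    ## The overlapping PAM/alternate-telomeric IRs are not modeled here.
    ho_seq <- random_dna(config$ho_len)
    ho_start <- cut17 - config$ho_cut_offset
    v <- write_seg(v, ho_start, ho_seq)
    guides[["HO"]] <- tibble(guide = "HO", chrom = "chrV",
                             start = ho_start, end = ho_start + config$ho_len,
                             seq = ho_seq, source = "HO_site",
                             cut_offset = config$ho_cut_offset)
  } else {
    ## alternate IR telomeric to the target IR, centromeric to the gRNA-48
    ## cut (7-bp perfect arms, 12-bp spacer)
    at_ls <- cut48 + 6L
    at_arm <- random_dna(7L)
    v <- write_seg(v, at_ls, at_arm)
    v <- write_seg(v, at_ls + 7L + 12L, revcomp(at_arm))
    irs[["alt_tel"]] <- ir_row("IR_alt_tel", "other", "chrV",
                               at_ls, at_ls + 7L, at_ls + 19L, at_ls + 26L,
                               integer(0))

    ## PAM-overlapping IR: telomeric arm 1 bp from the gRNA-17 cut; its
    ## centromeric arm lies inside the target IR's centromeric arm, so the
    ## telomeric arm is the reverse complement of resident sequence (its
    ## GG provides the gRNA-17 PAM).
    pal <- config$pam_ir$arm_len
    psp <- config$pam_ir$spacer
    pa_start <- cut17 + 1L
    pb_start <- pa_start + pal + psp
    arm_b <- paste(v[(pb_start + 1):(pb_start + pal)], collapse = "")
    v <- write_seg(v, pa_start, revcomp(arm_b))
    irs[["pam"]] <- ir_row("IR_pam", "pam", "chrV",
                           pa_start, pa_start + pal, pb_start, pb_start + pal,
                           integer(0))
  }

  ## alternate IR centromeric to the target (8-bp perfect arms, 24-bp spacer)
  ac_ls <- i0 + 480L
  ac_arm <- random_dna(8L)
  v <- write_seg(v, ac_ls, ac_arm)
  v <- write_seg(v, ac_ls + 8L + 24L, revcomp(ac_arm))
  irs[["alt_cen"]] <- ir_row("IR_alt_cen", "other", "chrV",
                             ac_ls, ac_ls + 8L, ac_ls + 32L, ac_ls + 40L,
                             integer(0))

  ## PAM for the gRNA-48 protospacer
  v <- write_seg(v, cut48 + 4L, "GG")
  ## guides are read back from the finished locus (they may overlap IR arms)
  read_proto <- function(end3) {
    paste(v[(end3 - 20L + 1L):end3], collapse = "")
  }
  if (!config$ho_site) {
    guides[["gRNA-17"]] <- tibble(guide = "gRNA-17", chrom = "chrV",
                                  start = cut17 - 17L, end = cut17 + 3L,
                                  seq = read_proto(cut17 + 3L),
                                  source = "cas9_guide", cut_offset = NA_integer_)
  }
  guides[["gRNA-48"]] <- tibble(guide = "gRNA-48", chrom = "chrV",
                                start = cut48 - 17L, end = cut48 + 3L,
                                seq = read_proto(cut48 + 3L),
                                source = "cas9_guide", cut_offset = NA_integer_)

  ## repeat elements on the focal chromosome
  rep_row <- function(id, family, chrom, start, seqs) {
    tibble(id = id, family = family, chrom = chrom, start = start,
           end = start + nchar(seqs), strand = "+", seq = seqs)
  }
  cl_end <- config$cen_v - config$delta_cluster_cen_offset
  cl_starts <- cl_end - 410L - (2:0) * 380L   # three copies, 50 bp apart
  for (k in 1:3) {
    s <- mutate_seq(delta_cons, 0.03)
    v <- write_seg(v, cl_starts[k], s)
    repeats[[paste0("delta_cluster_", k)]] <-
      rep_row(paste0("delta_cluster_", k), "delta", "chrV", cl_starts[k], s)
  }
  ds_start <- config$cen_v - config$delta_short_cen_offset
  delta_short <- mutate_seq(substr(delta_cons, 1, config$delta_short_len), 0.03)
  v <- write_seg(v, ds_start, delta_short)
  repeats[["delta_short"]] <- rep_row("delta_short", "delta", "chrV",
                                      ds_start, delta_short)
  pau_v1 <- mutate_seq(pau_cons, 0.02)
  v <- write_seg(v, 61000L, pau_v1)
  repeats[["pau_v1"]] <- rep_row("pau_v1", "PAU", "chrV", 61000L, pau_v1)
  pau_v2 <- mutate_seq(pau_cons, 0.02)
  v <- write_seg(v, config$chr_v_len - 3000L, pau_v2)
  repeats[["pau_v2"]] <- rep_row("pau_v2", "PAU", "chrV",
                                 config$chr_v_len - 3000L, pau_v2)
  trna_v <- mutate_seq(trna_cons, 0.02)
  v <- write_seg(v, 80000L, trna_v)
  repeats[["trna_v"]] <- rep_row("trna_v", "tRNA", "chrV", 80000L, trna_v)

  genes[["native"]] <- tibble(gene = "CAN1_like", chrom = "chrV",
                              start = config$gene[1], end = config$gene[2])
  chrV_seq <- paste(v, collapse = "")

  ## ---- donor chromosome -------------------------------------------------
  d <- new_chrom(config$donor_len)
  d <- add_telomeres(d)
  cens[["chrXIV"]] <- tibble(chrom = "chrXIV", start = 5000L, end = 5000L + config$cen_len)
  d <- write_seg(d, 5000L, cen_core)
  native_gene <- slice0(chrV_seq, config$gene[1], config$gene[2])
  homeolog <- mutate_seq(native_gene, config$homeolog_sub_rate)
  d <- write_seg(d, 20000L, homeolog)
  genes[["donor"]] <- tibble(gene = "LYP1_like", chrom = "chrXIV",
                             start = 20000L, end = 20000L + nchar(homeolog))
  delta_d <- mutate_seq(delta_cons, 0.03)
  d <- write_seg(d, 60000L, delta_d)
  repeats[["delta_donor"]] <- rep_row("delta_donor", "delta", "chrXIV", 60000L, delta_d)
  pau_d <- mutate_seq(pau_cons, 0.02)
  d <- write_seg(d, 85000L, pau_d)
  repeats[["pau_donor"]] <- rep_row("pau_donor", "PAU", "chrXIV", 85000L, pau_d)
  n_extra <- max(0L, config$pau_copies - 3L)
  if (length(config$ballast_lens) == 0 && n_extra > 0) {
    ## compact genome: a reduced subtelomeric PAU array on the donor
    n_extra <- min(n_extra, 4L)
    for (k in seq_len(n_extra)) {
      s <- mutate_seq(pau_cons, 0.02)
      st <- config$donor_len - 8000L + (k - 1L) * 400L
      d <- write_seg(d, st, s)
      repeats[[paste0("pau_d", k)]] <- rep_row(paste0("pau_d", k), "PAU", "chrXIV", st, s)
    }
  }
  donor_seq <- paste(d, collapse = "")

  seqs <- c(chrV = chrV_seq, chrXIV = donor_seq)

  ## ---- ballast chromosomes ---------------------------------------------
  if (length(config$ballast_lens) > 0) {
    per <- ceiling(n_extra / length(config$ballast_lens))
    for (bi in seq_along(config$ballast_lens)) {
      bl <- config$ballast_lens[bi]
      nm_b <- paste0("chrB", bi)
      b <- new_chrom(bl)
      b <- add_telomeres(b)
      cstart <- as.integer(bl %/% 2)
      cens[[nm_b]] <- tibble(chrom = nm_b, start = cstart, end = cstart + config$cen_len)
      b <- write_seg(b, cstart, cen_core)
      n_here <- min(per, n_extra - (bi - 1L) * per)
      if (n_here > 0) {
        for (k in seq_len(n_here)) {
          s <- mutate_seq(pau_cons, 0.02)
          st <- 1000L + (k - 1L) * 400L
          b <- write_seg(b, st, s)
          id <- paste0("pau_b", bi, "_", k)
          repeats[[id]] <- rep_row(id, "PAU", nm_b, st, s)
        }
      }
      trna_b <- mutate_seq(trna_cons, 0.02)
      b <- write_seg(b, as.integer(bl %/% 3), trna_b)
      repeats[[paste0("trna_b", bi)]] <-
        rep_row(paste0("trna_b", bi), "tRNA", nm_b, as.integer(bl %/% 3), trna_b)
      seqs[nm_b] <- paste(b, collapse = "")
    }
  }

  ## ---- primer catalog ---------------------------------------------------
  fwd_primer <- function(chrom, start, len = 20L) {
    tibble(chrom = chrom, start = start, end = start + len,
           seq = slice0(seqs[[chrom]], start, start + len))
  }
  rev_primer <- function(chrom, start, len = 20L) {
    tibble(chrom = chrom, start = start, end = start + len,
           seq = revcomp(slice0(seqs[[chrom]], start, start + len)))
  }
  primer_pair <- function(name, fwd, rev) {
    tibble(pair = name,
           fwd_seq = fwd$seq, rev_seq = rev$seq, chrom = fwd$chrom,
           fwd_start = fwd$start, fwd_end = fwd$end,
           rev_start = rev$start, rev_end = rev$end)
  }
  primers <- bind_rows(
    primer_pair("P1/P2", fwd_primer("chrV", 10000L), rev_primer("chrV", 10480L)),
    primer_pair("P3/P4", fwd_primer("chrV", 39700L), rev_primer("chrV", 40190L)),
    primer_pair("P5/P6", fwd_primer("chrV", 60000L), rev_primer("chrV", 60480L)),
    ## P7 anchors the native flank; P8 matches donor-gene interior sequence
    ## so the pair amplifies only a homeologous conversion product.
    primer_pair("P7/P8", fwd_primer("chrV", 39300L),
                tibble(chrom = "chrV", start = 40190L, end = 40210L,
                       seq = revcomp(slice0(donor_seq, 20690L, 20710L)))),
    primer_pair("P11/P12",
                tibble(chrom = "chrV", start = 39976L, end = 39992L,
                       seq = slice0(chrV_seq, 39976L, 39992L)),
                rev_primer("chrV", 40040L)),
    primer_pair("P13/P14", fwd_primer("chrV", 40100L), rev_primer("chrV", 40260L)),
    primer_pair("control", fwd_primer("chrXIV", 40000L), rev_primer("chrXIV", 40300L)),
    primer_pair("qpcr_ref", fwd_primer("chrXIV", 50000L), rev_primer("chrXIV", 50180L))
  )

  model <- structure(list(
    seq = seqs,
    chroms = tibble(chrom = names(seqs), length = nchar(seqs)),
    centromeres = bind_rows(cens),
    cen_core = cen_core,
    telomere_seed = tel,
    irs = bind_rows(irs),
    repeats = bind_rows(repeats),
    primers = primers,
    guides = bind_rows(guides),
    genes = bind_rows(genes),
    essential_boundary = c(chrV = config$essential_boundary),
    config = config
  ), class = "reference_model")
  check_reference_model(model)
  model
}

## configuration sanity: no unplanned collisions among point features
check_reference_model <- function(model) {
  feats <- bind_rows(
    model$centromeres |> mutate(id = paste0("CEN_", .data$chrom)),
    model$repeats |> select("chrom", "start", "end", "id"),
    model$guides |> select("chrom", "start", "end", id = "guide")
  )
  feats <- feats |> arrange(.data$chrom, .data$start)
  by_chr <- split(feats, feats$chrom)
  for (f in by_chr) {
    if (nrow(f) < 2) next
    bad <- which(f$start[-1] < f$end[-nrow(f)])
    if (length(bad) > 0) {
      stopf("overlapping features on %s: %s and %s", f$chrom[bad[1]],
            f$id[bad[1]], f$id[bad[1] + 1])
    }
  }
  ## every feature's slice matches its declared content
  for (k in seq_len(nrow(model$repeats))) {
    r <- model$repeats[k, ]
    stopifnot(slice0(model$seq[[r$chrom]], r$start, r$end) == r$seq)
  }
  for (k in seq_len(nrow(model$irs))) {
    ir <- model$irs[k, ]
    left <- slice0(model$seq[[ir$chrom]], ir$left_start, ir$left_end)
    right <- slice0(model$seq[[ir$chrom]], ir$right_start, ir$right_end)
    mism <- sum(strsplit(left, "")[[1]] != strsplit(revcomp(right), "")[[1]])
    if (mism != ir$n_mismatch) {
      stopf("IR %s: %d arm mismatches, declared %d", ir$id, mism, ir$n_mismatch)
    }
  }
  invisible(model)
}

#' @export
print.reference_model <- function(x, ...) {
  cat("<reference_model>\n")
  cat("  chromosomes:",
      paste(sprintf("%s (%d bp)", x$chroms$chrom, x$chroms$length), collapse = ", "),
      "\n")
  cat("  IRs:", nrow(x$irs), " repeat elements:", nrow(x$repeats),
      " primer pairs:", nrow(x$primers), "\n")
  invisible(x)
}

#' Locate the DSB position for a guide or HO site
#'
#' For a Cas9 guide the cut is placed 3 bp from the protospacer's 3'
#' (PAM-proximal) end; for an HO site at the site's designed cleavage point.
#' Cut positions are between-base, 0-based.
#'
#' @param model A `reference_model`.
#' @param guide A guide name from the model's catalog (`"gRNA-17"`,
#'   `"gRNA-48"`, `"HO"`), or a protospacer sequence to search for.
#' @return A one-row tibble: `chrom`, `cut`, `source`, `guide`,
#'   `distance_to_target_ir`.
#' @export
locate_cut_site <- function(model, guide = "gRNA-17") {
  if (guide %in% model$guides$guide) {
    g <- model$guides[model$guides$guide == guide, ]
  } else {
    hits <- purrr::imap(model$seq, function(s, nm) {
      p <- c(locate_motif(s, guide), locate_motif(s, revcomp(guide)))
      if (length(p)) tibble(chrom = nm, start = p) else NULL
    }) |> bind_rows()
    if (nrow(hits) != 1) {
      stopf("guide sequence has %d genomic matches; need exactly 1", nrow(hits))
    }
    glen <- nchar(guide)
    g <- tibble(guide = "custom", chrom = hits$chrom, start = hits$start,
                end = hits$start + glen, source = "cas9_guide",
                cut_offset = NA_integer_)
  }
  cut <- if (g$source == "HO_site") g$start + g$cut_offset else g$end - 3L
  tir <- model$irs[model$irs$class == "target", ]
  dist <- if (nrow(tir) == 1 && tir$chrom == g$chrom) {
    ## gap from the cut to the nearest edge of the DSB-proximal arm
    if (cut <= tir$left_start) tir$left_start - cut else cut - tir$right_end
  } else NA_integer_
  tibble(chrom = g$chrom, cut = as.integer(cut), source = g$source,
         guide = g$guide, distance_to_target_ir = as.integer(dist))
}

#' Heterologous flap length for a cut/IR pair
#'
#' The number of unpaired 3' nucleotides between the DSB end and the
#' DSB-proximal edge of the annealed repeat arm.
#'
#' @param cut A cut-site tibble from [locate_cut_site()] (or a list with
#'   `chrom` and `cut`).
#' @param ir A one-row IR tibble (from a model's `irs` catalog or
#'   [find_inverted_repeats()] with a `chrom` column added).
#' @return Flap length in nt (>= 0).
#' @export
flap_length <- function(cut, ir) {
  if (!is.null(ir$chrom) && !is.null(cut$chrom) && cut$chrom != ir$chrom) {
    stopf("cut (%s) and IR (%s) are on different chromosomes", cut$chrom, ir$chrom)
  }
  fl <- ir$left_start - cut$cut
  if (fl < 0) {
    stopf("cut at %d is centromeric to the IR arm at %d", cut$cut, ir$left_start)
  }
  as.integer(fl)
}

#' Write the reference as FASTA and features as BED
#'
#' @param model A `reference_model`.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_reference <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(model$seq), fa)
  bed <- file.path(dir, "features.bed")
  feats <- bind_rows(
    model$centromeres |> mutate(name = paste0("centromere:CEN_", .data$chrom)),
    model$repeats |> transmute(.data$chrom, .data$start, .data$end,
                               name = paste0("repeat_", .data$family, ":", .data$id)),
    model$irs |> transmute(.data$chrom, start = .data$left_start,
                           end = .data$right_end,
                           name = paste0("ir_", .data$class, ":", .data$id)),
    model$guides |> transmute(.data$chrom, .data$start, .data$end,
                              name = paste0("guide:", .data$guide))
  ) |> arrange(.data$chrom, .data$start)
  readr::write_tsv(feats |> select("chrom", "start", "end", "name"),
                   bed, col_names = FALSE)
  invisible(c(fasta = fa, bed = bed))
}
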