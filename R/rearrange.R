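## ---------------------------------------------------------------------------
## Block maps: every derivative chromosome is described by an ordered set of
## blocks, each a slice of a reference chromosome (either strand) or a novel
## insertion. Blocks are the replay recipe for a derivative (and the ground
## truth for projecting read alignments back onto the reference).
## ---------------------------------------------------------------------------

block_tbl <- function(ref_chrom, ref_start, ref_end, strand, ins_seq = NA_character_) {
  len <- if_else(is.na(ref_chrom), nchar(ins_seq), ref_end - ref_start)
  d_end <- cumsum(len)
  tibble(d_start = d_end - len, d_end = d_end,
         ref_chrom = ref_chrom, ref_start = ref_start, ref_end = ref_end,
         strand = strand, ins_seq = ins_seq)
}

ins_block <- function(seq) {
  tibble(ref_chrom = NA_character_, ref_start = NA_integer_,
         ref_end = NA_integer_, strand = "+", ins_seq = seq)
}

ref_block <- function(chrom, start, end, strand = "+") {
  tibble(ref_chrom = chrom, ref_start = as.integer(start),
         ref_end = as.integer(end), strand = strand, ins_seq = NA_character_)
}

## recompute derivative coordinates after editing the block list
reindex_blocks <- function(blocks) {
  len <- if_else(is.na(blocks$ref_chrom), nchar(blocks$ins_seq),
                 blocks$ref_end - blocks$ref_start)
  blocks$d_end <- cumsum(len)
  blocks$d_start <- blocks$d_end - len
  blocks[len > 0, ]
}

## restrict a block map to derivative interval [s, e)
slice_blocks <- function(blocks, s, e) {
  keep <- blocks[blocks$d_end > s & blocks$d_start < e, ]
  for (k in seq_len(nrow(keep))) {
    b <- keep[k, ]
    trim_l <- max(0L, s - b$d_start)
    trim_r <- max(0L, b$d_end - e)
    if (trim_l == 0 && trim_r == 0) next
    if (is.na(b$ref_chrom)) {
      keep$ins_seq[k] <- substr(b$ins_seq, trim_l + 1, nchar(b$ins_seq) - trim_r)
    } else if (b$strand == "+") {
      keep$ref_start[k] <- b$ref_start + trim_l
      keep$ref_end[k] <- b$ref_end - trim_r
    } else {
      keep$ref_start[k] <- b$ref_start + trim_r
      keep$ref_end[k] <- b$ref_end - trim_l
    }
  }
  reindex_blocks(keep)
}

## reverse-complement a whole block map
flip_blocks <- function(blocks) {
  fl <- blocks[rev(seq_len(nrow(blocks))), ]
  fl$strand <- if_else(fl$strand == "+", "-", "+")
  has_ins <- !is.na(fl$ins_seq)
  if (any(has_ins)) fl$ins_seq[has_ins] <- revcomp(fl$ins_seq[has_ins])
  reindex_blocks(fl)
}

#' Rebuild a derivative sequence from its block map
#'
#' Replays a derivative chromosome from the reference plus the block map in
#' its event log; the result is byte-identical to the simulated sequence.
#'
#' @param blocks A block-map tibble (columns `ref_chrom`, `ref_start`,
#'   `ref_end`, `strand`, `ins_seq`).
#' @param model The `reference_model` the blocks refer to.
#' @return A single DNA string.
#' @export
replay_blocks <- function(blocks, model) {
  parts <- map_chr(seq_len(nrow(blocks)), function(k) {
    b <- blocks[k, ]
    if (is.na(b$ref_chrom)) return(b$ins_seq)
    s <- slice0(model$seq[[b$ref_chrom]], b$ref_start, b$ref_end)
    if (b$strand == "-") s <- revcomp(s)
    s
  })
  paste(parts, collapse = "")
}

## ---------------------------------------------------------------------------
## Event engine
## ---------------------------------------------------------------------------

#' Sample primary repair outcomes
#'
#' Draws survivor event kinds from the configured categorical distribution.
#'
#' @param params A [foldback_params()].
#' @param n Number of draws.
#' @return Character vector of event kinds.
#' @export
sample_event_type <- function(params, n = 1) {
  w <- params$event_weights
  if (any(w < 0)) stopf("negative event weights")
  sample(names(w), n, replace = TRUE, prob = w)
}

new_derivative <- function(seqs, blocks, event) {
  structure(list(seq = seqs, blocks = blocks, event = event),
            class = "derivative_genome")
}

#' @export
print.derivative_genome <- function(x, ...) {
  cat("<derivative_genome>", x$event$event[1], "\n")
  cat("  chromosomes:",
      paste(sprintf("%s (%d bp)", names(x$seq), nchar(x$seq)), collapse = ", "), "\n")
  invisible(x)
}

## identity block maps for the untouched chromosomes
identity_blocks <- function(model, except = "chrV") {
  other <- setdiff(names(model$seq), except)
  setNames(lapply(other, function(ch) {
    reindex_blocks(ref_block(ch, 0L, nchar(model$seq[[ch]])))
  }), other)
}

## assemble a derivative genome: rearranged focal chromosome + the rest
assemble_derivative <- function(model, der_blocks, der_seq, event,
                                der_name = "chrV_der") {
  blocks <- identity_blocks(model)
  seqs <- model$seq[names(blocks)]
  blocks[[der_name]] <- der_blocks
  seqs[der_name] <- der_seq
  ord <- c(der_name, setdiff(names(seqs), der_name))
  event$deriv_len <- nchar(der_seq)
  new_derivative(seqs[ord], blocks[ord], event)
}

base_event <- function(kind, cut = NULL) {
  tibble(event = kind,
         complex = FALSE, n_foldbacks = if (kind == "foldback") 1L else 0L,
         guide = cut$guide %||% NA_character_,
         cut_pos = cut$cut %||% NA_integer_,
         ir_id = NA_character_, ir_class = NA_character_,
         ir_side = NA_character_, ir_center = NA_integer_,
         ir_spacer = NA_integer_, corrected = NA,
         hairpin_len = NA_integer_, break_pos = NA_integer_,
         ref_break = NA_integer_, stabilization = NA_character_,
         junction_pos = NA_integer_, donor_chrom = NA_character_,
         donor_pos = NA_integer_, secondary_family = "none",
         secondary_element = NA_character_,
         dup_start = NA_integer_, dup_end = NA_integer_,
         del_start = NA_integer_, del_end = NA_integer_,
         deriv_len = NA_integer_)
}

#' Simulate an NHEJ survivor
#'
#' A small indel (1-10 nt) or substitution within 2 nt of the cut; the
#' product no longer matches the protospacer.
#'
#' @param model A `reference_model`.
#' @param cut A cut site from [locate_cut_site()].
#' @return A `derivative_genome`.
#' @export
apply_nhej <- function(model, cut) {
  L <- nchar(model$seq[[cut$chrom]])
  guide_seq <- model$guides$seq[model$guides$chrom == cut$chrom &
                                  vapply(model$guides$guide, function(g) {
                                    identical(g, cut$guide)
                                  }, logical(1))]
  ## an edit can by chance recreate the target (e.g. inserting the displaced
  ## base); like Cas9 re-cutting, retry until the target really is gone
  for (attempt in 1:25) {
    kind <- sample(c("insertion", "deletion", "substitution"), 1)
    offset <- sample(-2:2, 1)
    pos <- cut$cut + offset
    size <- sample(1:10, 1)
    if (kind == "insertion") {
      blocks <- bind_rows(ref_block(cut$chrom, 0L, pos),
                          ins_block(random_dna(size)),
                          ref_block(cut$chrom, pos, L))
    } else if (kind == "deletion") {
      blocks <- bind_rows(ref_block(cut$chrom, 0L, pos),
                          ref_block(cut$chrom, pos + size, L))
    } else {
      ## substitution: replace one base (within the protospacer) by another
      orig <- slice0(model$seq[[cut$chrom]], pos, pos + 1L)
      blocks <- bind_rows(ref_block(cut$chrom, 0L, pos),
                          ins_block(sample(setdiff(DNA_BASES, orig), 1)),
                          ref_block(cut$chrom, pos + 1L, L))
      size <- 1L
    }
    blocks <- reindex_blocks(blocks)
    seq <- replay_blocks(blocks, model)
    if (length(guide_seq) != 1 ||
        (length(locate_motif(seq, guide_seq)) +
         length(locate_motif(seq, revcomp(guide_seq)))) == 0) break
  }
  ev <- base_event("nhej", cut)
  ev$nhej_kind <- kind
  ev$nhej_size <- as.integer(size)
  ev$nhej_pos <- as.integer(pos)
  assemble_derivative(model, blocks, seq, ev)
}

#' Simulate a homeologous gene-conversion survivor
#'
#' The conversion tract (the CAN1-like gene) spanning the cut is replaced by
#' the donor homeolog; chromosome length is preserved and terminal sequences
#' retained.
#'
#' @inheritParams apply_nhej
#' @return A `derivative_genome`.
#' @export
apply_homeologous_gc <- function(model, cut) {
  donor <- model$genes[model$genes$gene == "LYP1_like", ]
  native <- model$genes[model$genes$gene == "CAN1_like", ]
  if (nrow(donor) == 0) stopf("no homeologous donor configured")
  L <- nchar(model$seq[[cut$chrom]])
  blocks <- reindex_blocks(bind_rows(
    ref_block(cut$chrom, 0L, native$start),
    ref_block(donor$chrom, donor$start, donor$end),
    ref_block(cut$chrom, native$end, L)
  ))
  seq <- replay_blocks(blocks, model)
  ev <- base_event("homeologous_gc", cut)
  ev$del_start <- native$start
  ev$del_end <- native$end
  assemble_derivative(model, blocks, seq, ev)
}

#' Foldback annealing: form a hairpin-capped chromosome
#'
#' Resection exposes the IR in single-stranded DNA; the 3' end anneals
#' intramolecularly at the IR (after trimming the heterologous flap) and
#' fill-in synthesis seals the end as a hairpin. The returned sequence is
#' the reference from the IR center to the centromere-bearing end. With
#' mismatch correction on (default) the annealed arm is corrected toward the
#' centromere-proximal copy, so subsequent replication yields a perfect
#' palindrome; with correction off the annealed (DSB-proximal) arm keeps its
#' original bases.
#'
#' @inheritParams apply_nhej
#' @param ir One row of the model's `irs` catalog (or a compatible tibble).
#' @param params A [foldback_params()].
#' @return An object of class `hairpin`: list with `seq`, `blocks`, `ir`,
#'   `corrected`, `cut`.
#' @export
apply_foldback <- function(model, cut, ir, params = foldback_params()) {
  fl <- flap_length(cut, ir)
  if (fl > params$max_flap) {
    stopf("flap of %d nt exceeds max_flap = %d", fl, params$max_flap)
  }
  bnd <- model$essential_boundary[[cut$chrom]] %||% NA_real_
  if (!is.na(bnd) && ir$center > bnd) {
    stopf("IR center at %d is centromeric to the essential boundary (%d): lethal",
          ir$center, as.integer(bnd))
  }
  L <- nchar(model$seq[[cut$chrom]])
  corrected <- params$correct_mismatches
  if (corrected || ir$n_mismatch == 0) {
    blocks <- ref_block(cut$chrom, ir$center, L)
  } else {
    ## uncorrected: the DSB-proximal (telomeric) arm's own bases occupy the
    ## annealed copy, i.e. the centromere-proximal arm position carries the
    ## reverse complement of the telomeric arm
    blocks <- bind_rows(
      ref_block(cut$chrom, ir$center, ir$right_start),
      ref_block(cut$chrom, ir$left_start, ir$left_end, strand = "-"),
      ref_block(cut$chrom, ir$right_end, L)
    )
  }
  blocks <- reindex_blocks(blocks)
  structure(list(seq = replay_blocks(blocks, model), blocks = blocks,
                 chrom = cut$chrom, ir = ir, corrected = corrected, cut = cut),
            class = "hairpin")
}

#' Replicate a hairpin-capped chromosome into a dicentric
#'
#' Replication through the hairpin cap doubles the molecule: the output is
#' `revcomp(S)` concatenated with `S`, a perfect palindrome about the former
#' cap, carrying two centromeres in inverted orientation.
#'
#' @param hairpin A `hairpin` object from [apply_foldback()], or a bare DNA
#'   string.
#' @param model The `reference_model` (needed only for block bookkeeping when
#'   a `hairpin` object is given).
#' @return For a bare string, the dicentric string. For a `hairpin`, an
#'   object of class `dicentric` (list with `seq`, `blocks`, `ir`,
#'   `corrected`, `center` = palindrome center offset).
#' @export
replicate_to_dicentric <- function(hairpin, model = NULL) {
  if (is.character(hairpin)) {
    return(paste0(revcomp(hairpin), hairpin))
  }
  blocks <- reindex_blocks(bind_rows(flip_blocks(hairpin$blocks), hairpin$blocks))
  seq <- paste0(revcomp(hairpin$seq), hairpin$seq)
  structure(list(seq = seq, blocks = blocks, chrom = hairpin$chrom,
                 ir = hairpin$ir, corrected = hairpin$corrected,
                 cut = hairpin$cut, center = nchar(hairpin$seq)),
            class = "dicentric")
}

## centromere copies of a dicentric, via motif search on both strands
find_centromeres <- function(seq, cen_core) {
  fwd <- locate_motif(seq, cen_core)
  rev <- locate_motif(seq, revcomp(cen_core))
  tibble(start = c(fwd, rev), strand = rep(c("+", "-"), c(length(fwd), length(rev)))) |>
    mutate(end = .data$start + nchar(cen_core)) |>
    arrange(.data$start)
}

#' Break a dicentric chromosome
#'
#' The anaphase bridge breaks within a configured window measured from one
#' (randomly chosen) centromere toward the palindrome center; the fragment
#' retaining that centromere is returned.
#'
#' @param dicentric A `dicentric` object from [replicate_to_dicentric()].
#' @param model The `reference_model`.
#' @param params A [foldback_params()] (uses `break_window`).
#' @return An object of class `broken_chromosome`: list with `seq`, `blocks`,
#'   `break_pos` (coordinate on the dicentric), `side` ("left"/"right"), and
#'   the dicentric's annotation fields.
#' @export
break_dicentric <- function(dicentric, model, params = foldback_params()) {
  cens <- find_centromeres(dicentric$seq, model$cen_core)
  if (nrow(cens) != 2) {
    stopf("dicentric must carry exactly 2 centromeres, found %d", nrow(cens))
  }
  ctr <- dicentric$center
  w <- as.integer(params$break_window)
  pick <- sample(1:2, 1)
  cen <- cens[pick, ]
  span <- if (pick == 1) ctr - cen$end else cen$start - ctr
  if (w[1] > span) {
    stopf("break window [%d, %d] lies outside the centromere-to-center span (%d)",
          w[1], w[2], span)
  }
  off <- if (w[1] == w[2]) w[1] else sample(w[1]:min(w[2], span), 1)
  ## the viable product is the fragment containing the palindrome center
  ## (and hence the other centromere copy): it keeps the full essential
  ## complement plus the inverted duplication
  if (pick == 1) {
    break_pos <- cen$end + off
    blocks <- slice_blocks(dicentric$blocks, break_pos, nchar(dicentric$seq))
    seq <- slice0(dicentric$seq, break_pos, nchar(dicentric$seq))
    side <- "right"
  } else {
    break_pos <- cen$start - off
    blocks <- slice_blocks(dicentric$blocks, 0L, break_pos)
    seq <- slice0(dicentric$seq, 0L, break_pos)
    side <- "left"
  }
  structure(list(seq = seq, blocks = blocks, break_pos = as.integer(break_pos),
                 side = side, chrom = dicentric$chrom, ir = dicentric$ir,
                 corrected = dicentric$corrected, cut = dicentric$cut,
                 center = ctr, dicentric = dicentric),
            class = "broken_chromosome")
}

## map a dicentric coordinate (inverted half) to the reference coordinate
## of the focal chromosome; valid for x < center
dicentric_to_ref <- function(x, model, dic) {
  L <- nchar(model$seq[[dic$chrom]])
  L - 1L - as.integer(x)
}

#' Stabilize a broken dicentric (or delete a centromere)
#'
#' Three telomere-restoring routes: `repeat_translocation` places a
#' non-reciprocal junction inside a repeat element between the break and the
#' palindrome center and captures a donor chromosome's terminal segment
#' through its telomere; `telomere_addition` seals the break with de novo
#' telomeric repeats; `centromere_deletion` acts on the un-broken dicentric,
#' removing one centromere copy with flanks drawn log-uniformly from the
#' configured range, yielding a near-full-length monocentric inversion
#' chromosome.
#'
#' @param broken A `broken_chromosome` (for translocation / telomere
#'   addition) or a `dicentric` (for centromere deletion).
#' @param mode One of `"repeat_translocation"`, `"telomere_addition"`,
#'   `"centromere_deletion"`.
#' @param model The `reference_model`.
#' @param params A [foldback_params()].
#' @return A `derivative_genome`.
#' @export
stabilize <- function(broken, mode, model, params = foldback_params()) {
  mode <- match.arg(mode, c("repeat_translocation", "telomere_addition",
                            "centromere_deletion"))
  if (mode == "centromere_deletion") {
    return(stabilize_cen_deletion(broken, model, params))
  }
  ## canonicalize: broken end at the left
  blocks <- broken$blocks
  seq <- broken$seq
  if (broken$side == "left") {
    blocks <- flip_blocks(blocks)
    seq <- revcomp(seq)
  }
  dic <- broken$dicentric
  L <- nchar(model$seq[[broken$chrom]])
  ctr_ref <- broken$ir$center
  ## dicentric coordinates of the retained inverted segment between the
  ## break and the palindrome center, expressed in reference coordinates
  bk <- if (broken$side == "right") broken$break_pos else
    nchar(dic$seq) - broken$break_pos        # after canonical flip
  seg_ref_lo <- ctr_ref                       # palindrome center
  seg_ref_hi <- dicentric_to_ref(bk, model, dic)  # ref coord at the break

  ev <- base_event("foldback", broken$cut)
  ev$ir_id <- broken$ir$id
  ev$ir_class <- broken$ir$class %||% "other"
  ev$ir_center <- broken$ir$center
  ev$ir_spacer <- broken$ir$spacer_len
  ev$ir_side <- ir_side_of(broken$ir, model)
  ev$corrected <- broken$corrected
  ev$break_pos <- broken$break_pos
  ev$ref_break <- as.integer(seg_ref_hi)
  ev$stabilization <- mode

  if (mode == "telomere_addition") {
    tel <- substr(strrep(model$telomere_seed, 10), 1, 100)
    out_blocks <- reindex_blocks(bind_rows(ins_block(revcomp(tel)), blocks))
    out_seq <- paste0(revcomp(tel), seq)
    ev$dup_start <- as.integer(ctr_ref)
    ev$dup_end <- as.integer(seg_ref_hi + 1L)
    return(assemble_derivative(model, out_blocks, out_seq, ev))
  }

  ## repeat_translocation: elements on the focal chromosome wholly inside
  ## (center, break) with a same-family copy on another chromosome
  cand <- model$repeats |>
    filter(.data$chrom == broken$chrom,
           .data$start >= seg_ref_lo, .data$end <= seg_ref_hi)
  donors <- model$repeats |> filter(.data$chrom != broken$chrom)
  cand <- cand |> filter(.data$family %in% donors$family)
  if (nrow(cand) == 0) {
    ## no repeat available between break and center: fall back
    return(stabilize(broken, "telomere_addition", model, params))
  }
  if (params$element_choice == "nearest") {
    cand <- cand |> arrange(dplyr::desc(.data$end))   # nearest to the break
    elem <- cand[1, ]
  } else {
    elem <- cand[sample.int(nrow(cand), 1), ]
  }
  dn <- donors |> filter(.data$family == elem$family)
  dn <- dn[sample.int(nrow(dn), 1), ]
  max_off <- min(elem$end - elem$start, dn$end - dn$start) - 2L
  p <- sample(0:max_off, 1)                   # junction offset within the element
  ## derivative coordinate of the junction: the inverted segment maps ref
  ## r -> d = (L - 1 - r) - break  (canonical orientation, broken end left)
  xj <- (L - 1L - (elem$start + p)) - as.integer(bk)
  ## donor terminal segment from the element through its telomere, reverse
  ## complemented so the captured telomere caps the broken (left) end
  dlen <- nchar(model$seq[[dn$chrom]])
  donor_blocks <- ref_block(dn$chrom, dn$start + p + 1L, dlen, strand = "-")
  keep <- slice_blocks(blocks, xj, nchar(seq))
  out_blocks <- reindex_blocks(bind_rows(donor_blocks, keep))
  out_seq <- paste0(revcomp(slice0(model$seq[[dn$chrom]], dn$start + p + 1L, dlen)),
                    slice0(seq, xj, nchar(seq)))
  ev$stabilization <- "repeat_translocation"
  ev$junction_pos <- as.integer(elem$start + p)
  ev$donor_chrom <- dn$chrom
  ev$donor_pos <- as.integer(dn$start + p)
  ev$secondary_family <- elem$family
  ev$secondary_element <- elem$id
  ev$dup_start <- as.integer(ctr_ref)
  ev$dup_end <- as.integer(elem$start + p)
  assemble_derivative(model, out_blocks, out_seq, ev)
}

ir_side_of <- function(ir, model) {
  tgt <- model$irs[model$irs$class == "target", ]
  if (nrow(tgt) == 0 || is.null(ir$center)) return(NA_character_)
  if (ir$id %||% "" == tgt$id) return("target")
  if (ir$center < tgt$center) "telomeric" else "centromeric"
}

stabilize_cen_deletion <- function(dic, model, params) {
  if (!inherits(dic, "dicentric")) {
    stopf("centromere_deletion applies to the un-broken dicentric")
  }
  cens <- find_centromeres(dic$seq, model$cen_core)
  if (nrow(cens) != 2) stopf("need a dicentric with 2 centromeres")
  pick <- sample(1:2, 1)
  cen <- cens[pick, ]
  fr <- params$cen_del_flank_range
  lu <- function() exp(runif(1, log(fr[1]), log(fr[2])))
  ## clamp flanks: keep the other centromere, the telomere block, and the
  ## essential region beyond the palindrome center
  bnd <- model$essential_boundary[[dic$chrom]] %||% dic$ir$center
  ctr <- dic$center
  slack <- as.integer(bnd - dic$ir$center)     # dispensable bp past the center
  if (pick == 1) {
    f_tel <- min(lu(), cen$start - 400)
    f_ctr <- min(lu(), (ctr + slack) - cen$end)
    del <- c(cen$start - round(f_tel), cen$end + round(f_ctr))
  } else {
    f_ctr <- min(lu(), cen$start - (ctr - slack))
    f_tel <- min(lu(), nchar(dic$seq) - 400 - cen$end)
    del <- c(cen$start - round(f_ctr), cen$end + round(f_tel))
  }
  del <- as.integer(del)
  out_blocks <- reindex_blocks(bind_rows(
    slice_blocks(dic$blocks, 0L, del[1]),
    slice_blocks(dic$blocks, del[2], nchar(dic$seq))
  ))
  out_seq <- paste0(slice0(dic$seq, 0L, del[1]),
                    slice0(dic$seq, del[2], nchar(dic$seq)))
  ev <- base_event("foldback", dic$cut)
  ev$ir_id <- dic$ir$id
  ev$ir_class <- dic$ir$class %||% "other"
  ev$ir_center <- dic$ir$center
  ev$ir_spacer <- dic$ir$spacer_len
  ev$ir_side <- ir_side_of(dic$ir, model)
  ev$corrected <- dic$corrected
  ev$stabilization <- "centromere_deletion"
  ev$del_start <- del[1]
  ev$del_end <- del[2]
  ev$dup_start <- as.integer(dic$ir$center)
  ev$dup_end <- as.integer(nchar(model$seq[[dic$chrom]]))
  assemble_derivative(model, out_blocks, out_seq, ev)
}

## primary (non-foldback) terminal events --------------------------------

apply_interstitial_deletion <- function(model, cut) {
  L <- nchar(model$seq[[cut$chrom]])
  bnd <- model$essential_boundary[[cut$chrom]] %||% (cut$cut + 1000L)
  d_tel <- round(exp(runif(1, log(600), log(3000))))
  d_cen <- round(exp(runif(1, log(500), log(max(501, bnd - cut$cut)))))
  del <- c(cut$cut - d_tel, min(cut$cut + d_cen, bnd))
  blocks <- reindex_blocks(bind_rows(ref_block(cut$chrom, 0L, del[1]),
                                     ref_block(cut$chrom, del[2], L)))
  ev <- base_event("interstitial_deletion", cut)
  ev$del_start <- as.integer(del[1])
  ev$del_end <- as.integer(del[2])
  assemble_derivative(model, blocks, replay_blocks(blocks, model), ev)
}

apply_telomere_addition <- function(model, cut) {
  L <- nchar(model$seq[[cut$chrom]])
  bnd <- model$essential_boundary[[cut$chrom]] %||% (cut$cut + 1000L)
  r <- round(exp(runif(1, log(100), log(max(101, bnd - cut$cut)))))
  start <- min(cut$cut + r, bnd)
  tel <- substr(strrep(model$telomere_seed, 10), 1, 100)
  blocks <- reindex_blocks(bind_rows(ins_block(revcomp(tel)),
                                     ref_block(cut$chrom, start, L)))
  ev <- base_event("telomere_addition", cut)
  ev$del_start <- 0L
  ev$del_end <- as.integer(start)
  assemble_derivative(model, blocks, replay_blocks(blocks, model), ev)
}

## candidate IRs for foldback priming at a given cut
foldback_candidates <- function(model, cut, params) {
  irs <- model$irs |> filter(.data$chrom == cut$chrom)
  if (!is.null(params$ir_candidates)) {
    irs <- irs |> filter(.data$id %in% params$ir_candidates)
  }
  irs <- irs |> mutate(flap = .data$left_start - cut$cut) |>
    filter(.data$flap >= 0, .data$flap <= params$max_flap)
  bnd <- model$essential_boundary[[cut$chrom]] %||% Inf
  irs |> filter(.data$center <= bnd)
}

simulate_one_foldback <- function(model, cut, params) {
  cand <- foldback_candidates(model, cut, params)
  if (nrow(cand) == 0) stopf("no eligible IR for foldback at this cut")
  w <- exp(-cand$flap / params$ir_lambda)
  ir <- cand[sample.int(nrow(cand), 1, prob = w), ]
  hp <- apply_foldback(model, cut, ir, params)
  dic <- replicate_to_dicentric(hp, model)
  mode <- sample(names(params$stabilization_weights), 1,
                 prob = params$stabilization_weights)
  if (mode == "centromere_deletion") {
    return(stabilize(dic, "centromere_deletion", model, params))
  }
  broken <- break_dicentric(dic, model, params)
  if (params$refold_prob > 0 && runif(1) < params$refold_prob) {
    der <- refold_broken(broken, model, params)
    if (!is.null(der)) return(der)
  }
  stabilize(broken, mode, model, params)
}

## second round of foldback priming at the broken dicentric end: an IR near
## the break seeds another hairpin, replication yields a new dicentric, it
## breaks again, and the product is sealed by telomere addition - the route
## to triplications/quadruplications. Returns NULL when no usable IR or
## window geometry exists (the caller then stabilizes normally).
refold_broken <- function(broken, model, params) {
  blocks <- broken$blocks
  seqs <- broken$seq
  if (broken$side == "left") {        # canonical: broken end at the left
    blocks <- flip_blocks(blocks)
    seqs <- revcomp(seqs)
  }
  win <- substr(seqs, 1, 1000)
  irs <- find_inverted_repeats(win, min_arm = 5L, max_spacer = 50L,
                               max_mismatch = 1L)
  irs <- irs[irs$left_start <= params$max_flap, ]
  if (nrow(irs) == 0) return(NULL)
  c2 <- irs$center[1]
  s2 <- slice0(seqs, c2, nchar(seqs))
  b2 <- slice_blocks(blocks, c2, nchar(seqs))
  dic2 <- structure(list(
    seq = paste0(revcomp(s2), s2),
    blocks = reindex_blocks(bind_rows(flip_blocks(b2), b2)),
    chrom = broken$chrom, ir = broken$ir, corrected = broken$corrected,
    cut = broken$cut, center = nchar(s2)), class = "dicentric")
  broken2 <- tryCatch(break_dicentric(dic2, model, params),
                      error = function(e) NULL)
  if (is.null(broken2)) return(NULL)
  bl <- broken2$blocks
  sq <- broken2$seq
  if (broken2$side == "left") {
    bl <- flip_blocks(bl)
    sq <- revcomp(sq)
  }
  tel <- substr(strrep(model$telomere_seed, 10), 1, 100)
  out_blocks <- reindex_blocks(bind_rows(ins_block(revcomp(tel)), bl))
  out_seq <- paste0(revcomp(tel), sq)
  ev <- base_event("foldback", broken$cut)
  ev$complex <- TRUE
  ev$n_foldbacks <- 2L
  ev$ir_id <- broken$ir$id
  ev$ir_class <- broken$ir$class %||% "other"
  ev$ir_center <- broken$ir$center
  ev$ir_spacer <- broken$ir$spacer_len
  ev$ir_side <- ir_side_of(broken$ir, model)
  ev$corrected <- broken$corrected
  ev$break_pos <- broken$break_pos
  ev$stabilization <- "telomere_addition"
  ev$dup_start <- as.integer(broken$ir$center)
  assemble_derivative(model, out_blocks, out_seq, ev)
}

#' Simulate a cohort of survivors
#'
#' Draws `n` independent survivors under the configured event weights and
#' returns the derivative genomes plus a truth table (one row per clone with
#' the full event log).
#'
#' @param model A `reference_model`.
#' @param n Number of survivors.
#' @param params A [foldback_params()].
#' @param guide Guide name passed to [locate_cut_site()].
#' @param seed RNG seed (defaults to the seed in `params`).
#' @return A list with `derivatives` (list of `derivative_genome`) and
#'   `truth` (tibble).
#' @export
simulate_cohort <- function(model, n, params = foldback_params(),
                            guide = "gRNA-17", seed = params$seed) {
  stopifnot(n >= 0)
  set.seed(derive_seed(seed, "cohort"))
  cut <- locate_cut_site(model, guide)
  sim_one <- function(kind) {
    switch(kind,
      foldback = simulate_one_foldback(model, cut, params),
      nhej = apply_nhej(model, cut),
      homeologous_gc = apply_homeologous_gc(model, cut),
      interstitial_deletion = apply_interstitial_deletion(model, cut),
      telomere_addition = apply_telomere_addition(model, cut),
      cas9_inactivated = {
        blocks <- reindex_blocks(ref_block(cut$chrom, 0L,
                                           nchar(model$seq[[cut$chrom]])))
        assemble_derivative(model, blocks, model$seq[[cut$chrom]],
                            base_event("cas9_inactivated", cut))
      },
      stopf("unknown event kind '%s'", kind))
  }
  kinds <- if (n > 0) sample_event_type(params, n) else character(0)
  derivs <- vector("list", n)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    derivs[[k]] <- sim_one(kinds[k])
    rows[[k]] <- derivs[[k]]$event |> mutate(clone_id = sprintf("clone_%03d", k),
                                             .before = 1)
  }
  truth <- if (n > 0) bind_rows(rows) else
    base_event("none")[0, ] |> mutate(clone_id = character(0), .before = 1)
  list(derivatives = derivs, truth = truth)
}

#' Does a genome still contain the guide target?
#'
#' Scans all chromosomes of a derivative for an exact protospacer match on
#' either strand (the survivor condition: Cas9 keeps cutting until the
#' target is gone).
#'
#' @param derivative A `derivative_genome`.
#' @param model The `reference_model`.
#' @param guide Guide name.
#' @return `TRUE` if a match remains.
#' @export
has_protospacer <- function(derivative, model, guide = "gRNA-17") {
  g <- model$guides[model$guides$guide == guide, ]
  if (nrow(g) == 0) stopf("unknown guide '%s'", guide)
  any(map_int(derivative$seq, function(s) {
    length(locate_motif(s, g$seq)) + length(locate_motif(s, revcomp(g$seq)))
  }) > 0)
}

#' Write a cohort's derivative genomes and truth table
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (k in seq_along(cohort$derivatives)) {
    d <- cohort$derivatives[[k]]
    p <- file.path(dir, sprintf("%s.fa", cohort$truth$clone_id[k]))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(d$seq), p)
    paths <- c(paths, p)
  }
  tt <- file.path(dir, "truth.tsv")
  truth_flat <- cohort$truth
  readr::write_tsv(truth_flat, tt)
  invisible(c(paths, tt))
}
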