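#' Estimate insert-size statistics from pair spans
#'
#' @param pairs A pair tibble from [pair_table()].
#' @return A list with `mu` and `sigma` (median / MAD of inward
#'   opposite-strand spans).
#' @export
estimate_insert_stats <- function(pairs) {
  ok <- pairs$chrom1 == pairs$chrom2 & pairs$strand1 != pairs$strand2
  span <- abs(pmax(pairs$end1, pairs$end2) - pmin(pairs$pos1, pairs$pos2))[ok]
  list(mu = median(span), sigma = max(stats::mad(span), 1))
}

#' Collapse per-mate alignment records into one row per pair
#'
#' Unpaired records are skipped (count reported as an attribute).
#'
#' @param alignments Projected alignment tibble.
#' @return A tibble with one row per read pair: `qname`, and
#'   `chrom/pos/end/strand/clip` for each mate (mate 1 = lower coordinate on
#'   its chromosome, for determinism).
#' @export
pair_table <- function(alignments) {
  a1 <- alignments[alignments$mate == 1L, ]
  a2 <- alignments[alignments$mate == 2L, ]
  common <- intersect(a1$qname, a2$qname)
  n_unpaired <- nrow(a1) + nrow(a2) - 2L * length(common)
  a1 <- a1[match(common, a1$qname), ]
  a2 <- a2[match(common, a2$qname), ]
  ## order mates by (chrom, pos) for deterministic downstream handling
  swap <- (a2$chrom < a1$chrom) | (a2$chrom == a1$chrom & a2$pos < a1$pos)
  first <- function(x, y) if_else(swap, y, x)
  out <- tibble(
    qname = a1$qname,
    chrom1 = first(a1$chrom, a2$chrom), pos1 = first(a1$pos, a2$pos),
    end1 = first(a1$pos + a1$aln_len, a2$pos + a2$aln_len),
    strand1 = first(a1$strand, a2$strand),
    clip1 = first(a1$clip5 + a1$clip3, a2$clip5 + a2$clip3),
    chrom2 = first(a2$chrom, a1$chrom), pos2 = first(a2$pos, a1$pos),
    end2 = first(a2$pos + a2$aln_len, a1$pos + a1$aln_len),
    strand2 = first(a2$strand, a1$strand),
    clip2 = first(a2$clip5 + a2$clip3, a1$clip5 + a1$clip3)
  )
  attr(out, "n_unpaired") <- n_unpaired
  out
}

#' Classify read pairs by orientation and span
#'
#' Exhaustive, mutually exclusive classes: `interchromosomal` (mates on
#' different chromosomes), `inverted_same_strand` (both mates on one strand
#' - the signature of a foldback junction), `concordant` (opposite strands,
#' inward-facing, span within `mu +/- 4 sigma`), and `distance_discordant`
#' (orientation fine but span out of bounds, or outward-facing).
#'
#' @param pairs A pair tibble from [pair_table()].
#' @param insert_stats List with `mu`, `sigma` (see
#'   [estimate_insert_stats()]).
#' @return `pairs` with a `class` column.
#' @export
classify_pairs <- function(pairs, insert_stats) {
  mu <- insert_stats$mu
  s4 <- 4 * insert_stats$sigma
  span <- pmax(pairs$end1, pairs$end2) - pmin(pairs$pos1, pairs$pos2)
  inward <- (pairs$strand1 == "+" & pairs$strand2 == "-" & pairs$pos1 <= pairs$pos2) |
    (pairs$strand1 == "-" & pairs$strand2 == "+" & pairs$pos2 <= pairs$pos1)
  pairs |>
    mutate(span = if_else(.data$chrom1 == .data$chrom2, span, NA_integer_),
           class = dplyr::case_when(
             chrom1 != chrom2 ~ "interchromosomal",
             strand1 == strand2 ~ "inverted_same_strand",
             inward & abs(span - mu) <= s4 ~ "concordant",
             TRUE ~ "distance_discordant"
           ))
}

#' Cluster discordant pairs
#'
#' Single-linkage clustering of same-class discordant pairs: two pairs join
#' a cluster when both footprints lie within `window` of each other
#' (per-anchor, sorted-gap linkage). Ordering is deterministic.
#'
#' @param pairs Classified pair tibble (discordant classes only are used).
#' @param window Linkage window (bp), typically one fragment length.
#' @return A tibble of clusters: `class`, `cluster`, `chrom1`, `start1`,
#'   `end1`, `chrom2`, `start2`, `end2`, `support`, `members` (list of
#'   qnames).
#' @export
cluster_discordant <- function(pairs, window = 500) {
  disc <- pairs |>
    filter(.data$class %in% c("inverted_same_strand", "interchromosomal",
                              "distance_discordant")) |>
    arrange(.data$class, .data$chrom1, .data$chrom2, .data$pos1, .data$pos2)
  if (nrow(disc) == 0) {
    return(tibble(class = character(0), cluster = integer(0),
                  chrom1 = character(0), start1 = integer(0), end1 = integer(0),
                  chrom2 = character(0), start2 = integer(0), end2 = integer(0),
                  support = integer(0), members = list()))
  }
  disc |>
    group_by(.data$class, .data$chrom1, .data$chrom2) |>
    mutate(.brk = cumsum(
      {
        gap1 <- .data$pos1 - lag(.data$pos1, default = dplyr::first(.data$pos1))
        gap2 <- abs(.data$pos2 - lag(.data$pos2, default = dplyr::first(.data$pos2)))
        as.integer(gap1 > window | gap2 > window)
      })) |>
    group_by(.data$class, .data$chrom1, .data$chrom2, .data$.brk) |>
    summarise(start1 = min(.data$pos1), end1 = max(.data$end1),
              start2 = min(.data$pos2), end2 = max(.data$end2),
              support = n(), members = list(.data$qname), .groups = "drop") |>
    arrange(.data$class, .data$chrom1, .data$start1) |>
    mutate(cluster = row_number(), .before = 1) |>
    select("cluster", "class", "chrom1", "start1", "end1",
           "chrom2", "start2", "end2", "support", "members")
}

#' Extract reads informative about a boundary
#'
#' All discordant or clipped reads with an end, a mate, or a clip inside
#' the boundary interval extended by `margin`.
#'
#' @param alignments Projected alignment tibble.
#' @param pairs Classified pair tibble (same read set).
#' @param chrom,start,end Boundary interval (0-based half-open).
#' @param margin Extension (bp) on each side.
#' @param min_clip A record counts as clipped if `clip5 + clip3` is at least
#'   this many bases.
#' @return The subset of `alignments` (both mates of qualifying pairs).
#' @export
extract_boundary_reads <- function(alignments, pairs, chrom, start, end,
                                   margin = 500, min_clip = 10L) {
  lo <- start - margin
  hi <- end + margin
  in_win <- function(ch, p, e) ch == chrom & e > lo & p < hi
  qual <- pairs$class != "concordant" |
    (pairs$clip1 >= min_clip & in_win(pairs$chrom1, pairs$pos1, pairs$end1)) |
    (pairs$clip2 >= min_clip & in_win(pairs$chrom2, pairs$pos2, pairs$end2))
  touch <- in_win(pairs$chrom1, pairs$pos1, pairs$end1) |
    in_win(pairs$chrom2, pairs$pos2, pairs$end2)
  keep <- pairs$qname[qual & touch]
  alignments[alignments$qname %in% keep, ]
}

## ---------------------------------------------------------------------------
## Greedy overlap assembly
## ---------------------------------------------------------------------------

## index reads by their first `k` bases (both orientations)
kmer_index <- function(seqs, k) {
  pre <- substr(seqs, 1, k)
  split(seq_along(seqs), pre)
}

## count mismatches between equal-length strings
str_mismatch <- function(a, b) {
  if (a == b) return(0L)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## best extension of `contig` to the right using unused reads
extend_right <- function(contig, seqs, used, idx, min_overlap, max_mismatch) {
  Lc <- nchar(contig)
  best <- NULL
  max_o <- min(Lc, max(nchar(seqs)))
  for (o in seq(max_o, min_overlap)) {
    p <- Lc - o + 1L
    key <- substr(contig, p, min(Lc, p + attr(idx, "k") - 1L))
    if (nchar(key) < attr(idx, "k")) next
    cand <- idx[[key]]
    cand <- cand[!used[cand]]
    if (length(cand) == 0) next
    cand <- cand[order(names(seqs)[cand])]   # deterministic tie-break
    for (ri in cand) {
      r <- seqs[[ri]]
      ol <- min(o, nchar(r))
      if (str_mismatch(substr(contig, Lc - ol + 1L, Lc), substr(r, 1, ol)) <=
          max_mismatch) {
        if (nchar(r) > ol) {
          return(list(read = ri, overlap = ol,
                      ext = substr(r, ol + 1L, nchar(r))))
        }
        best <- best %||% list(read = ri, overlap = ol, ext = "")
      }
    }
    if (!is.null(best)) return(best)   # contained read: absorb, no extension
  }
  best
}

#' Greedy overlap assembly of a read set
#'
#' Minimal overlap-layout-consensus assembler for (near) error-free reads:
#' reads are merged by the longest exact-or-near-exact suffix-prefix
#' overlap of at least `min_overlap` bases, considering both orientations,
#' with deterministic tie-breaking (longest overlap, then lexicographic
#' read id). Unmerged reads are returned as singleton contigs.
#'
#' @param reads Character vector of read sequences, named by read id (names
#'   generated if absent).
#' @param min_overlap Minimum overlap (nt).
#' @param max_mismatch Maximum mismatches tolerated in an overlap.
#' @return A tibble with `contig`, `length`, `n_reads`, sorted by decreasing
#'   length then sequence.
#' @export
assemble_overlap <- function(reads, min_overlap = 15L, max_mismatch = 0L) {
  if (length(reads) == 0) stopf("no reads to assemble")
  if (is.null(names(reads))) names(reads) <- sprintf("r%05d", seq_along(reads))
  reads <- reads[order(names(reads))]
  ## both orientations share a 'used' slot per original read
  n <- length(reads)
  seqs <- c(reads, setNames(revcomp(reads), paste0(names(reads), "_rc")))
  orig <- rep(seq_len(n), 2)
  k <- min(min_overlap, min(nchar(reads)))
  idx <- kmer_index(seqs, k)
  attr(idx, "k") <- k
  used <- logical(n)
  contigs <- character(0)
  counts <- integer(0)
  ord <- order(-nchar(reads), names(reads))
  for (si in ord) {
    if (used[si]) next
    used[si] <- TRUE
    contig <- reads[[si]]
    n_in <- 1L
    repeat {
      extended <- FALSE
      for (flip in c(FALSE, TRUE)) {
        if (flip) contig <- revcomp(contig)
        repeat {
          hit <- extend_right(contig, seqs, used[orig], idx,
                              min_overlap, max_mismatch)
          if (is.null(hit)) break
          used[orig[hit$read]] <- TRUE
          n_in <- n_in + 1L
          if (nchar(hit$ext) > 0) {
            contig <- paste0(contig, hit$ext)
            extended <- TRUE
          }
        }
        if (flip) contig <- revcomp(contig)
      }
      if (!extended) break
    }
    contigs <- c(contigs, contig)
    counts <- c(counts, n_in)
  }
  tibble(contig = contigs, length = nchar(contigs), n_reads = counts) |>
    arrange(dplyr::desc(.data$length), .data$contig)
}

## ---------------------------------------------------------------------------
## Foldback center finding
## ---------------------------------------------------------------------------

## locate a unique anchor for `kmer` in the reference (either strand);
## returns NULL if not unique
anchor_kmer <- function(kmer, ref_seqs) {
  hits <- NULL
  for (ch in names(ref_seqs)) {
    fw <- locate_motif(ref_seqs[[ch]], kmer)
    rv <- locate_motif(ref_seqs[[ch]], revcomp(kmer))
    if (length(fw)) hits <- bind_rows(hits, tibble(chrom = ch, pos = fw, strand = "+"))
    if (length(rv)) hits <- bind_rows(hits, tibble(chrom = ch, pos = rv, strand = "-"))
  }
  if (is.null(hits) || nrow(hits) != 1) return(NULL)
  hits
}

## maximal mismatch-tolerant extension of an anchored seed; returns the
## contig/ref interval pair of the matched segment (trimmed to last match)
extend_anchor <- function(contig, cpos, ref, rpos, dir_c, dir_r, max_mismatch) {
  Lc <- nchar(contig)
  Lr <- nchar(ref)
  mism <- 0L
  last_ok <- 0L
  i <- 0L
  repeat {
    ci <- cpos + dir_c * (i + 1L)
    ri <- rpos + dir_r * (i + 1L)
    if (ci < 1L || ci > Lc || ri < 1L || ri > Lr) break
    cb <- substr(contig, ci, ci)
    rb <- substr(ref, ri, ri)
    if (dir_c * dir_r < 0) rb <- comp_base(rb)
    ok <- cb == rb
    if (!ok) {
      mism <- mism + 1L
      if (mism > max_mismatch) break
    } else {
      last_ok <- i + 1L
    }
    i <- i + 1L
  }
  last_ok
}

#' Find the foldback center of a junction contig
#'
#' Anchors the contig's two ends in the reference with exact k-mer seeds,
#' extends each anchor maximally (tolerating up to `max_mismatch`
#' substitutions, trimmed back to the last matching base), and reports a
#' foldback center when the two ends align to the same locus on opposite
#' strands: the center is the midpoint between the inner ends of the two
#' arm alignments. Also reports the length of the perfect palindrome in the
#' contig about the switch point. A fully collinear contig yields no center.
#'
#' @param contig A contig sequence.
#' @param ref_seqs Named character vector of reference chromosomes (or a
#'   `reference_model`).
#' @param seed_len Anchor seed length (nt).
#' @param max_mismatch Mismatch tolerance during extension (covers
#'   uncorrected foldback arms).
#' @return A one-row tibble (`chrom`, `center`, `arm5_len`, `arm3_len`,
#'   `pal_len`, `center_contig`) or a zero-row tibble if no center.
#' @export
find_foldback_center <- function(contig, ref_seqs, seed_len = 20L,
                                 max_mismatch = 2L) {
  if (!is.character(ref_seqs)) ref_seqs <- ref_seqs$seq
  empty <- tibble(chrom = character(0), center = integer(0),
                  arm5_len = integer(0), arm3_len = integer(0),
                  pal_len = integer(0), center_contig = integer(0),
                  exact_gap = integer(0))
  Lc <- nchar(contig)
  if (Lc < 2L * seed_len) return(empty)
  find_anchor <- function(from_start) {
    for (off in seq(0L, min(200L, Lc - seed_len), by = 10L)) {
      cpos <- if (from_start) 1L + off else Lc - seed_len + 1L - off
      km <- substr(contig, cpos, cpos + seed_len - 1L)
      a <- anchor_kmer(km, ref_seqs)
      if (!is.null(a)) return(c(a, list(cpos = cpos, offset = off)))
    }
    NULL
  }
  a5 <- find_anchor(TRUE)
  a3 <- find_anchor(FALSE)
  if (is.null(a5) || is.null(a3)) return(empty)
  if (a5$chrom != a3$chrom || a5$strand == a3$strand) return(empty)
  ref <- ref_seqs[[a5$chrom]]
  ## inner-directed extension of each anchor, both mismatch-tolerant (to
  ## traverse uncorrected arms) and exact (to flag mismatch correction)
  ext5 <- function(mm) {
    if (a5$strand == "+") {
      e <- extend_anchor(contig, a5$cpos + seed_len - 1L, ref,
                         a5$pos + seed_len, 1L, 1L, mm)
      list(e = e, inner = a5$pos + seed_len + e)  # 0-based, exclusive
    } else {
      ## prefix maps to minus strand: moving right in contig moves left in ref
      e <- extend_anchor(contig, a5$cpos + seed_len - 1L, ref,
                         a5$pos + 1L, 1L, -1L, mm)
      list(e = e, inner = a5$pos - e)             # 0-based, inclusive edge
    }
  }
  ext3 <- function(mm) {
    if (a3$strand == "+") {
      e <- extend_anchor(contig, a3$cpos, ref, a3$pos + 1L, -1L, -1L, mm)
      list(e = e, inner = a3$pos - e)
    } else {
      e <- extend_anchor(contig, a3$cpos, ref, a3$pos + seed_len, -1L, 1L, mm)
      list(e = e, inner = a3$pos + seed_len + e)
    }
  }
  x5 <- ext5(max_mismatch); x3 <- ext3(max_mismatch)
  x5e <- ext5(0L); x3e <- ext3(0L)
  e5 <- x5$e; e3 <- x3$e
  inner5_ref <- x5$inner; inner3_ref <- x3$inner
  center <- (inner5_ref + inner3_ref) %/% 2L
  exact_gap <- max(abs(x5e$inner - center), abs(x3e$inner - center))
  ## contig-space switch point and palindrome length about it; the switch
  ## point is ambiguous within a few bases, so take the best nearby offset
  inner5_c <- a5$cpos + seed_len - 1L + e5        # last matched contig pos (1-based)
  inner3_c <- a3$cpos - e3
  cc0 <- (inner5_c + inner3_c) %/% 2L
  cand <- (cc0 - 3L):(cc0 + 3L)
  pals <- vapply(cand, function(p) palindrome_extent(contig, p), integer(1))
  cc <- cand[which.max(pals)]
  pal <- max(pals)
  tibble(chrom = a5$chrom, center = as.integer(center),
         arm5_len = as.integer(a5$offset + seed_len + e5),
         arm3_len = as.integer(a3$offset + seed_len + e3),
         pal_len = as.integer(pal), center_contig = as.integer(cc),
         exact_gap = as.integer(exact_gap))
}

## maximal k such that contig[c-k+1 .. c] == revcomp(contig[c+1 .. c+k])
palindrome_extent <- function(contig, c_pos) {
  L <- nchar(contig)
  k <- 0L
  while (c_pos - k >= 1L && c_pos + 1L + k <= L) {
    a <- substr(contig, c_pos - k, c_pos - k)
    b <- substr(contig, c_pos + 1L + k, c_pos + 1L + k)
    if (a != comp_base(b)) break
    k <- k + 1L
  }
  k
}

#' Annotate which inverted repeat a foldback center used
#'
#' Matches a foldback center coordinate against the model's IR catalog:
#' `target` if within the target IR's spacer (+/- tolerance), `pam` if
#' within the PAM-overlapping IR's extent, otherwise `other`. The side
#' relative to the target IR (telomeric/centromeric) and the
#' mismatch-correction flag (palindrome extends through the full arm) are
#' also reported.
#'
#' @param center_call One-row tibble from [find_foldback_center()].
#' @param model A `reference_model`.
#' @param tol Center placement tolerance (bp) added around each IR spacer.
#' @return A one-row tibble: `ir_id`, `ir_class`, `ir_side`, `corrected`.
#' @export
annotate_ir_usage <- function(center_call, model, tol = 1L) {
  irs <- model$irs[model$irs$chrom == center_call$chrom, ]
  tgt <- irs[irs$class == "target", ]
  hit <- irs |>
    filter(.data$left_end - tol - .data$spacer_len %/% 2L <= center_call$center,
           .data$right_start + tol + .data$spacer_len %/% 2L >= center_call$center) |>
    mutate(d = abs(.data$center - center_call$center)) |>
    arrange(.data$d)
  pam <- irs[irs$class == "pam", ]
  if (nrow(hit) > 0) {
    ir <- hit[1, ]
    cls <- ir$class
  } else if (nrow(pam) == 1 && center_call$center >= pam$left_start &&
             center_call$center < pam$right_end) {
    ir <- pam
    cls <- "pam"
  } else {
    ir <- NULL
    cls <- "other"
  }
  side <- if (nrow(tgt) == 1) {
    if (!is.null(ir) && ir$id == tgt$id) "target"
    else if (center_call$center < tgt$center) "telomeric" else "centromeric"
  } else NA_character_
  ## exact reference extension reaching (nearly) the center means the arm
  ## matches the centromere-proximal copy: mismatches were corrected. An
  ## uncorrected arm stops the exact extension at its outermost mismatch.
  corrected <- if (!is.null(ir) && "exact_gap" %in% names(center_call)) {
    center_call$exact_gap <= ir$spacer_len + 2L
  } else NA
  tibble(ir_id = if (!is.null(ir)) ir$id else NA_character_,
         ir_class = cls, ir_side = side, corrected = corrected)
}

#' Annotate a junction locus with its repeat family
#'
#' Family of the repeat element containing (or within `tol` bp of) a
#' junction locus; `"none"` for unique sequence.
#'
#' @param chrom,pos Junction locus.
#' @param model A `reference_model`.
#' @param tol Tolerance (bp).
#' @return A list with `family` and `element`.
#' @export
annotate_secondary <- function(chrom, pos, model, tol = 50L) {
  hit <- model$repeats |>
    filter(.data$chrom == !!chrom, .data$start - tol <= pos,
           .data$end + tol > pos)
  if (nrow(hit) == 0) return(list(family = "none", element = NA_character_))
  hit <- hit |> mutate(d = pmax(.data$start - pos, pos - .data$end, 0L)) |>
    arrange(.data$d)
  list(family = hit$family[1], element = hit$id[1])
}

#' Call junctions for one clone from projected alignments
#'
#' Classifies pairs, clusters the discordant ones, assembles boundary reads
#' for the strongest inverted-pair cluster into a contig and locates the
#' foldback center (with IR annotation), and annotates interchromosomal
#' clusters (translocations) and long-span clusters (interstitial
#' deletions) with their repeat families.
#'
#' @param alignments Projected alignment tibble (with `seq`).
#' @param model A `reference_model`.
#' @param insert_stats Optional list with `mu`, `sigma`; estimated from the
#'   data when `NULL`.
#' @param min_support Minimum cluster support.
#' @param min_overlap,max_mismatch Assembly parameters.
#' @return A tibble of junction calls: `kind`, `chrom`, `center`/`pos1`/
#'   `pos2`, `support`, `ir_id`, `ir_class`, `ir_side`, `corrected`,
#'   `family`, `element`, `contig`.
#' @export
call_junctions <- function(alignments, model, insert_stats = NULL,
                           min_support = 3L, min_overlap = 15L,
                           max_mismatch = 0L) {
  pairs <- pair_table(alignments)
  if (is.null(insert_stats)) insert_stats <- estimate_insert_stats(pairs)
  pairs <- classify_pairs(pairs, insert_stats)
  window <- insert_stats$mu + 4 * insert_stats$sigma
  clusters <- cluster_discordant(pairs, window = window) |>
    filter(.data$support >= min_support)
  calls <- list()
  ## foldback centers from inverted same-strand clusters
  inv <- clusters |> filter(.data$class == "inverted_same_strand") |>
    arrange(dplyr::desc(.data$support))
  for (k in seq_len(nrow(inv))) {
    cl <- inv[k, ]
    ## all discordant or clipped reads near the cluster footprint, so that
    ## junction-crossing reads in otherwise concordant-looking pairs are
    ## available to the assembler
    reads <- extract_boundary_reads(alignments, pairs, cl$chrom1,
                                    cl$start1, cl$end1,
                                    margin = window)
    if (nrow(reads) == 0) next
    contigs <- assemble_overlap(setNames(reads$seq,
                                         paste0(reads$qname, "/", reads$mate)),
                                min_overlap, max_mismatch)
    found <- FALSE
    for (ci in seq_len(min(3L, nrow(contigs)))) {
      cc <- find_foldback_center(contigs$contig[ci], model$seq)
      if (nrow(cc) == 1) {
        ann <- annotate_ir_usage(cc, model)
        calls[[length(calls) + 1L]] <- tibble(
          kind = "foldback_center", chrom = cc$chrom, center = cc$center,
          pos1 = cl$start1, pos2 = cl$end1, support = cl$support,
          pal_len = cc$pal_len) |> bind_cols(ann) |>
          mutate(family = "none", element = NA_character_,
                 contig = contigs$contig[ci])
        found <- TRUE
        break
      }
    }
    if (!found) {
      calls[[length(calls) + 1L]] <- tibble(
        kind = "inverted_cluster", chrom = cl$chrom1, center = NA_integer_,
        pos1 = cl$start1, pos2 = cl$end1, support = cl$support,
        pal_len = NA_integer_, ir_id = NA_character_, ir_class = NA_character_,
        ir_side = NA_character_, corrected = NA, family = "none",
        element = NA_character_, contig = NA_character_)
    }
  }
  ## translocations from interchromosomal clusters
  ic <- clusters |> filter(.data$class == "interchromosomal")
  for (k in seq_len(nrow(ic))) {
    cl <- ic[k, ]
    ## the junction lies at one footprint edge on each chromosome; test all
    ## four edges and keep the first repeat-family hit
    edges <- list(c(cl$chrom1, cl$start1), c(cl$chrom1, cl$end1),
                  c(cl$chrom2, cl$start2), c(cl$chrom2, cl$end2))
    anns <- map(edges, function(e) {
      annotate_secondary(e[1], as.integer(e[2]), model)
    })
    hits <- purrr::keep(anns, function(a) a$family != "none")
    fam <- if (length(hits) > 0) hits[[1]] else anns[[1]]
    calls[[length(calls) + 1L]] <- tibble(
      kind = "translocation", chrom = cl$chrom1, center = NA_integer_,
      pos1 = (cl$start1 + cl$end1) %/% 2L, pos2 = (cl$start2 + cl$end2) %/% 2L,
      support = cl$support, pal_len = NA_integer_,
      ir_id = NA_character_, ir_class = NA_character_,
      ir_side = NA_character_, corrected = NA,
      family = fam$family, element = fam$element, contig = NA_character_)
  }
  ## interstitial deletions from long-span clusters
  dd <- clusters |> filter(.data$class == "distance_discordant")
  for (k in seq_len(nrow(dd))) {
    cl <- dd[k, ]
    ann1 <- annotate_secondary(cl$chrom1, cl$end1, model)
    ann2 <- annotate_secondary(cl$chrom2, cl$start2, model)
    fam <- if (ann1$family != "none") ann1 else ann2
    calls[[length(calls) + 1L]] <- tibble(
      kind = "interstitial_deletion", chrom = cl$chrom1, center = NA_integer_,
      pos1 = cl$end1, pos2 = cl$start2, support = cl$support,
      pal_len = NA_integer_, ir_id = NA_character_, ir_class = NA_character_,
      ir_side = NA_character_, corrected = NA,
      family = fam$family, element = fam$element, contig = NA_character_)
  }
  if (length(calls) == 0) {
    return(tibble(kind = character(0), chrom = character(0), center = integer(0),
                  pos1 = integer(0), pos2 = integer(0), support = integer(0),
                  pal_len = integer(0), ir_id = character(0),
                  ir_class = character(0), ir_side = character(0),
                  corrected = logical(0), family = character(0),
                  element = character(0), contig = character(0)))
  }
  bind_rows(calls)
}
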