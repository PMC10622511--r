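#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Run the full pipeline end to end
#'
#' Builds the reference, simulates a survivor cohort, generates reads and
#' truth alignments for every clone (and a parental read set), runs the CNV
#' caller, junction reconstruction and the screening classifier, and writes
#' every intermediate in its standard format (FASTA, SAM, BED, TSV) plus a
#' run manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param write_sams Write per-clone projected SAM files (off by default:
#'   they dominate run time and disk for large cohorts).
#' @return A list with `model`, `cohort`, `cnv` (list of `cnv_scan`),
#'   `junctions` (tibble), `calls` (tibble), `summary`, `paths`.
#' @export
run_end_to_end <- function(config = pipeline_config(), out_dir,
                           write_sams = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  model <- stage("reference", build_reference(config$genome))
  write_reference(model, file.path(out_dir, "reference"))
  guide <- if (config$genome$ho_site) "HO" else "gRNA-48"
  cohort <- stage("cohort", simulate_cohort(model, config$n_clones,
                                            config$foldback, guide = guide))
  chrom_lengths <- setNames(model$chroms$length, model$chroms$chrom)

  ## the parental clone is shared by every survivor scan, so it is
  ## sequenced at twice the per-clone depth: its random halves then match
  ## the per-clone depth and the split-parental null is variance-matched
  par_params <- config$reads
  par_params$depth <- 2 * par_params$depth
  parental <- stage("reads", simulate_reads(
    model, par_params, with_seq = FALSE,
    seed = derive_seed(config$seed, "parental_reads")))

  cnv_list <- list()
  junc_rows <- list()
  if (config$n_clones > 0) {
    for (k in seq_len(config$n_clones)) {
      clone <- cohort$truth$clone_id[k]
      d <- cohort$derivatives[[k]]
      sim <- stage("reads", simulate_reads(
        d, config$reads, with_seq = TRUE,
        seed = derive_seed(config$seed, paste0("reads_", clone))))
      proj <- stage("projection", project_to_reference(sim, d, model))
      if (write_sams) {
        write_sam(proj, chrom_lengths,
                  file.path(out_dir, paste0(clone, ".sam")))
      }
      cnv_list[[clone]] <- stage("cnv", cnv_scan(
        proj, parental$alignments, chrom_lengths, config$cnv))
      jc <- stage("junctions", call_junctions(proj, model))
      junc_rows[[clone]] <- jc |> mutate(clone_id = clone, .before = 1)
    }
  }
  junctions <- bind_rows(junc_rows)

  screens <- stage("screens", simulate_screens(cohort, model, config$screen))
  calls <- stage("classification", classify_cohort(screens, config$screen))
  smry <- if (nrow(calls) > 0) {
    summarize_cohort(calls, cohort$truth)
  } else {
    list(counts = tibble(category = character(0), n = integer(0),
                         fraction = numeric(0)),
         confusion = NULL, accuracy = NA_real_)
  }

  paths <- list(truth = file.path(out_dir, "truth.tsv"),
                calls = file.path(out_dir, "calls.tsv"),
                junctions = file.path(out_dir, "junctions.tsv"),
                summary = file.path(out_dir, "summary.tsv"),
                manifest = file.path(out_dir, "manifest.yaml"))
  readr::write_tsv(cohort$truth, paths$truth)
  readr::write_tsv(calls, paths$calls)
  readr::write_tsv(junctions |> select(-dplyr::any_of("contig")), paths$junctions)
  readr::write_tsv(smry$counts, paths$summary)
  for (clone in names(cnv_list)) {
    write_cnv(cnv_list[[clone]], file.path(out_dir, paste0(clone, "_cnv")))
  }
  yaml::write_yaml(list(
    package = "foldbackr",
    version = as.character(utils::packageVersion("foldbackr")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    n_clones = config$n_clones,
    guide = guide
  ), paths$manifest)

  list(model = model, cohort = cohort, cnv = cnv_list, junctions = junctions,
       calls = calls, summary = smry, paths = paths, out_dir = out_dir)
}

#' Write a human-readable run report
#'
#' Formats (without recomputation) the classification table, per-clone CNV
#' segment summaries and junction calls of a completed run.
#'
#' @param run Result of [run_end_to_end()].
#' @param path Output path (markdown-ish plain text).
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path = file.path(run$out_dir, "report.md")) {
  missing <- purrr::keep(c("cohort", "calls", "cnv"),
                         function(f) is.null(run[[f]]))
  if (length(missing) > 0) {
    stopf("run is missing intermediates: %s", paste(missing, collapse = ", "))
  }
  ln <- c("# Survivor cohort report", "",
          sprintf("Clones: %d", nrow(run$cohort$truth)), "",
          "## Category counts", "")
  for (k in seq_len(nrow(run$summary$counts))) {
    r <- run$summary$counts[k, ]
    ln <- c(ln, sprintf("- %s: %d (%.1f%%)", r$category, r$n, 100 * r$fraction))
  }
  ln <- c(ln, "", "## Clones", "")
  for (k in seq_len(nrow(run$cohort$truth))) {
    clone <- run$cohort$truth$clone_id[k]
    call <- run$calls[run$calls$clone_id == clone, ]
    segs <- run$cnv[[clone]]$segments
    seg_txt <- if (is.null(segs) || nrow(segs) == 0) "no CNV" else {
      paste(sprintf("%s %s:%d-%d (log2 %.2f)", segs$direction, segs$chrom,
                    segs$start, segs$end, segs$mean_log2), collapse = "; ")
    }
    jc <- run$junctions[run$junctions$clone_id == clone, ]
    jc_txt <- if (nrow(jc) == 0) "none" else {
      paste(unique(sprintf("%s%s", jc$kind,
                           if_else(jc$family != "none",
                                   paste0(" (", jc$family, ")"), ""))),
            collapse = "; ")
    }
    ln <- c(ln, sprintf("- %s: %s | CNV: %s | junctions: %s", clone,
                        call$category[1] %||% "unclassified", seg_txt, jc_txt))
  }
  readr::write_lines(ln, path)
  invisible(path)
}
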