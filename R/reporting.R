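format_p_value <- function(p) {
  # publication style: plain to 2 significant digits down to 0.01,
  # scientific with 2 significant digits below
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x >= 0.01) format(signif(x, 2), scientific = FALSE)
    else {
      s <- formatC(x, format = "e", digits = 1)
      sub("e([+-])0?(\\d+)$", "e\\1\\2", s)
    }
  }, character(1))
}

#' Render a publication-style per-assay ASE table
#'
#' Formats assay-level results in the conventional column order:
#' Transcribed SNP, Gene, (MAF for blood panels), Het. samples, Risk
#' allele, Observed ASE, Overall P value. P values are shown to two
#' significant digits, in scientific notation when small.
#'
#' @param assays per-assay tibble from [run_ase()] (`$assays`).
#' @param maf optional named numeric vector of minor allele
#'   frequencies keyed by assay id; when supplied, a MAF column is
#'   included (blood-panel layout).
#' @param snp optional named character vector mapping assay id to the
#'   transcribed SNP rsID; defaults to the assay id itself.
#' @return tibble with display columns.
#' @export
render_assay_table <- function(assays, maf = NULL, snp = NULL) {
  snp_of <- function(id) {
    if (!is.null(snp) && id %in% names(snp)) snp[[id]] else id
  }
  out <- tibble::tibble(
    `Transcribed SNP` = vapply(assays$assay_id, snp_of, character(1)),
    Gene = assays$gene)
  if (!is.null(maf))
    out$MAF <- unname(maf[assays$assay_id])
  out$`Het. samples` <- assays$n_het
  out$`Risk allele` <- assays$risk_allele
  out$`Observed ASE` <- assays$direction_label
  out$`Overall P value` <- format_p_value(assays$overall_p)
  out
}

write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Run the end-to-end ASE pipeline from input files
#'
#' Ties the stages together: optional transcribed-marker selection,
#' optional assay calibration, heterozygote genotyping, the allelic
#' expression analysis, and (when two tissues are present)
#' cross-tissue classification. All outputs are written under
#' `outdir`; the run summary echoes every parameter and per-stage
#' count. Any stage failure aborts with the stage name and cause.
#'
#' @param plate_csv path to the plate-well CSV.
#' @param meta_csv path to the sample-metadata CSV.
#' @param assays_tsv path to the assay-metadata TSV (`assay_id`,
#'   `gene`, `risk_allele`, `fam_allele`, `vic_allele`).
#' @param outdir output directory.
#' @param candidates_tsv optional candidate-variant TSV; when given,
#'   the selection stage runs and its report is written.
#' @param mixture_csv optional mixture-series plate CSV; when given,
#'   each assay present is calibrated and failing assays are dropped
#'   from the ASE stage.
#' @param alpha,ct_cutoff,ld_threshold,het_window analysis parameters.
#' @return the run summary (a list), invisibly; outputs on disk.
#' @export
run_ase_pipeline <- function(plate_csv, meta_csv, assays_tsv, outdir,
                             candidates_tsv = NULL, mixture_csv = NULL,
                             alpha = 0.05, ct_cutoff = 36,
                             ld_threshold = 0.6, het_window = 1.5) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  for (p in c(plate_csv, meta_csv, assays_tsv, candidates_tsv, mixture_csv))
    if (!is.null(p) && !file.exists(p))
      stop("input file does not exist: ", p, call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  wells <- stage("read", read_plate_csv(plate_csv))
  meta <- stage("read", read_meta_csv(meta_csv))
  assays <- stage("read", tibble::as_tibble(
    utils::read.delim(assays_tsv, stringsAsFactors = FALSE, quote = "")))
  summary <- list(parameters = list(alpha = alpha, ct_cutoff = ct_cutoff,
                                    ld_threshold = ld_threshold,
                                    het_window = het_window),
                  counts = list())

  if (!is.null(candidates_tsv)) {
    sel <- stage("select", run_selection(read_candidates_tsv(candidates_tsv),
                                         ld_threshold = ld_threshold,
                                         ct_cutoff = ct_cutoff))
    write_selection_report(sel, file.path(outdir, "selection"))
    summary$counts$selected_markers <- nrow(sel$selected)
  }

  if (!is.null(mixture_csv)) {
    mix <- stage("calibrate", read_plate_csv(mixture_csv))
    cal <- stage("calibrate", lapply(split(mix, mix$assay_id),
                                     calibrate_assay))
    cal_tab <- dplyr::bind_rows(lapply(cal, function(r)
      tibble::tibble(assay_id = r$assay_id, slope = r$slope,
                     intercept = r$intercept, r_squared = r$r_squared,
                     verdict = r$verdict,
                     reasons = paste(r$reasons, collapse = ";"))))
    write_tsv(cal_tab, file.path(outdir, "calibration.tsv"))
    failed <- cal_tab$assay_id[cal_tab$verdict == "FAIL"]
    summary$counts$assays_failed_calibration <- length(failed)
    assays <- assays[!assays$assay_id %in% failed, , drop = FALSE]
  }

  geno <- stage("genotype", call_cohort(wells, meta,
                                        het_window = het_window,
                                        dropout_ct = ct_cutoff))
  write_tsv(geno$calls, file.path(outdir, "genotype_calls.tsv"))
  write_tsv(geno$roster, file.path(outdir, "heterozygote_roster.tsv"))
  summary$counts$heterozygotes <- nrow(geno$roster)

  res <- stage("ase", run_ase(wells, meta, geno$roster, assays,
                              alpha = alpha, ct_cutoff = ct_cutoff))
  write_tsv(res$samples, file.path(outdir, "ase_samples.tsv"))
  write_tsv(res$assays, file.path(outdir, "ase_assays.tsv"))
  write_tsv(res$exclusions, file.path(outdir, "exclusions.tsv"))
  write_tsv(render_assay_table(res$assays),
            file.path(outdir, "assay_table.tsv"))
  summary$counts$assays_reported <- nrow(res$assays)
  summary$counts$replicates_excluded <- nrow(res$exclusions)

  tissues <- unique(res$assays$tissue)
  if (all(c("brain", "blood") %in% tissues)) {
    cmp <- stage("compare",
                 compare_tissues(res$assays[res$assays$tissue == "brain", ],
                                 res$assays[res$assays$tissue == "blood", ]))
    write_tsv(cmp, file.path(outdir, "tissue_comparison.tsv"))
  }

  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Simulation-to-report demonstration run
#'
#' Generates a small synthetic study with three assays — one with
#' concordant allelic imbalance in brain and blood, one with a
#' brain-specific effect, and one balanced — then genotypes the
#' cohort, runs the ASE analysis per tissue, classifies the
#' cross-tissue patterns, and writes all output tables under
#' `outdir`. Fully deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param outdir output directory.
#' @param n_donors donors per tissue cohort (default 60).
#' @return list with `assays`, `samples`, `comparison` and
#'   `assay_table` tibbles (also written to `outdir`).
#' @export
run_demo <- function(seed = 1, outdir = tempfile("aseqpcr_demo_"),
                     n_donors = 60) {
  scenarios <- tibble::tibble(
    assay_id = c("assayA", "assayB", "assayC"),
    gene = c("GENEA", "GENEB", "GENEC"),
    phi_brain = c(1.7, 1.6, 1),
    phi_blood = c(1.7, 1.0, 1),
    risk_allele = c("A", "T", "G"),
    fam_allele = c("A", "C", "A"),
    vic_allele = c("G", "T", "G"))
  wells <- list(); meta <- list()
  for (i in seq_len(nrow(scenarios))) {
    for (tis in c("brain", "blood")) {
      phi <- if (tis == "brain") scenarios$phi_brain[i]
             else scenarios$phi_blood[i]
      cfg <- sim_config(seed = seed + 101 * i +
                          7 * match(tis, c("brain", "blood")),
                        n_donors = n_donors, true_fold_change = phi,
                        tissues = tis, assay_id = scenarios$assay_id[i])
      sim <- simulate_study(cfg)
      wells[[length(wells) + 1]] <- sim$wells
      meta[[length(meta) + 1]] <- sim$meta
    }
  }
  wells <- dplyr::bind_rows(wells)
  meta <- dplyr::distinct(dplyr::bind_rows(meta))
  geno <- call_cohort(wells, meta)
  res <- run_ase(wells, meta, geno$roster, scenarios)
  cmp <- compare_tissues(res$assays[res$assays$tissue == "brain", ],
                         res$assays[res$assays$tissue == "blood", ])
  tab <- render_assay_table(res$assays[res$assays$tissue == "brain", ])
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_plate_csv(wells, file.path(outdir, "plate.csv"))
  write_meta_csv(meta, file.path(outdir, "meta.csv"))
  write_tsv(res$samples, file.path(outdir, "ase_samples.tsv"))
  write_tsv(res$assays, file.path(outdir, "ase_assays.tsv"))
  write_tsv(cmp, file.path(outdir, "tissue_comparison.tsv"))
  write_tsv(tab, file.path(outdir, "assay_table_brain.tsv"))
  invisible(list(assays = res$assays, samples = res$samples,
                 comparison = cmp, assay_table = tab, outdir = outdir))
}
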