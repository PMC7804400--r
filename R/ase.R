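#' Per-replicate allelic ratio on the Ct scale
#'
#' Adds `delta_ct = ct_fam - ct_vic` to a plate-well table. dCt is the
#' log2-scale allelic ratio as seen by the instrument: one Ct of
#' difference corresponds to a two-fold template difference at full
#' amplification efficiency, with lower Ct meaning more template. A
#' well with an undetermined channel gets `NA` — absence is a value
#' here, not an error.
#'
#' @param wells plate-well tibble with `ct_fam` and `ct_vic` columns.
#' @return `wells` with a `delta_ct` column appended.
#' @export
compute_delta_ct <- function(wells) {
  dplyr::mutate(wells, delta_ct = .data$ct_fam - .data$ct_vic)
}

#' Exclude unreliable replicates and under-measured samples
#'
#' A replicate is dropped when either dye channel is undetermined or
#' above `ct_cutoff` (very low template cannot be quantified reliably).
#' A sample is then dropped entirely when fewer than `min_replicates`
#' replicates survive, so that no sample is carried by one or two
#' measurements. Every drop is logged with a machine-readable reason.
#'
#' @param wells plate-well tibble.
#' @param ct_cutoff expression cutoff; replicates with any channel
#'   strictly above it are removed (default 36).
#' @param min_replicates minimum surviving replicates per sample
#'   (default 3).
#' @return list with `wells` (retained rows) and `log` (tibble of
#'   dropped rows: `sample_id`, `assay_id`, `replicate`, `reason`).
#' @export
apply_ct_exclusion <- function(wells, ct_cutoff = 36, min_replicates = 3) {
  stopifnot(ct_cutoff > 0, min_replicates >= 1)
  undet <- is.na(wells$ct_fam) | is.na(wells$ct_vic)
  high <- !undet & (wells$ct_fam > ct_cutoff | wells$ct_vic > ct_cutoff)
  reason <- rep(NA_character_, nrow(wells))
  reason[undet] <- "CHANNEL_UNDETERMINED"
  reason[high] <- "CT_ABOVE_CUTOFF"
  kept <- wells[!undet & !high, , drop = FALSE]

  counts <- table(paste(kept$sample_id, kept$assay_id, sep = "\r"))
  key <- paste(kept$sample_id, kept$assay_id, sep = "\r")
  starved <- key %in% names(counts)[counts < min_replicates]
  log <- dplyr::bind_rows(
    tibble::tibble(sample_id = wells$sample_id[!is.na(reason)],
                   assay_id = wells$assay_id[!is.na(reason)],
                   replicate = wells$replicate[!is.na(reason)],
                   reason = reason[!is.na(reason)]),
    tibble::tibble(sample_id = kept$sample_id[starved],
                   assay_id = kept$assay_id[starved],
                   replicate = kept$replicate[starved],
                   reason = "TOO_FEW_REPLICATES")
  )
  list(wells = kept[!starved, , drop = FALSE], log = log)
}

#' Normalize cDNA allelic ratios against the gDNA baseline
#'
#' Heterozygous genomic DNA carries the two alleles at an obligate 1:1
#' ratio, so its mean dCt measures the assay's dye and amplification
#' bias. Subtracting it from each cDNA dCt yields the normalized dCt
#' (nDCt), for which 0 means balanced allelic expression:
#' `nDCt = dCt(cDNA replicate) - mean(dCt of all gDNA replicates)`.
#'
#' @param delta_ct cDNA replicate dCt values.
#' @param gdna_delta_ct dCt values of all heterozygous gDNA replicates
#'   for the same assay.
#' @return nDCt values, same length as `delta_ct`.
#' @export
normalize_delta_ct <- function(delta_ct, gdna_delta_ct) {
  gdna_delta_ct <- gdna_delta_ct[!is.na(gdna_delta_ct)]
  if (length(gdna_delta_ct) == 0)
    stop("normalization impossible: no heterozygous gDNA dCt values",
         call. = FALSE)
  delta_ct - mean(gdna_delta_ct)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Wilcoxon rank-sum (Mann-Whitney U) test of two independent groups
#' with midrank tie handling. Uses the exact null distribution when
#' both groups are untied and `n + m <= exact_max`; otherwise the
#' normal approximation with tie correction (and continuity correction
#' by default). When all pooled values are identical there is no
#' ordering information and the p-value is 1 by convention, flagged as
#' degenerate.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_max largest `n + m` for which the exact distribution is
#'   used (default 12).
#' @param correct apply continuity correction in the approximate
#'   branch (default `TRUE`).
#' @return list with `statistic` (the U statistic for `x`), `p_value`,
#'   `exact` (logical), `tied` (logical) and `degenerate` (logical).
#' @export
rank_sum_test <- function(x, y, exact_max = 12, correct = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(pooled)
  tied <- any(ties > 1)

  if (length(ties) == 1)  # every pooled value identical: no information
    return(list(statistic = U, p_value = 1, exact = FALSE, tied = TRUE,
                degenerate = TRUE))

  if (!tied && n + m <= exact_max) {
    p <- if (U > n * m / 2)
      stats::pwilcox(U - 1, n, m, lower.tail = FALSE)
    else
      stats::pwilcox(U, n, m)
    return(list(statistic = U, p_value = min(2 * p, 1), exact = TRUE,
                tied = FALSE, degenerate = FALSE))
  }

  z <- U - n * m / 2
  sigma <- sqrt((n * m / 12) *
                  ((n + m + 1) -
                     sum(ties^3 - ties) / ((n + m) * (n + m - 1))))
  if (sigma == 0)
    return(list(statistic = U, p_value = 1, exact = FALSE, tied = tied,
                degenerate = TRUE))
  if (correct) z <- z - sign(z) * 0.5
  z <- z / sigma
  p <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  list(statistic = U, p_value = min(p, 1), exact = FALSE, tied = tied,
       degenerate = FALSE)
}

#' Shapiro-Wilk normality screen for allelic-ratio measurements
#'
#' Screens the cDNA and gDNA dCt distributions for normality. The
#' screen documents why a nonparametric test is appropriate; it never
#' switches the analysis — the pipeline always uses the rank-sum test.
#' Groups smaller than 3 are skipped with a note.
#'
#' @param cdna_delta,gdna_delta dCt values per group.
#' @param alpha screening level (default 0.05).
#' @return list with `table` (per-group W, p, rejected/skipped) and
#'   `any_rejected`.
#' @export
normality_screen <- function(cdna_delta, gdna_delta, alpha = 0.05) {
  groups <- list(cDNA = cdna_delta[!is.na(cdna_delta)],
                 gDNA = gdna_delta[!is.na(gdna_delta)])
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (length(v) < 3)
      return(tibble::tibble(group = g, n = length(v), W = NA_real_,
                            p_value = NA_real_, rejected = NA,
                            note = "skipped: fewer than 3 values"))
    res <- tryCatch(stats::shapiro.test(v), error = function(e) NULL)
    if (is.null(res))
      return(tibble::tibble(group = g, n = length(v), W = NA_real_,
                            p_value = NA_real_, rejected = NA,
                            note = "skipped: degenerate sample"))
    tibble::tibble(group = g, n = length(v),
                   W = unname(res$statistic), p_value = res$p.value,
                   rejected = res$p.value < alpha, note = "")
  })
  tab <- dplyr::bind_rows(rows)
  list(table = tab, any_rejected = isTRUE(any(tab$rejected, na.rm = TRUE)))
}

direction_label <- function(mean_ndct, detected, fam_allele, vic_allele) {
  # lower Ct = more template, so negative nDCt means the FAM allele is
  # the more expressed one
  if (!detected) return(paste0(fam_allele, "=", vic_allele))
  if (mean_ndct < 0) paste0(fam_allele, ">", vic_allele)
  else paste0(fam_allele, "<", vic_allele)
}

more_expressed_allele <- function(mean_ndct, detected, fam_allele,
                                  vic_allele) {
  if (!detected) return(NA_character_)
  if (mean_ndct < 0) fam_allele else vic_allele
}

#' Per-sample allelic expression results for one assay
#'
#' For each heterozygous cDNA sample: replicate dCt values, mean dCt,
#' nDCt (gDNA-normalized), fold change `2^|nDCt|`, and a rank-sum test
#' of the sample's replicate dCt values against the gDNA comparator.
#' The default comparator pools all heterozygous gDNA replicate dCt
#' values; `comparator = "means"` instead uses the per-sample gDNA
#' mean dCt values.
#'
#' @param cdna_wells excluded-and-filtered cDNA wells with `delta_ct`.
#' @param gdna_wells heterozygous gDNA wells with `delta_ct`.
#' @param meta sample metadata.
#' @param alpha significance level (default 0.05).
#' @param comparator `"pooled"` (default) or `"means"`.
#' @param p_adjust `"none"` (default, mirroring conventional small-panel
#'   reporting) or `"BH"` to apply Benjamini-Hochberg correction across
#'   the per-sample tests before calling significance.
#' @return tibble, one row per cDNA sample.
#' @export
ase_sample_results <- function(cdna_wells, gdna_wells, meta, alpha = 0.05,
                               comparator = c("pooled", "means"),
                               p_adjust = c("none", "BH")) {
  comparator <- match.arg(comparator)
  p_adjust <- match.arg(p_adjust)
  gdna_delta <- gdna_wells$delta_ct[!is.na(gdna_wells$delta_ct)]
  if (length(gdna_delta) == 0)
    stop("no heterozygous gDNA measurements to normalize against",
         call. = FALSE)
  comp <- if (comparator == "pooled") gdna_delta else {
    tapply(gdna_wells$delta_ct, gdna_wells$sample_id, mean, na.rm = TRUE)
  }
  gdna_mean <- mean(gdna_delta)
  res <- dplyr::bind_rows(lapply(split(cdna_wells, cdna_wells$sample_id),
                          function(sw) {
    d <- sw$delta_ct[!is.na(sw$delta_ct)]
    m <- meta[match(sw$sample_id[1], meta$sample_id), ]
    test <- rank_sum_test(d, as.numeric(comp))
    ndct <- mean(d) - gdna_mean
    tibble::tibble(
      sample_id = sw$sample_id[1], assay_id = sw$assay_id[1],
      donor_id = m$donor_id, tissue = m$tissue, diagnosis = m$diagnosis,
      n_replicates_used = length(d),
      mean_delta_ct = mean(d), n_delta_ct = ndct,
      fold_change = 2^abs(ndct),
      p_value = test$p_value, significant = test$p_value <= alpha)
  }))
  if (p_adjust == "BH") {
    res$p_value <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_value <= alpha
  }
  res
}

#' Pooled per-assay allelic expression summary
#'
#' The assay-level ASE verdict: a rank-sum test of all heterozygous
#' cDNA replicate dCt values pooled against all heterozygous gDNA
#' replicate dCt values. ASE is called iff the pooled p-value is at
#' most `alpha`. The direction label maps the sign of the mean nDCt
#' through the assay's dye-to-allele orientation (negative nDCt: the
#' FAM-labelled allele is over-expressed), and the risk-allele
#' direction says whether the GWAS risk allele is the more or less
#' expressed one. Also reported: a consistency metric (fraction of
#' individually significant samples sharing the pooled sign) and a
#' PD-versus-control comparison of sample-level nDCt.
#'
#' @param samples per-sample tibble from [ase_sample_results()].
#' @param cdna_delta,gdna_delta pooled replicate dCt values.
#' @param assay_info one-row tibble or list with `assay_id`, `gene`,
#'   `risk_allele`, `fam_allele`, `vic_allele`.
#' @param alpha significance level (default 0.05).
#' @param tissue tissue label for the summary row.
#' @return one-row tibble (assay verdict).
#' @export
assay_summary <- function(samples, cdna_delta, gdna_delta, assay_info,
                          alpha = 0.05, tissue = NA_character_) {
  if (nrow(samples) == 0)
    stop("assay ", assay_info$assay_id,
         ": no heterozygous cDNA samples to summarise", call. = FALSE)
  overall <- rank_sum_test(cdna_delta[!is.na(cdna_delta)],
                           gdna_delta[!is.na(gdna_delta)])
  detected <- overall$p_value <= alpha
  mean_ndct <- mean(samples$n_delta_ct)
  label <- direction_label(mean_ndct, detected,
                           assay_info$fam_allele, assay_info$vic_allele)
  more <- more_expressed_allele(mean_ndct, detected,
                                assay_info$fam_allele,
                                assay_info$vic_allele)
  rad <- if (!detected) "none"
         else if (identical(more, assay_info$risk_allele)) "more" else "less"
  sig <- samples[samples$significant, , drop = FALSE]
  consistency <- if (nrow(sig) == 0) NA_real_
                 else mean(sign(sig$n_delta_ct) == sign(mean_ndct))
  pd <- samples$n_delta_ct[samples$diagnosis == "PD"]
  ctrl <- samples$n_delta_ct[samples$diagnosis == "control"]
  p_dx <- if (length(pd) > 0 && length(ctrl) > 0)
    rank_sum_test(pd, ctrl)$p_value else NA_real_
  tibble::tibble(
    assay_id = assay_info$assay_id, gene = assay_info$gene,
    tissue = tissue, n_het = nrow(samples),
    risk_allele = assay_info$risk_allele,
    direction_label = label, risk_allele_direction = rad,
    overall_p = overall$p_value, ase_detected = detected,
    mean_n_delta_ct = mean_ndct, fold_change = 2^abs(mean_ndct),
    consistency = consistency,
    mean_n_delta_ct_pd = if (length(pd)) mean(pd) else NA_real_,
    mean_n_delta_ct_control = if (length(ctrl)) mean(ctrl) else NA_real_,
    p_diagnosis = p_dx)
}

#' Run the allelic expression analysis across assays and tissues
#'
#' The core analysis: for every assay and tissue, take the
#' heterozygous donors from the genotype roster, apply the Ct
#' exclusion rules to their cDNA and gDNA wells, compute dCt and
#' gDNA-normalized nDCt, test each sample and the pooled assay with
#' the rank-sum test, and label the direction of imbalance.
#'
#' @param wells plate wells for all samples and assays.
#' @param meta sample metadata.
#' @param roster heterozygote roster from [call_cohort()].
#' @param assays assay metadata tibble: `assay_id`, `gene`,
#'   `risk_allele`, `fam_allele`, `vic_allele`.
#' @param alpha significance level (default 0.05).
#' @param ct_cutoff,min_replicates exclusion rules
#'   (see [apply_ct_exclusion()]).
#' @param comparator per-sample comparator (see
#'   [ase_sample_results()]).
#' @param p_adjust per-sample multiple-testing correction, `"none"`
#'   (default) or `"BH"` (see [ase_sample_results()]); never affects
#'   the pooled assay-level verdict.
#' @return list with `samples`, `assays`, `exclusions` and `screens`.
#' @export
run_ase <- function(wells, meta, roster, assays, alpha = 0.05,
                    ct_cutoff = 36, min_replicates = 3,
                    comparator = "pooled", p_adjust = "none") {
  stopifnot(all(c("assay_id", "gene", "risk_allele", "fam_allele",
                  "vic_allele") %in% names(assays)))
  samples_out <- list(); assays_out <- list(); logs <- list()
  screens <- list()
  for (i in seq_len(nrow(assays))) {
    info <- assays[i, ]
    aw <- wells[wells$assay_id == info$assay_id, , drop = FALSE]
    for (tis in unique(roster$tissue[roster$assay_id == info$assay_id])) {
      het_donors <- roster$donor_id[roster$assay_id == info$assay_id &
                                      roster$tissue == tis]
      tmeta <- meta[meta$tissue == tis & meta$donor_id %in% het_donors, ]
      gids <- tmeta$sample_id[tmeta$material == "gDNA"]
      cids <- tmeta$sample_id[tmeta$material == "cDNA"]
      filt <- apply_ct_exclusion(aw[aw$sample_id %in% c(gids, cids), ],
                                 ct_cutoff, min_replicates)
      logs[[length(logs) + 1]] <- filt$log
      w <- compute_delta_ct(filt$wells)
      gw <- w[w$sample_id %in% gids, , drop = FALSE]
      cw <- w[w$sample_id %in% cids, , drop = FALSE]
      if (nrow(cw) == 0 || nrow(gw) == 0) next
      screens[[paste(info$assay_id, tis)]] <-
        normality_screen(cw$delta_ct, gw$delta_ct, alpha)
      smp <- ase_sample_results(cw, gw, meta, alpha, comparator, p_adjust)
      samples_out[[length(samples_out) + 1]] <- smp
      assays_out[[length(assays_out) + 1]] <-
        assay_summary(smp, cw$delta_ct, gw$delta_ct, info, alpha, tis)
    }
  }
  list(samples = dplyr::bind_rows(samples_out),
       assays = dplyr::bind_rows(assays_out),
       exclusions = dplyr::bind_rows(logs),
       screens = screens)
}

#' Classify cross-tissue allelic expression patterns
#'
#' Joins per-assay ASE verdicts from two tissues and classifies each
#' assay: `concordant_ase` (detected in both, same direction),
#' `discordant_direction` (detected in both, opposite directions),
#' `brain_specific` / `blood_specific` (detected in one), `no_ase`
#' (detected in neither), or `incomparable` when the assay was only
#' run in one tissue.
#'
#' @param brain,blood per-assay tibbles from [run_ase()] (`$assays`).
#' @return tibble, one row per assay, with both verdicts and the class.
#' @export
compare_tissues <- function(brain, blood) {
  ids <- union(brain$assay_id, blood$assay_id)
  rows <- lapply(ids, function(id) {
    b <- brain[brain$assay_id == id, , drop = FALSE]
    w <- blood[blood$assay_id == id, , drop = FALSE]
    if (nrow(b) == 0 || nrow(w) == 0) {
      return(tibble::tibble(
        assay_id = id,
        gene = c(b$gene, w$gene)[1],
        brain_ase = if (nrow(b)) b$ase_detected else NA,
        blood_ase = if (nrow(w)) w$ase_detected else NA,
        brain_direction = if (nrow(b)) b$direction_label else NA_character_,
        blood_direction = if (nrow(w)) w$direction_label else NA_character_,
        class = "incomparable"))
    }
    cls <- if (b$ase_detected && w$ase_detected) {
      if (sign(b$mean_n_delta_ct) == sign(w$mean_n_delta_ct))
        "concordant_ase" else "discordant_direction"
    } else if (b$ase_detected) "brain_specific"
      else if (w$ase_detected) "blood_specific"
      else "no_ase"
    tibble::tibble(assay_id = id, gene = b$gene,
                   brain_ase = b$ase_detected, blood_ase = w$ase_detected,
                   brain_direction = b$direction_label,
                   blood_direction = w$direction_label, class = cls)
  })
  dplyr::bind_rows(rows)
}
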