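#' Call a genotype from replicate gDNA Ct pairs
#'
#' Calls one gDNA sample on one allele-discrimination assay from its
#' replicate Ct pairs. A channel that is undetermined or beyond
#' `dropout_ct` in every replicate while the other channel amplifies
#' indicates a homozygote for the amplifying channel's allele. When
#' both channels amplify, the sample is heterozygous if its mean dCt
#' (FAM - VIC) lies within `het_window` of the assay's dye-bias
#' estimate — the dCt a true 1:1 template produces. Anything
#' ambiguous is `NO_CALL`; the caller is never forced.
#'
#' @param wells replicate plate wells for a single gDNA sample and
#'   assay.
#' @param het_window half-width (Ct) of the heterozygote acceptance
#'   window around the dye-bias estimate (default 1.5, half the ~3 Ct
#'   separation a homozygote-vs-heterozygote template difference
#'   produces at full efficiency).
#' @param dropout_ct Ct above which a gDNA channel is treated as
#'   failed (default 36).
#' @param dye_bias_estimate expected dCt of a balanced template for
#'   this assay (default 0; see [estimate_dye_bias()]).
#' @param material material of the sample; genotypes are called from
#'   gDNA only, and cDNA input is rejected (allelic imbalance in cDNA
#'   would masquerade as genotype).
#' @return a one-row tibble: `sample_id`, `assay_id`, `call`
#'   (`HOM_FAM`, `HET`, `HOM_VIC` or `NO_CALL`), `delta_ct`,
#'   `quality_note`.
#' @export
call_genotype <- function(wells, het_window = 1.5, dropout_ct = 36,
                          dye_bias_estimate = 0, material = "gDNA") {
  if (!identical(material, "gDNA"))
    stop("genotype calls are gDNA-only; got material '", material, "'",
         call. = FALSE)
  stopifnot(nrow(wells) >= 1)
  if (length(unique(wells$sample_id)) > 1 ||
      length(unique(wells$assay_id)) > 1)
    stop("call_genotype() expects wells from one sample and one assay",
         call. = FALSE)
  fam_ok <- !is.na(wells$ct_fam) & wells$ct_fam <= dropout_ct
  vic_ok <- !is.na(wells$ct_vic) & wells$ct_vic <= dropout_ct

  out <- function(call, delta, note) {
    tibble::tibble(sample_id = wells$sample_id[1],
                   assay_id = wells$assay_id[1],
                   call = call, delta_ct = delta, quality_note = note)
  }
  if (!any(fam_ok) && !any(vic_ok))
    return(out("NO_CALL", NA_real_, "no amplification in either channel"))
  if (!any(vic_ok))
    return(out("HOM_FAM", NA_real_, "VIC channel dropped out"))
  if (!any(fam_ok))
    return(out("HOM_VIC", NA_real_, "FAM channel dropped out"))

  both <- fam_ok & vic_ok
  if (!any(both))
    return(out("NO_CALL", NA_real_,
               "channels never amplified in the same replicate"))
  delta <- mean(wells$ct_fam[both] - wells$ct_vic[both])
  if (abs(delta - dye_bias_estimate) <= het_window)
    out("HET", delta, sprintf("mean dCt %.2f within het window", delta))
  else
    out("NO_CALL", delta,
        sprintf("mean dCt %.2f outside het window around %.2f",
                delta, dye_bias_estimate))
}

#' Estimate per-assay dye bias from bi-allelic gDNA samples
#'
#' The dCt a genuinely balanced (1:1) template produces is not zero
#' when the dyes amplify unequally. This estimates it as the median
#' mean-dCt of confidently bi-allelic gDNA samples — samples whose
#' two channels are determined and below `dropout_ct` in every
#' replicate. The median is robust to the occasional extreme sample.
#'
#' @param wells gDNA plate wells for one assay.
#' @param dropout_ct channel-failure cutoff (default 36).
#' @return the median dCt, or 0 (with a warning) when no sample
#'   qualifies.
#' @export
estimate_dye_bias <- function(wells, dropout_ct = 36) {
  per_sample <- wells %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      biallelic = all(!is.na(.data$ct_fam) & .data$ct_fam <= dropout_ct &
                        !is.na(.data$ct_vic) & .data$ct_vic <= dropout_ct),
      delta = mean(.data$ct_fam - .data$ct_vic), .groups = "drop")
  vals <- per_sample$delta[per_sample$biallelic]
  if (length(vals) == 0) {
    warning("no confidently bi-allelic gDNA sample; assuming dye bias 0",
            call. = FALSE)
    return(0)
  }
  stats::median(vals)
}

#' Genotype a cohort and build the heterozygote roster
#'
#' Calls every (gDNA sample, assay) pair and lists the heterozygous
#' donors per assay and tissue — the donors informative for allelic
#' expression. The per-assay dye-bias estimate is computed once from
#' the cohort's bi-allelic samples and shared across calls.
#'
#' @param wells plate wells (any materials; only gDNA is genotyped).
#' @param meta sample metadata tibble (see [simulate_study()]).
#' @param het_window,dropout_ct as in [call_genotype()].
#' @return list with `calls` (one row per sample x assay) and
#'   `roster` (heterozygous donors per assay and tissue).
#' @export
call_cohort <- function(wells, meta, het_window = 1.5, dropout_ct = 36) {
  gmeta <- meta[meta$material == "gDNA", , drop = FALSE]
  gw <- wells[wells$sample_id %in% gmeta$sample_id, , drop = FALSE]
  if (anyDuplicated(gw[, c("sample_id", "assay_id", "replicate")]))
    stop("duplicate (sample, assay, replicate) wells in gDNA input",
         call. = FALSE)
  empty_calls <- tibble::tibble(sample_id = character(),
                                assay_id = character(), call = character(),
                                delta_ct = numeric(),
                                quality_note = character())
  empty_roster <- tibble::tibble(assay_id = character(), tissue = character(),
                                 donor_id = character(),
                                 sample_id = character())
  if (nrow(gw) == 0) return(list(calls = empty_calls, roster = empty_roster))

  calls <- dplyr::bind_rows(lapply(split(gw, gw$assay_id), function(aw) {
    bias <- estimate_dye_bias(aw, dropout_ct)
    dplyr::bind_rows(lapply(split(aw, aw$sample_id), call_genotype,
                            het_window = het_window,
                            dropout_ct = dropout_ct,
                            dye_bias_estimate = bias))
  }))
  hets <- calls[calls$call == "HET", , drop = FALSE]
  roster <- dplyr::left_join(hets, gmeta, by = "sample_id") %>%
    dplyr::select(assay_id = "assay_id", tissue = "tissue",
                  donor_id = "donor_id", sample_id = "sample_id") %>%
    dplyr::arrange(.data$assay_id, .data$tissue, .data$donor_id)
  list(calls = tibble::as_tibble(calls),
       roster = if (nrow(roster)) roster else empty_roster)
}
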