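#' @importFrom dplyr %>%
NULL

ANNOTATIONS <- c("synonymous", "missense", "3'UTR", "5'UTR",
                 "intronic", "intergenic")
TRANSCRIBED_ANNOTATIONS <- c("synonymous", "missense", "3'UTR", "5'UTR")
CODING_ANNOTATIONS <- c("synonymous", "missense")

#' Selection reports
#'
#' Every selection filter partitions its input candidate table into a
#' `selected` tibble and an `excluded` tibble carrying a `reason` code
#' from a closed enumeration (`LOW_LD`, `NOT_TRANSCRIBED`,
#' `INVERSION_LOCUS`, `ISOFORM_RESTRICTED`, `ASSAY_FAILED`,
#' `LOW_EXPRESSION`, `NOT_SELECTED_PER_LOCUS`). `counts` records how
#' many candidates each stage removed.
#'
#' @param selected,excluded candidate tibbles; `excluded` has a
#'   `reason` column.
#' @param counts named integer vector of per-stage exclusion counts.
#' @return an object of class `selection_report`.
#' @keywords internal
selection_report <- function(selected, excluded, counts = integer(0)) {
  structure(list(selected = selected, excluded = excluded, counts = counts),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Selection report: %d selected, %d excluded\n",
              nrow(x$selected), nrow(x$excluded)))
  if (length(x$counts)) {
    for (nm in names(x$counts))
      cat(sprintf("  %-24s -%d\n", nm, x$counts[[nm]]))
  }
  if (nrow(x$excluded)) {
    tab <- table(x$excluded$reason)
    cat("  exclusion reasons:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

empty_excluded <- function(candidates) {
  dplyr::mutate(candidates[0, , drop = FALSE], reason = character(0))
}

validate_candidates <- function(candidates) {
  needed <- c("lead_snp", "proxy_snp", "gene", "r2", "annotation", "locus_id")
  missing <- setdiff(needed, names(candidates))
  if (length(missing))
    stop("candidate table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!is.na(candidates$r2) & (candidates$r2 < 0 | candidates$r2 > 1)))
    stop("r2 must lie in [0, 1]", call. = FALSE)
  invisible(candidates)
}

#' Filter candidates on linkage disequilibrium with the lead SNP
#'
#' Retains transcribed proxy candidates whose LD correlation with the
#' lead SNP satisfies `r2 >= threshold` (inclusive); the default
#' threshold of 0.6 is the conventional cut-off for a proxy to act as a
#' marker of the association signal.
#'
#' @param candidates candidate-variant tibble (see [pd_candidates()]).
#' @param threshold minimum r-squared, in `[0, 1]`.
#' @return a [selection_report()].
#' @export
filter_ld <- function(candidates, threshold = 0.6) {
  validate_candidates(candidates)
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- candidates$r2 >= threshold
  excl <- candidates[!keep, , drop = FALSE]
  excl$reason <- rep("LOW_LD", nrow(excl))
  selection_report(candidates[keep, , drop = FALSE], excl,
                   c(LOW_LD = sum(!keep)))
}

#' Filter candidates to transcribed regions
#'
#' Only variants located in mature transcripts (coding or UTR) can
#' serve as allelic markers in cDNA; intronic and intergenic candidates
#' are excluded with reason `NOT_TRANSCRIBED`.
#'
#' @inheritParams filter_ld
#' @return a [selection_report()].
#' @export
filter_transcribed <- function(candidates) {
  validate_candidates(candidates)
  unknown <- setdiff(unique(candidates$annotation), ANNOTATIONS)
  if (length(unknown))
    stop("unknown functional annotation label(s): ",
         paste(unknown, collapse = ", "),
         "; expected one of ", paste(ANNOTATIONS, collapse = ", "),
         call. = FALSE)
  keep <- candidates$annotation %in% TRANSCRIBED_ANNOTATIONS
  excl <- candidates[!keep, , drop = FALSE]
  excl$reason <- rep("NOT_TRANSCRIBED", nrow(excl))
  selection_report(candidates[keep, , drop = FALSE], excl,
                   c(NOT_TRANSCRIBED = sum(!keep)))
}

#' Exclude candidates in problematic genomic contexts
#'
#' Removes candidates flagged as lying within a complex polymorphic
#' inversion region (where assay interpretation is confounded by the
#' inversion haplotypes) and candidates present only in a restricted
#' transcript isoform (which would report a sub-population of the
#' gene's mRNA rather than total expression).
#'
#' @inheritParams filter_ld
#' @return a [selection_report()].
#' @export
filter_special_regions <- function(candidates) {
  validate_candidates(candidates)
  inv <- isTRUE_vec(candidates$in_inversion_region)
  iso <- !inv & isTRUE_vec(candidates$isoform_restricted)
  keep <- !(inv | iso)
  excl <- candidates[!keep, , drop = FALSE]
  excl$reason <- as.character(ifelse(inv[!keep], "INVERSION_LOCUS",
                                     "ISOFORM_RESTRICTED"))
  selection_report(candidates[keep, , drop = FALSE], excl,
                   c(INVERSION_LOCUS = sum(inv),
                     ISOFORM_RESTRICTED = sum(iso)))
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Exclude assays that failed sensitivity calibration
#'
#' A candidate whose genotyping assay failed the mixture-ratio
#' sensitivity check (flagged `assay_failed`) is removed with reason
#' `ASSAY_FAILED`; a replacement assay for the same gene enters the
#' table as an ordinary candidate row.
#'
#' @inheritParams filter_ld
#' @return a [selection_report()].
#' @export
filter_failed_assays <- function(candidates) {
  validate_candidates(candidates)
  fail <- isTRUE_vec(candidates$assay_failed)
  excl <- candidates[fail, , drop = FALSE]
  excl$reason <- rep("ASSAY_FAILED", nrow(excl))
  selection_report(candidates[!fail, , drop = FALSE], excl,
                   c(ASSAY_FAILED = sum(fail)))
}

#' Low-expression exclusion rule for a single assay
#'
#' An assay is uninformative when the target gene is barely expressed:
#' the rule excludes an assay iff strictly more than `fraction` of its
#' cDNA samples yielded Ct above `ct_cutoff`. An undetermined Ct counts
#' as exceeding the cutoff.
#'
#' @param cdna_cts numeric Ct values, `NA` for undetermined reactions.
#' @param ct_cutoff expression cutoff (default 36, the conventional
#'   bound beyond which template levels are too low to quantify).
#' @param fraction exclusion fraction (default 0.5).
#' @return `TRUE` to retain the assay, `FALSE` to exclude it.
#' @export
filter_low_expression <- function(cdna_cts, ct_cutoff = 36, fraction = 0.5) {
  if (length(cdna_cts) == 0)
    stop("no cDNA Ct values supplied for the low-expression rule",
         call. = FALSE)
  high <- is.na(cdna_cts) | cdna_cts > ct_cutoff
  mean(high) <= fraction
}

annotation_rank <- function(annotation) {
  # coding beats UTR when LD ties
  match(annotation, c("synonymous", "missense", "3'UTR", "5'UTR"),
        nomatch = 5L)
}

#' Choose one transcribed marker per locus and gene
#'
#' Keeps, per (locus, gene) pair, the single candidate with the highest
#' LD to the lead signal. A lead SNP that is itself transcribed is
#' always preferred; LD ties are broken by annotation (coding over
#' UTR), then by rsID. Candidates flagged as independent secondary
#' association signals are exempt from the cap and always retained.
#' Grouping by gene as well as locus keeps both genes when one lead SNP
#' tags transcribed markers in two genes.
#'
#' @inheritParams filter_ld
#' @return a [selection_report()].
#' @export
select_one_per_locus <- function(candidates) {
  validate_candidates(candidates)
  if (nrow(candidates) == 0)
    return(selection_report(candidates, empty_excluded(candidates),
                            c(NOT_SELECTED_PER_LOCUS = 0L)))
  secondary <- isTRUE_vec(candidates$is_secondary_signal)
  pool <- candidates[!secondary, , drop = FALSE]
  ranked <- pool %>%
    dplyr::mutate(.lead_is_marker = .data$proxy_snp == .data$lead_snp,
                  .ann_rank = annotation_rank(.data$annotation)) %>%
    dplyr::arrange(.data$locus_id, .data$gene,
                   dplyr::desc(.data$.lead_is_marker),
                   dplyr::desc(.data$r2), .data$.ann_rank,
                   .data$proxy_snp) %>%
    dplyr::group_by(.data$locus_id, .data$gene) %>%
    dplyr::mutate(chosen = dplyr::row_number() == 1L) %>%
    dplyr::ungroup()
  kept_ids <- ranked$proxy_snp[ranked$chosen]
  keep <- secondary | candidates$proxy_snp %in% kept_ids
  excl <- candidates[!keep, , drop = FALSE]
  excl$reason <- rep("NOT_SELECTED_PER_LOCUS", nrow(excl))
  selection_report(candidates[keep, , drop = FALSE], excl,
                   c(NOT_SELECTED_PER_LOCUS = sum(!keep)))
}

#' Run the full transcribed-marker selection workflow
#'
#' Composes the selection filters in order: LD threshold, transcribed
#' region, special-region exclusions (inversion locus, isoform
#' restriction), failed-assay exclusion, low-expression exclusion (when
#' cDNA Ct data are supplied), and the one-marker-per-locus choice.
#' Every input candidate appears exactly once in `selected` or
#' `excluded`.
#'
#' @inheritParams filter_ld
#' @param cdna_ct optional tibble of cDNA expression screens with
#'   columns `proxy_snp`, `sample_id`, `ct` (`NA` = undetermined);
#'   assays without rows here skip the low-expression rule.
#' @param ld_threshold minimum r-squared (default 0.6).
#' @param ct_cutoff low-expression Ct cutoff (default 36).
#' @param low_expr_fraction exclusion fraction (default 0.5).
#' @return a [selection_report()] for the composed pipeline.
#' @examples
#' report <- run_selection(pd_candidates(), cdna_ct = pd_expression_screen())
#' nrow(report$selected)   # 13 transcribed markers
#' @export
run_selection <- function(candidates, cdna_ct = NULL, ld_threshold = 0.6,
                          ct_cutoff = 36, low_expr_fraction = 0.5) {
  validate_candidates(candidates)
  excluded <- empty_excluded(candidates)
  counts <- integer(0)
  absorb <- function(report) {
    excluded <<- dplyr::bind_rows(excluded, report$excluded)
    counts <<- c(counts, report$counts)
    report$selected
  }
  current <- absorb(filter_ld(candidates, ld_threshold))
  current <- absorb(filter_transcribed(current))
  current <- absorb(filter_special_regions(current))
  current <- absorb(filter_failed_assays(current))

  if (!is.null(cdna_ct) && nrow(current) > 0) {
    screened <- intersect(unique(cdna_ct$proxy_snp), current$proxy_snp)
    drop <- vapply(current$proxy_snp, function(snp) {
      if (!snp %in% screened) return(FALSE)
      cts <- cdna_ct$ct[cdna_ct$proxy_snp == snp]
      !filter_low_expression(cts, ct_cutoff, low_expr_fraction)
    }, logical(1))
    excl <- current[drop, , drop = FALSE]
    excl$reason <- rep("LOW_EXPRESSION", nrow(excl))
    excluded <- dplyr::bind_rows(excluded, excl)
    counts <- c(counts, c(LOW_EXPRESSION = sum(drop)))
    current <- current[!drop, , drop = FALSE]
  }

  current <- absorb(select_one_per_locus(current))
  selection_report(current, excluded, counts)
}

#' Count loci whose lead SNP is itself a transcribed coding variant
#'
#' A lead association signal that is itself a coding (synonymous or
#' missense) variant can be assayed directly, without a proxy. Counts
#' distinct loci whose primary (non-secondary) lead SNP appears in the
#' candidate table as its own transcribed coding marker.
#'
#' @inheritParams filter_ld
#' @return integer count of loci.
#' @export
count_coding_lead_loci <- function(candidates) {
  validate_candidates(candidates)
  hit <- candidates$proxy_snp == candidates$lead_snp &
    candidates$annotation %in% CODING_ANNOTATIONS &
    !isTRUE_vec(candidates$is_secondary_signal)
  length(unique(candidates$locus_id[hit]))
}

#' Packaged candidate-variant fixture for the PD GWAS worked example
#'
#' `pd_candidates()` returns the candidate table for the worked
#' example: the 13 transcribed markers chosen for the published PD
#' allelic-expression study, together with the candidates that the
#' selection workflow removes — the chromosome 17q21 inversion-locus
#' proxies of rs17649553, the isoform-restricted SNCA 3'UTR variant
#' rs356165, the failed KASP assay rs749670 (replaced by the TaqMan
#' assay for rs749671), the low-expressed TMEM229B assay rs2273596,
#' and the intronic GCH1 lead SNP rs11158026. Fields that the study
#' did not print for the excluded candidates (proxy rsIDs of the
#' inversion-locus variants, their LD values and annotations) are
#' synthetic placeholders; the `candidate_source` column marks each
#' row as `reported` or `synthetic`.
#'
#' `pd_expression_screen()` returns the accompanying synthetic cDNA
#' expression screen (per-sample Ct values) under which rs2273596
#' trips the low-expression rule.
#'
#' @return a tibble of candidate variants / expression-screen rows.
#' @export
pd_candidates <- function() {
  path <- system.file("extdata", "pd_candidates_reconstructed.tsv",
                      package = "aseqpcr", mustWork = TRUE)
  read_candidates_tsv(path)
}

#' @rdname pd_candidates
#' @export
pd_expression_screen <- function() {
  path <- system.file("extdata", "tmem229b_cdna_ct_synthetic.csv",
                      package = "aseqpcr", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  ct <- raw$ct
  ct[ct %in% c("Undetermined", "")] <- NA
  tibble::tibble(proxy_snp = raw$proxy_snp, sample_id = raw$sample_id,
                 ct = as.numeric(ct))
}

#' Read or write a candidate-variant table (TSV)
#' @param path file path.
#' @return a candidate tibble.
#' @export
read_candidates_tsv <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  for (col in c("is_secondary_signal", "in_inversion_region",
                "isoform_restricted", "assay_failed"))
    if (col %in% names(raw)) raw[[col]] <- as.logical(raw[[col]])
  validate_candidates(tibble::as_tibble(raw))
}

#' @rdname read_candidates_tsv
#' @param candidates candidate tibble.
#' @export
write_candidates_tsv <- function(candidates, path) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a selection report to disk
#'
#' Emits the selected and excluded tables as TSV plus a JSON summary of
#' per-stage exclusion counts.
#'
#' @param report a [selection_report()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_selection_report <- function(report, dir) {
  stopifnot(inherits(report, "selection_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_candidates_tsv(report$selected, file.path(dir, "selected.tsv"))
  write_candidates_tsv(report$excluded, file.path(dir, "excluded.tsv"))
  jsonlite::write_json(
    list(n_selected = nrow(report$selected),
         n_excluded = nrow(report$excluded),
         counts = as.list(report$counts)),
    file.path(dir, "selection_summary.json"), auto_unbox = TRUE)
  invisible(dir)
}
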