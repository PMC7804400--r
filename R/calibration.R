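#' Summarize a mixture-ratio plate into a calibration series
#'
#' Computes per-replicate `dCt = ct_fam - ct_vic` for each mixture
#' ratio of a sensitivity experiment and groups replicates by ratio
#' with mean and standard error. Ratios are parsed from the
#' instrument-export `sample_id` convention `"mix_<a>_<b>"` (FAM:VIC
#' ratio `a/b`); the heterozygous 1:1 control is recognised by
#' `sample_id == "het_control"` and kept apart from the fitted points.
#' Wells with an undetermined channel are dropped with a warning; a
#' ratio losing all its replicates is an error.
#'
#' @param wells plate-well tibble for one assay (see [read_plate_csv()]).
#' @return an object of class `calibration_series` with elements
#'   `assay_id`, `points` (per-replicate dCt by ratio), `summary`
#'   (mean/SE/n per ratio) and `het_control` (replicate dCt values).
#' @export
summarize_series <- function(wells) {
  stopifnot(all(c("sample_id", "ct_fam", "ct_vic") %in% names(wells)))
  if (length(unique(wells$assay_id)) > 1)
    stop("summarize_series() expects wells from a single assay", call. = FALSE)
  all_mix_ids <- unique(wells$sample_id[wells$sample_id != "het_control"])
  undet <- is.na(wells$ct_fam) | is.na(wells$ct_vic)
  if (any(undet)) {
    warning(sprintf("dropping %d well(s) with an undetermined channel",
                    sum(undet)), call. = FALSE)
    wells <- wells[!undet, , drop = FALSE]
  }
  is_het <- wells$sample_id == "het_control"
  het <- wells$ct_fam[is_het] - wells$ct_vic[is_het]
  mix <- wells[!is_het, , drop = FALSE]
  ratio <- parse_mix_ratio(mix$sample_id)
  points <- tibble::tibble(ratio = ratio,
                           delta_ct = mix$ct_fam - mix$ct_vic)
  surviving <- unique(mix$sample_id)
  if (length(setdiff(all_mix_ids, surviving)))
    stop("ratio(s) with zero surviving replicates: ",
         paste(setdiff(all_mix_ids, surviving), collapse = ", "),
         call. = FALSE)
  summary <- points %>%
    dplyr::group_by(.data$ratio) %>%
    dplyr::summarise(mean_delta_ct = mean(.data$delta_ct),
                     se = stats::sd(.data$delta_ct) /
                       sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(.data$ratio)
  structure(list(assay_id = unique(wells$assay_id),
                 points = points, summary = summary, het_control = het),
            class = "calibration_series")
}

parse_mix_ratio <- function(sample_id) {
  m <- regmatches(sample_id,
                  regexec("^mix_([0-9.]+)_([0-9.]+)$", sample_id))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad))
    stop("cannot parse mixture ratio from sample_id: ",
         paste(unique(sample_id[bad]), collapse = ", "), call. = FALSE)
  vapply(m, function(x) as.numeric(x[2]) / as.numeric(x[3]), numeric(1))
}

#' Fit and QC a mixture-ratio calibration series
#'
#' Regresses mean dCt on `log2(ratio)` by ordinary least squares. Under
#' the exponential amplification model the expected line is
#' `dCt = -log2(r)/log2(1+E) + delta`, so a well-behaved assay has a
#' slope near -1 (at efficiency 1), an intercept estimating the dye
#' bias, and strictly monotone mean dCt across ratios. The verdict is
#' `PASS` iff all of: `|slope|` within `[1 - slope_tol, 1 + slope_tol]`;
#' `r_squared >= r2_min`; means strictly monotone in ratio; and the
#' heterozygous control mean lies within two standard errors of the
#' fitted dCt at ratio 1. Each violated criterion contributes a reason
#' code (`SLOPE_OUT_OF_RANGE`, `POOR_FIT`, `NON_MONOTONE`,
#' `HET_INCONSISTENT`).
#'
#' @param series a `calibration_series` from [summarize_series()].
#' @param slope_tol slope-magnitude tolerance around 1 (default 0.3).
#' @param r2_min minimum coefficient of determination (default 0.9).
#' @return an object of class `calibration_result`.
#' @export
fit_calibration <- function(series, slope_tol = 0.3, r2_min = 0.9) {
  stopifnot(inherits(series, "calibration_series"))
  s <- series$summary
  if (nrow(s) < 2)
    stop("calibration requires at least two distinct mixture ratios",
         call. = FALSE)
  fit <- stats::lm(mean_delta_ct ~ log2(ratio), data = s)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_tot <- sum((s$mean_delta_ct - mean(s$mean_delta_ct))^2)
  # a flat series has no ratio response: score it 0, not NaN; a
  # noiseless series fits perfectly and lm's summary warning is moot
  r_squared <- if (ss_tot < .Machine$double.eps) 0
               else suppressWarnings(summary(fit)$r.squared)

  d <- diff(s$mean_delta_ct)          # s is sorted by increasing ratio
  monotone <- all(d < 0) || all(d > 0)

  het <- series$het_control
  if (length(het) >= 1) {
    het_se <- if (length(het) > 1) stats::sd(het) / sqrt(length(het)) else 0
    # small absolute floor so that noiseless series are not failed by
    # floating-point residue in an SE of exactly zero
    het_consistent <- abs(mean(het) - intercept) <= 2 * het_se + 1e-8
  } else {
    het_consistent <- NA
  }

  reasons <- character(0)
  if (!(abs(slope) >= 1 - slope_tol && abs(slope) <= 1 + slope_tol))
    reasons <- c(reasons, "SLOPE_OUT_OF_RANGE")
  if (r_squared < r2_min) reasons <- c(reasons, "POOR_FIT")
  if (!monotone) reasons <- c(reasons, "NON_MONOTONE")
  if (isFALSE(het_consistent)) reasons <- c(reasons, "HET_INCONSISTENT")

  structure(list(assay_id = series$assay_id, slope = slope,
                 intercept = intercept, r_squared = r_squared,
                 monotone = monotone, het_consistent = het_consistent,
                 verdict = if (length(reasons)) "FAIL" else "PASS",
                 reasons = reasons),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration %s [%s]\n", x$assay_id, x$verdict))
  cat(sprintf("  slope %.4f dCt per log2(ratio), intercept %.4f, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  monotone: %s; het control consistent: %s\n",
              x$monotone, x$het_consistent))
  if (length(x$reasons))
    cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Calibrate an assay directly from a mixture plate
#'
#' Convenience wrapper: [summarize_series()] then [fit_calibration()].
#' @inheritParams summarize_series
#' @inheritParams fit_calibration
#' @return a `calibration_result`.
#' @export
calibrate_assay <- function(wells, slope_tol = 0.3, r2_min = 0.9) {
  fit_calibration(summarize_series(wells), slope_tol, r2_min)
}

#' Write a calibration result as JSON
#' @param result a `calibration_result`.
#' @param path file path.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
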