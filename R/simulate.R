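#' Simulation configuration for synthetic qPCR plates
#'
#' Bundles the parameters of the generative amplification model used by
#' [simulate_study()] and [simulate_mixture_series()]. The model is the
#' standard exponential-amplification relation: a template present at
#' relative quantity \eqn{q} crosses the detection threshold at
#' \deqn{Ct = C_0 - \log_2(q) / \log_2(1 + E) + \delta_{dye} + \epsilon,}
#' where \eqn{E} is the per-cycle amplification efficiency (\eqn{E = 1}
#' is perfect doubling), \eqn{\delta} is an additive dye bias applied to
#' the FAM channel only, and \eqn{\epsilon \sim N(0, \sigma^2)} is
#' replicate noise. Reactions whose Ct would exceed `ct_max` never cross
#' threshold and are reported as undetermined (`NA`), mirroring real
#' instrument exports.
#'
#' Defaults emulate a post-mortem brain ASE cohort: 101 donors of whom
#' 37\% are cases, a marker with minor allele frequency 0.4 (so roughly
#' half the donors are informative heterozygotes), five cDNA and three
#' gDNA replicates per sample, replicate noise of 0.15 Ct, a dye bias of
#' 0.3 Ct on the FAM channel, and perfect amplification efficiency (the
#' assumption under which the conventional `2^dCt` fold-change reading
#' of a Ct difference is exact).
#'
#' @param seed integer seed; identical config + seed gives identical output.
#' @param n_donors number of donors in the cohort.
#' @param maf frequency of the FAM-labelled allele, in `[0, 1]`.
#' @param case_fraction fraction of donors labelled as cases (diagnosis
#'   `"PD"`); the rest are `"control"`.
#' @param true_fold_change true cDNA abundance ratio `phi` of the
#'   FAM-allele transcript to the VIC-allele transcript in heterozygotes.
#'   `phi = 1` is balanced expression.
#' @param efficiency per-cycle amplification efficiency `E` in `(0, 1]`,
#'   shared by both dye channels.
#' @param dye_bias additive Ct offset `delta` applied to the FAM channel.
#' @param noise_sd replicate Ct standard deviation `sigma` (>= 0).
#' @param baseline_ct Ct of a template at relative quantity 1.
#' @param ct_max detection limit; larger Ct values are censored
#'   (a standard 40-cycle run by default).
#' @param n_replicates_cdna,n_replicates_gdna wells per sample.
#' @param tissues character vector of tissue labels to simulate.
#' @param assay_id assay label stamped on the generated wells.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_donors = 20, true_fold_change = 2)
#' sim <- simulate_study(cfg)
#' head(sim$wells)
#' @export
sim_config <- function(seed = 1L,
                       n_donors = 101L,
                       maf = 0.4,
                       case_fraction = 0.37,
                       true_fold_change = 1,
                       efficiency = 1,
                       dye_bias = 0.3,
                       noise_sd = 0.15,
                       baseline_ct = 26,
                       ct_max = 40,
                       n_replicates_cdna = 5L,
                       n_replicates_gdna = 3L,
                       tissues = "brain",
                       assay_id = "assay1") {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (!is.numeric(maf) || maf < 0 || maf > 1)
    stop("`maf` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(case_fraction) || case_fraction < 0 || case_fraction > 1)
    stop("`case_fraction` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(true_fold_change) || true_fold_change <= 0)
    stop("`true_fold_change` must be a positive real", call. = FALSE)
  if (!is.numeric(efficiency) || efficiency <= 0 || efficiency > 1)
    stop("`efficiency` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(ct_max) || ct_max <= 0)
    stop("`ct_max` must be positive", call. = FALSE)
  stopifnot(n_donors >= 0, n_replicates_cdna >= 1, n_replicates_gdna >= 1,
            length(tissues) >= 1)
  structure(
    list(seed = as.integer(seed), n_donors = as.integer(n_donors),
         maf = maf, case_fraction = case_fraction,
         true_fold_change = true_fold_change, efficiency = efficiency,
         dye_bias = dye_bias, noise_sd = noise_sd,
         baseline_ct = baseline_ct, ct_max = ct_max,
         n_replicates_cdna = as.integer(n_replicates_cdna),
         n_replicates_gdna = as.integer(n_replicates_gdna),
         tissues = as.character(tissues), assay_id = assay_id),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("qPCR simulation config\n")
  cat(sprintf("  donors: %d (case fraction %.2f), FAM-allele freq %.2f\n",
              x$n_donors, x$case_fraction, x$maf))
  cat(sprintf("  fold change phi = %g, efficiency E = %g, dye bias = %g Ct\n",
              x$true_fold_change, x$efficiency, x$dye_bias))
  cat(sprintf("  noise sd = %g Ct, baseline Ct = %g, censor at Ct > %g\n",
              x$noise_sd, x$baseline_ct, x$ct_max))
  cat(sprintf("  replicates: %d cDNA / %d gDNA; tissues: %s; seed %d\n",
              x$n_replicates_cdna, x$n_replicates_gdna,
              paste(x$tissues, collapse = ", "), x$seed))
  invisible(x)
}

#' Simulate Ct values under the exponential amplification model
#'
#' Draws one Ct value per element of `quantity` for the given dye
#' channel. Values beyond the detection limit are censored to `NA`
#' (reported as "Undetermined" by instrument software). Censoring is
#' applied after noise, so a noisy draw may cross the limit even when
#' the noiseless Ct would not.
#'
#' Uses the current R random number stream; callers control
#' reproducibility with `set.seed()`.
#'
#' @param quantity positive relative template quantities.
#' @param dye `"FAM"` or `"VIC"`; the FAM channel receives the dye bias.
#' @param config a [sim_config()].
#' @return numeric vector of Ct values, `NA` where censored.
#' @export
simulate_ct <- function(quantity, dye = c("FAM", "VIC"), config) {
  dye <- match.arg(dye)
  if (!is.numeric(quantity) || any(!is.finite(quantity)) || any(quantity <= 0))
    stop("`quantity` must be positive and finite; zero-template wells never amplify",
         call. = FALSE)
  ct <- config$baseline_ct -
    log2(quantity) / log2(1 + config$efficiency) +
    if (dye == "FAM") config$dye_bias else 0
  ct <- ct + stats::rnorm(length(quantity), 0, config$noise_sd)
  ct[ct > config$ct_max] <- NA_real_
  ct
}

#' Simulate genotypes under Hardy-Weinberg proportions
#'
#' Allele A is the FAM-labelled allele with frequency `maf`; genotypes
#' are drawn with probabilities `maf^2` (AA), `2*maf*(1-maf)` (AB) and
#' `(1-maf)^2` (BB).
#'
#' @param n_donors number of donors.
#' @param maf frequency of allele A in `[0, 1]`.
#' @return character vector of genotypes in `{"AA", "AB", "BB"}`.
#' @export
simulate_genotypes <- function(n_donors, maf) {
  if (!is.numeric(maf) || length(maf) != 1 || is.na(maf) || maf < 0 || maf > 1)
    stop("`maf` must be a single frequency in [0, 1]", call. = FALSE)
  if (n_donors == 0) return(character(0))
  sample(c("AA", "AB", "BB"), n_donors, replace = TRUE,
         prob = c(maf^2, 2 * maf * (1 - maf), (1 - maf)^2))
}

well_labels <- function(n) {
  # 384-well plate coordinates A01..P24, recycled across plates
  rows <- rep(LETTERS[1:16], each = 24)
  cols <- sprintf("%02d", rep(1:24, times = 16))
  idx <- ((seq_len(n) - 1) %% 384) + 1
  paste0(rows[idx], cols[idx])
}

allele_quantities <- function(genotype, material, phi) {
  # relative template quantity per allele; total held at 1
  switch(genotype,
    AA = c(fam = 1, vic = 0),
    BB = c(fam = 0, vic = 1),
    AB = if (material == "gDNA") c(fam = 0.5, vic = 0.5)
         else c(fam = phi / (phi + 1), vic = 1 / (phi + 1)),
    stop("unknown genotype: ", genotype, call. = FALSE)
  )
}

#' Simulate a full ASE study (gDNA + cDNA plates, metadata, truth)
#'
#' Generates one allele-discrimination assay measured over a donor
#' cohort. Genomic DNA from every donor is plated (the genotyping step),
#' and cDNA is plated for all donors as well (heterozygote selection
#' happens downstream, as in a real study). Heterozygous gDNA carries
#' the two allele templates at 1:1; heterozygous cDNA carries them at
#' the configured fold change `phi` (FAM : VIC); homozygotes carry a
#' single-allele template. A zero-quantity channel never amplifies and
#' is exported as undetermined.
#'
#' @param config a [sim_config()].
#' @param genotypes optional character vector of length `n_donors`
#'   overriding the Hardy-Weinberg draw (e.g. `rep("AB", n)` to force an
#'   all-heterozygote cohort for power studies).
#' @return list with tibbles `wells` (one row per replicate well),
#'   `meta` (sample metadata) and `truth` (per-donor genotype and the
#'   assay's true fold change).
#' @export
simulate_study <- function(config, genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_donors
  if (is.null(genotypes)) {
    genotypes <- simulate_genotypes(n, config$maf)
  } else {
    stopifnot(length(genotypes) == n, all(genotypes %in% c("AA", "AB", "BB")))
  }
  donors <- sprintf("d%03d", seq_len(n))
  n_cases <- round(config$case_fraction * n)
  diagnosis <- rep("control", n)
  if (n > 0 && n_cases > 0) diagnosis[seq_len(n_cases)] <- "PD"

  grid <- expand.grid(donor = donors, tissue = config$tissues,
                      material = c("gDNA", "cDNA"),
                      stringsAsFactors = FALSE)
  meta <- tibble::tibble(
    sample_id = paste(grid$donor, grid$tissue, grid$material, sep = "_"),
    donor_id = grid$donor,
    tissue = grid$tissue,
    material = grid$material,
    diagnosis = diagnosis[match(grid$donor, donors)]
  )

  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    g <- genotypes[match(m$donor_id, donors)]
    nrep <- if (m$material == "gDNA") config$n_replicates_gdna
            else config$n_replicates_cdna
    q <- allele_quantities(g, m$material, config$true_fold_change)
    ct_fam <- if (q[["fam"]] > 0)
      simulate_ct(rep(q[["fam"]], nrep), "FAM", config) else rep(NA_real_, nrep)
    ct_vic <- if (q[["vic"]] > 0)
      simulate_ct(rep(q[["vic"]], nrep), "VIC", config) else rep(NA_real_, nrep)
    rows[[i]] <- tibble::tibble(
      sample_id = m$sample_id, assay_id = config$assay_id,
      replicate = seq_len(nrep), ct_fam = ct_fam, ct_vic = ct_vic
    )
  }
  wells <- dplyr::bind_rows(rows)
  if (nrow(wells) == 0) {
    wells <- tibble::tibble(sample_id = character(), assay_id = character(),
                            replicate = integer(), ct_fam = numeric(),
                            ct_vic = numeric())
  }
  wells <- tibble::tibble(
    plate_id = paste0(config$assay_id, "_p",
                      if (nrow(wells)) ((seq_len(nrow(wells)) - 1) %/% 384) + 1
                      else integer(0)),
    well = well_labels(nrow(wells)),
    wells
  )
  truth <- tibble::tibble(
    donor_id = donors, genotype = genotypes,
    assay_id = config$assay_id,
    true_fold_change = config$true_fold_change,
    fam_allele = "A", vic_allele = "B"
  )
  list(wells = wells, meta = meta, truth = truth)
}

#' Default allele mixture ratios for sensitivity calibration
#'
#' The nine fixed FAM:VIC mixing ratios used in the assay sensitivity
#' experiment: 4:1, 2:1, 1.5:1, 1.25:1, 1:1, 1:1.25, 1:1.5, 1:2, 1:4.
#' @return numeric vector of length 9.
#' @export
default_mixture_ratios <- function() {
  c(4, 2, 1.5, 1.25, 1, 1 / 1.25, 1 / 1.5, 1 / 2, 1 / 4)
}

ratio_sample_id <- function(r) {
  fmt <- function(x) sub("\\.?0+$", "", format(x, nsmall = 2))
  ifelse(r >= 1, paste0("mix_", fmt(r), "_1"), paste0("mix_1_", fmt(1 / r)))
}

#' Simulate an allele-mixture calibration series
#'
#' Emulates the assay sensitivity experiment: gDNA from the two
#' homozygotes mixed at known ratios, run in triplicate, plus one
#' heterozygous gDNA control for the 1:1 ratio. Each ratio `r` gives
#' wells with allele quantities `(r*q, q)` scaled so total template is
#' constant across ratios.
#'
#' @param config a [sim_config()].
#' @param ratios FAM:VIC mixing ratios; defaults to the nine-point
#'   series of [default_mixture_ratios()].
#' @param n_replicates wells per ratio (triplicates by default).
#' @return tibble of plate wells; the heterozygous control has
#'   `sample_id == "het_control"`.
#' @export
simulate_mixture_series <- function(config,
                                    ratios = default_mixture_ratios(),
                                    n_replicates = 3L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(ratios) == 0) stop("`ratios` must be non-empty", call. = FALSE)
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("mixture ratios must be positive", call. = FALSE)
  set.seed(config$seed)
  ids <- c(ratio_sample_id(ratios), "het_control")
  rvals <- c(ratios, 1)
  rows <- lapply(seq_along(rvals), function(i) {
    r <- rvals[i]
    q_fam <- r / (r + 1)
    q_vic <- 1 / (r + 1)
    tibble::tibble(
      sample_id = ids[i], assay_id = config$assay_id,
      replicate = seq_len(n_replicates),
      ct_fam = simulate_ct(rep(q_fam, n_replicates), "FAM", config),
      ct_vic = simulate_ct(rep(q_vic, n_replicates), "VIC", config)
    )
  })
  wells <- dplyr::bind_rows(rows)
  tibble::tibble(plate_id = paste0(config$assay_id, "_mix"),
                 well = well_labels(nrow(wells)), wells)
}
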