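test_that("delta Ct is the channel difference, absent when censored", {
  w <- make_wells(ct_fam = c(25, 25, 25, NA), ct_vic = c(24, 25, NA, 24))
  d <- compute_delta_ct(w)$delta_ct
  expect_equal(d, c(1, 0, NA, NA))
})

test_that("Ct exclusion is strict at the cutoff and enforces a replicate floor", {
  w <- make_wells(ct_fam = c(36.5, 36.0, 30, 30, 30),
                  ct_vic = c(30, 30, 30, 30, 30))
  res <- apply_ct_exclusion(w, ct_cutoff = 36, min_replicates = 3)
  expect_equal(nrow(res$wells), 4)          # 36.0 exactly is retained
  expect_equal(res$log$reason, "CT_ABOVE_CUTOFF")
  expect_equal(res$log$replicate, 1L)

  # sample with 2 of 5 surviving replicates drops out entirely
  w2 <- make_wells(ct_fam = c(37, 37, NA, 30, 30),
                   ct_vic = c(30, 30, 30, 30, 30))
  res2 <- apply_ct_exclusion(w2, min_replicates = 3)
  expect_equal(nrow(res2$wells), 0)
  expect_setequal(unique(res2$log$reason),
                  c("CT_ABOVE_CUTOFF", "CHANNEL_UNDETERMINED",
                    "TOO_FEW_REPLICATES"))
})

test_that("normalization centres on the gDNA mean", {
  gdna <- c(0.4, 0.6, 0.5)
  expect_equal(normalize_delta_ct(c(0.5, 0.5), gdna), c(0, 0))
  # gDNA normalised against itself has mean zero
  expect_equal(mean(normalize_delta_ct(gdna, gdna)), 0)
  expect_error(normalize_delta_ct(1, numeric(0)), "impossible")
})

test_that("simulated two-fold imbalance recovers nDCt -1 and fold 2", {
  cfg <- sim_config(seed = 2, n_donors = 10, maf = 0.5, noise_sd = 0,
                    dye_bias = 0.4, efficiency = 1, true_fold_change = 2)
  sim <- simulate_study(cfg)
  geno <- call_cohort(sim$wells, sim$meta)
  assays <- tibble::tibble(assay_id = "assay1", gene = "G",
                           risk_allele = "A", fam_allele = "A",
                           vic_allele = "B")
  res <- run_ase(sim$wells, sim$meta, geno$roster, assays)
  expect_equal(res$samples$n_delta_ct, rep(-1, nrow(res$samples)),
               tolerance = 1e-12)
  expect_equal(res$samples$fold_change, rep(2, nrow(res$samples)),
               tolerance = 1e-12)
})

test_that("rank-sum test matches hand enumeration and conventions", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)  # enumeration over C(4,2)=6 assignments
  expect_true(r$exact)

  same <- rank_sum_test(c(5, 5, 5), c(5, 5))
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("exact branch equals the exhaustive permutation oracle", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    v <- sample(seq_len(50), n + m)  # distinct values: no ties
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    expect_equal(rank_sum_test(x, y)$p_value, perm_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("approximate branch matches the reference implementation", {
  set.seed(32)
  for (i in 1:20) {
    x <- round(rnorm(15, 0, 1), 1)   # rounding induces ties
    y <- round(rnorm(12, 0.5, 1), 1)
    ours <- rank_sum_test(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("normality screen flags skew and skips tiny groups", {
  set.seed(40)
  skewed <- rexp(50)
  normal <- rnorm(50)
  res <- normality_screen(skewed, normal)
  expect_true(res$table$rejected[res$table$group == "cDNA"])
  expect_true(res$any_rejected)

  grid <- rep(c(-1, 0, 1), 2)
  res2 <- normality_screen(grid, grid)
  expect_equal(res2$table$rejected, c(FALSE, FALSE))
  # agrees with the reference test on the same data
  expect_equal(res2$table$p_value[1], stats::shapiro.test(grid)$p.value)

  res3 <- normality_screen(c(1, 2), rnorm(10))
  expect_match(res3$table$note[res3$table$group == "cDNA"], "skipped")
})

ase_fixture <- function(seed, phi, n_donors = 24, noise_sd = 0.15,
                        dye_bias = 0.3, fam = "G", vic = "A",
                        risk = "A") {
  cfg <- sim_config(seed = seed, n_donors = n_donors, maf = 0.5,
                    noise_sd = noise_sd, dye_bias = dye_bias,
                    true_fold_change = phi)
  sim <- simulate_study(cfg)
  geno <- call_cohort(sim$wells, sim$meta)
  assays <- tibble::tibble(assay_id = "assay1", gene = "G1",
                           risk_allele = risk, fam_allele = fam,
                           vic_allele = vic)
  list(sim = sim, geno = geno, assays = assays,
       res = run_ase(sim$wells, sim$meta, geno$roster, assays))
}

test_that("assay summary labels direction through the dye orientation", {
  # phi = 2: FAM allele over-expressed, negative nDCt -> "G>A"
  fx <- ase_fixture(seed = 51, phi = 2, fam = "G", vic = "A")
  a <- fx$res$assays
  expect_true(a$ase_detected)
  expect_lt(a$mean_n_delta_ct, 0)
  expect_equal(a$direction_label, "G>A")
  expect_equal(a$risk_allele_direction, "less")  # risk allele A under-expressed

  # balanced expression: no ASE, "X=Y", direction none
  fx0 <- ase_fixture(seed = 52, phi = 1)
  if (!fx0$res$assays$ase_detected) {
    expect_equal(fx0$res$assays$direction_label, "G=A")
    expect_equal(fx0$res$assays$risk_allele_direction, "none")
  }
})

test_that("channel-label swap negates effects and flips labels", {
  fx <- ase_fixture(seed = 53, phi = 1.6)
  swapped_wells <- dplyr::rename(fx$sim$wells, ct_fam = "ct_vic",
                                 ct_vic = "ct_fam")
  assays_sw <- fx$assays
  assays_sw$fam_allele <- fx$assays$vic_allele
  assays_sw$vic_allele <- fx$assays$fam_allele
  res_sw <- run_ase(swapped_wells, fx$sim$meta, fx$geno$roster, assays_sw)

  expect_equal(res_sw$samples$n_delta_ct, -fx$res$samples$n_delta_ct,
               tolerance = 1e-12)
  expect_equal(res_sw$samples$p_value, fx$res$samples$p_value,
               tolerance = 1e-12)
  expect_equal(res_sw$assays$overall_p, fx$res$assays$overall_p,
               tolerance = 1e-12)
  # "G>A" becomes "A<G": same biology read from the other channel
  expect_equal(res_sw$assays$mean_n_delta_ct,
               -fx$res$assays$mean_n_delta_ct, tolerance = 1e-12)
})

test_that("a constant FAM offset on all wells cancels in nDCt", {
  fx <- ase_fixture(seed = 54, phi = 1.5)
  shifted <- fx$sim$wells
  shifted$ct_fam <- shifted$ct_fam + 0.8
  res_sh <- run_ase(shifted, fx$sim$meta, fx$geno$roster, fx$assays)
  expect_equal(res_sh$samples$n_delta_ct, fx$res$samples$n_delta_ct,
               tolerance = 1e-10)
  expect_equal(res_sh$assays$mean_n_delta_ct, fx$res$assays$mean_n_delta_ct,
               tolerance = 1e-10)
})

test_that("gDNA heterozygote set self-centres to nDCt zero", {
  fx <- ase_fixture(seed = 55, phi = 1.8)
  gids <- fx$geno$roster$sample_id
  gw <- compute_delta_ct(fx$sim$wells[fx$sim$wells$sample_id %in% gids, ])
  expect_equal(mean(normalize_delta_ct(gw$delta_ct, gw$delta_ct)), 0,
               tolerance = 1e-12)
})

test_that("overall p ignores diagnosis labels", {
  fx <- ase_fixture(seed = 56, phi = 1.4)
  meta_perm <- fx$sim$meta
  set.seed(1)
  meta_perm$diagnosis <- sample(meta_perm$diagnosis)
  res_perm <- run_ase(fx$sim$wells, meta_perm, fx$geno$roster, fx$assays)
  expect_equal(res_perm$assays$overall_p, fx$res$assays$overall_p)
  expect_equal(sort(res_perm$samples$p_value), sort(fx$res$samples$p_value))
})

test_that("per-sample comparator options both run", {
  fx <- ase_fixture(seed = 57, phi = 1.5)
  gids <- fx$geno$roster$sample_id
  w <- compute_delta_ct(fx$sim$wells)
  cw <- w[grepl("cDNA", w$sample_id) &
            sub("_.*", "", w$sample_id) %in%
              sub("_.*", "", gids), ]
  gw <- w[w$sample_id %in% gids, ]
  pooled <- ase_sample_results(cw, gw, fx$sim$meta, comparator = "pooled")
  means <- ase_sample_results(cw, gw, fx$sim$meta, comparator = "means")
  expect_equal(pooled$n_delta_ct, means$n_delta_ct)
  expect_false(identical(pooled$p_value, means$p_value))

  # optional BH correction across per-sample tests
  bh <- ase_sample_results(cw, gw, fx$sim$meta, p_adjust = "BH")
  expect_equal(bh$p_value, stats::p.adjust(pooled$p_value, "BH"))
  expect_true(all(bh$p_value >= pooled$p_value))
})

test_that("tissue comparison classifies the four patterns", {
  mk <- function(id, detected, nd) {
    tibble::tibble(assay_id = id, gene = toupper(id),
                   ase_detected = detected, mean_n_delta_ct = nd,
                   direction_label = ifelse(detected,
                                            ifelse(nd < 0, "A>B", "A<B"),
                                            "A=B"))
  }
  brain <- dplyr::bind_rows(mk("a", TRUE, -1), mk("b", TRUE, -1),
                            mk("c", FALSE, 0.01), mk("d", TRUE, -1),
                            mk("e", TRUE, 0.8))
  blood <- dplyr::bind_rows(mk("a", TRUE, -0.8), mk("b", FALSE, 0),
                            mk("c", FALSE, -0.01), mk("e", TRUE, -0.5),
                            mk("f", TRUE, 1))
  cmp <- compare_tissues(brain, blood)
  cls <- setNames(cmp$class, cmp$assay_id)
  expect_equal(unname(cls[c("a", "b", "c", "d", "e", "f")]),
               c("concordant_ase", "brain_specific", "no_ase",
                 "incomparable", "discordant_direction", "incomparable"))
})
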