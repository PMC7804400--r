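test_that("LD filter is inclusive at the threshold", {
  cands <- make_candidates(c("rs4649383", "rs_low", "rs_edge"),
                           r2 = c(0.64, 0.59, 0.6))
  rep <- filter_ld(cands)
  expect_setequal(rep$selected$proxy_snp, c("rs4649383", "rs_edge"))
  expect_equal(rep$excluded$reason, "LOW_LD")

  empty <- filter_ld(cands[0, ])
  expect_equal(nrow(empty$selected) + nrow(empty$excluded), 0)
})

test_that("transcribed filter keeps coding and UTR, rejects unknown labels", {
  cands <- make_candidates(
    c("rs_syn", "rs_mis", "rs_3u", "rs_5u", "rs_int", "rs_ig"),
    annotation = c("synonymous", "missense", "3'UTR", "5'UTR",
                   "intronic", "intergenic"))
  rep <- filter_transcribed(cands)
  expect_setequal(rep$selected$proxy_snp,
                  c("rs_syn", "rs_mis", "rs_3u", "rs_5u"))
  expect_true(all(rep$excluded$reason == "NOT_TRANSCRIBED"))
  expect_error(filter_transcribed(make_candidates("rs1", annotation = "exonic")),
               "unknown functional annotation")
})

test_that("intronic lead SNP is excluded while its UTR proxy survives", {
  fx <- pd_candidates()
  rep <- filter_transcribed(fx)
  expect_true("rs11158026" %in% rep$excluded$proxy_snp)
  expect_true("rs28481699" %in% rep$selected$proxy_snp)
})

test_that("special-region filter removes inversion and isoform flags", {
  cands <- make_candidates(c("rs_inv", "rs_iso", "rs_ok"),
                           in_inversion_region = c(TRUE, FALSE, FALSE),
                           isoform_restricted = c(FALSE, TRUE, FALSE))
  rep <- filter_special_regions(cands)
  expect_equal(rep$selected$proxy_snp, "rs_ok")
  expect_equal(rep$excluded$reason[rep$excluded$proxy_snp == "rs_inv"],
               "INVERSION_LOCUS")
  expect_equal(rep$excluded$reason[rep$excluded$proxy_snp == "rs_iso"],
               "ISOFORM_RESTRICTED")
})

test_that("low-expression rule is strict majority above the cutoff", {
  expect_false(filter_low_expression(c(rep(37, 6), rep(30, 4))))   # 6/10
  expect_true(filter_low_expression(c(rep(37, 5), rep(30, 5))))    # exactly half
  expect_true(filter_low_expression(rep(20, 10)))
  expect_false(filter_low_expression(c(NA, NA, NA, 30, 30)))       # NA counts high
  expect_true(filter_low_expression(36, ct_cutoff = 36))           # boundary: not > 36
  expect_error(filter_low_expression(numeric(0)), "no cDNA")
})

test_that("one-per-locus keeps max r2 with stated tie-breaks", {
  cands <- make_candidates(c("rs_a", "rs_b"), r2 = c(0.8, 0.7), gene = "G1")
  expect_equal(select_one_per_locus(cands)$selected$proxy_snp, "rs_a")

  # tie on r2: coding beats UTR
  tie <- make_candidates(c("rs_utr", "rs_cod"), r2 = 0.8, gene = "G1",
                         annotation = c("3'UTR", "synonymous"))
  expect_equal(select_one_per_locus(tie)$selected$proxy_snp, "rs_cod")

  # transcribed lead SNP always preferred, even at lower r2 rank
  lead <- make_candidates(c("rs_lead", "rs_prox"), r2 = c(1, 1),
                          gene = "G1", lead_snp = "rs_lead")
  expect_equal(select_one_per_locus(lead)$selected$proxy_snp, "rs_lead")

  # secondary signals are exempt from the cap
  sec <- make_candidates(c("rs_p", "rs_s"), r2 = c(0.9, 0.9), gene = "G1",
                         is_secondary_signal = c(FALSE, TRUE))
  expect_setequal(select_one_per_locus(sec)$selected$proxy_snp,
                  c("rs_p", "rs_s"))

  # single-candidate locus is identity
  one <- make_candidates("rs_only")
  expect_equal(select_one_per_locus(one)$selected$proxy_snp, "rs_only")
})

test_that("every stage and the composed pipeline partition their input", {
  fx <- pd_candidates()
  for (rep in list(filter_ld(fx), filter_transcribed(fx),
                   filter_special_regions(fx), filter_failed_assays(fx),
                   select_one_per_locus(fx),
                   run_selection(fx, cdna_ct = pd_expression_screen()))) {
    expect_equal(nrow(rep$selected) + nrow(rep$excluded), nrow(fx))
    expect_setequal(c(rep$selected$proxy_snp, rep$excluded$proxy_snp),
                    fx$proxy_snp)
  }
})

test_that("selected set is invariant to input row order", {
  fx <- pd_candidates()
  ref <- sort(run_selection(fx, cdna_ct = pd_expression_screen())$selected$proxy_snp)
  set.seed(21)
  for (i in 1:5) {
    shuffled <- fx[sample(nrow(fx)), ]
    got <- run_selection(shuffled, cdna_ct = pd_expression_screen())$selected$proxy_snp
    expect_equal(sort(got), ref)
  }
})

test_that("raising the LD threshold never adds a selected variant", {
  fx <- pd_candidates()
  prev <- NULL
  for (thr in c(0.6, 0.7, 0.8, 0.9, 1)) {
    sel <- run_selection(fx, cdna_ct = pd_expression_screen(),
                         ld_threshold = thr)$selected$proxy_snp
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
  all_low <- run_selection(make_candidates(c("r1", "r2"), r2 = 0.3))
  expect_equal(nrow(all_low$selected), 0)
  expect_true(all(all_low$excluded$reason == "LOW_LD"))
})

test_that("the packaged worked example reproduces the published selection", {
  fx <- pd_candidates()
  rep <- run_selection(fx, cdna_ct = pd_expression_screen())
  expect_equal(nrow(rep$selected), 13)
  expect_equal(length(unique(rep$selected$gene)), 12)

  reason_of <- function(snp) rep$excluded$reason[rep$excluded$proxy_snp == snp]
  expect_equal(reason_of("rs2273596"), "LOW_EXPRESSION")
  expect_equal(reason_of("rs356165"), "ISOFORM_RESTRICTED")
  expect_equal(reason_of("rs749670"), "ASSAY_FAILED")
  inv <- rep$excluded[rep$excluded$reason == "INVERSION_LOCUS", ]
  expect_equal(nrow(inv), 5)
  expect_true(all(inv$lead_snp == "rs17649553"))
  expect_equal(length(unique(inv$gene)), 5)

  # replacement assay stands in for the failed one
  expect_true("rs749671" %in% rep$selected$proxy_snp)
  expect_false("rs749670" %in% rep$selected$proxy_snp)
  # both genes of the two-gene locus retained
  expect_true(all(c("RAB7L1", "NUCKS1") %in% rep$selected$gene))
})

test_that("coding-lead loci are counted once per locus", {
  expect_equal(count_coding_lead_loci(pd_candidates()), 2)
  # intronic self-proxy does not count
  expect_equal(count_coding_lead_loci(
    make_candidates("rs_x", lead_snp = "rs_x", annotation = "intronic")), 0)
})

test_that("candidate tables round-trip through TSV", {
  fx <- pd_candidates()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidates_tsv(fx, path)
  expect_equal(as.data.frame(read_candidates_tsv(path)), as.data.frame(fx))
})
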