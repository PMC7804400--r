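# toy candidate rows with sensible defaults; override per test
make_candidates <- function(proxy_snp, r2 = 0.9, gene = proxy_snp,
                            lead_snp = "rs_lead", annotation = "synonymous",
                            locus_id = "L1", dprime = 1,
                            is_secondary_signal = FALSE,
                            in_inversion_region = FALSE,
                            isoform_restricted = FALSE,
                            assay_failed = FALSE, technology = "TaqMan") {
  tibble::tibble(lead_snp = lead_snp, proxy_snp = proxy_snp, gene = gene,
                 r2 = r2, dprime = dprime, annotation = annotation,
                 locus_id = locus_id,
                 is_secondary_signal = is_secondary_signal,
                 in_inversion_region = in_inversion_region,
                 isoform_restricted = isoform_restricted,
                 technology = technology, assay_failed = assay_failed)
}

# exhaustive permutation oracle for the two-sided rank-sum p-value
# (no ties assumed); independent of the implementation under test
perm_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, u_of)
  mean(abs(us - n * m / 2) >= abs(u_obs - n * m / 2) - 1e-12)
}

# bare wells tibble for direct stats-layer tests
make_wells <- function(ct_fam, ct_vic, sample_id = "s1",
                       assay_id = "a1") {
  tibble::tibble(plate_id = "p1", well = "A01", sample_id = sample_id,
                 assay_id = assay_id,
                 replicate = seq_along(ct_fam),
                 ct_fam = ct_fam, ct_vic = ct_vic)
}
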