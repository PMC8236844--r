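test_that("MAF policy applies dataset overrides with inclusive thresholds", {
  pol <- maf_policy()
  expect_equal(maf_threshold_for(pol, c("nNFE", "AOGC", "MGRB")),
               c(1e-4, 0.005, 0.005))
  expect_error(maf_policy(default = 0.6), class = "kpburden_config_error")
  expect_error(maf_policy(overrides = c(x = 0)), class = "kpburden_config_error")
})

test_that("rarity is inclusive at the threshold and maximal for absentees", {
  v <- make_variant()
  # exactly at the nNFE threshold: AC such that maf == 1e-4
  at <- make_control(v, "nNFE", allele_count = 0.0001 * 2 * 51592,
                     sample_size = 51592)
  over <- make_control(v, "nNFE", allele_count = 0.0001 * 2 * 51592 + 1,
                       sample_size = 51592)
  expect_true(is_rare(v, at, maf_policy())$rare)
  expect_false(is_rare(v, over, maf_policy())$rare)

  # AOGC threshold 0.005, maf 0.004 is rare; 2e-4 in nNFE is not
  aogc <- make_control(v, "AOGC", allele_count = round(0.004 * 2 * 967),
                       sample_size = 967)
  expect_true(is_rare(v, aogc, maf_policy())$rare)
  nnfe <- make_control(v, "nNFE", allele_count = round(2e-4 * 2 * 51592),
                       sample_size = 51592)
  expect_false(is_rare(v, nnfe, maf_policy())$rare)

  # absent from every dataset: rare everywhere
  ctl <- dplyr::bind_rows(at, aogc)
  rar <- is_rare(make_variant(pos = 42L), ctl, maf_policy())
  expect_true(all(rar$rare))
  expect_true(all(rar$absent))
})

test_that("qualifying = protein-altering AND rare in every dataset", {
  pol <- maf_policy()
  v_mis <- make_variant()                       # missense, absent everywhere
  v_syn <- make_variant(pos = 10L, consequence = "synonymous SNV")
  v_common <- make_variant(pos = 20L)
  ctl <- make_control(v_common, "nNFE", allele_count = round(0.002 * 2 * 51592),
                      sample_size = 51592)
  q <- qualify_variants(dplyr::bind_rows(v_mis, v_syn, v_common), ctl, pol)

  expect_true(q$qualifies[q$variant_id == v_mis$variant_id])
  expect_false(q$qualifies[q$variant_id == v_syn$variant_id])
  expect_match(q$fail_reasons[q$variant_id == v_syn$variant_id],
               "not_protein_altering")
  expect_false(q$qualifies[q$variant_id == v_common$variant_id])
  expect_match(q$fail_reasons[q$variant_id == v_common$variant_id],
               "common_in_nNFE")

  # zygosity never disqualifies: homozygous carrier still qualifies
  v_hom <- make_variant(pos = 30L, samples = "SALS0002:hom")
  q2 <- qualify_variants(v_hom, ctl, pol)
  expect_true(q2$qualifies)

  # off-target rows carry their own reason
  v_off <- make_variant(pos = 40L, gene = "SOD1", off_target = TRUE)
  q3 <- qualify_variants(v_off, ctl, pol)
  expect_false(q3$qualifies)
  expect_equal(q3$fail_reasons, "off_target")
})

test_that("non-coding classes never qualify at any frequency", {
  pol <- maf_policy()
  for (cls in c("synonymous", "utr5", "utr3", "intronic", "intergenic")) {
    raw <- c(synonymous = "synonymous SNV", utr5 = "UTR5", utr3 = "UTR3",
             intronic = "intronic", intergenic = "intergenic")[[cls]]
    for (ac in c(0, 1, 50)) {
      v <- make_variant(pos = 100L, consequence = raw)
      ctl <- if (ac > 0) {
        make_control(v, "MGRB", allele_count = ac, sample_size = 1144)
      } else {
        make_control(make_variant(pos = 999L), "MGRB", allele_count = 1,
                     sample_size = 1144)
      }
      expect_false(qualify_variants(v, ctl, pol)$qualifies,
                   info = paste(cls, ac))
    }
  }
})

test_that("conjunction law holds over all flag combinations", {
  # brute force: protein-altering x rarity in two datasets
  pol <- maf_policy(default = 0.005, overrides = c(nNFE = 1e-4))
  for (pa in c(TRUE, FALSE)) {
    for (rare1 in c(TRUE, FALSE)) {
      for (rare2 in c(TRUE, FALSE)) {
        v <- make_variant(pos = 77L,
                          consequence = if (pa) "nonsynonymous SNV" else "UTR3")
        ac1 <- if (rare1) 1 else 100          # nNFE threshold 1e-4 ~ 10 alleles
        ac2 <- if (rare2) 1 else 500          # AOGC threshold 0.005 ~ 9 alleles
        ctl <- dplyr::bind_rows(
          make_control(v, "nNFE", allele_count = ac1, sample_size = 51592),
          make_control(v, "AOGC", allele_count = ac2, sample_size = 967))
        q <- qualify_variants(v, ctl, pol)
        expect_identical(q$qualifies, pa && rare1 && rare2,
                         info = paste(pa, rare1, rare2))
        if (!q$qualifies) expect_false(is.na(q$fail_reasons))
      }
    }
  }
})

test_that("lowering a MAF threshold never creates a qualifying variant", {
  set.seed(11)
  strict <- maf_policy(default = 0.002, overrides = c(nNFE = 5e-5))
  lax <- maf_policy(default = 0.005, overrides = c(nNFE = 1e-4))
  for (i in 1:40) {
    v <- make_variant(
      pos = i,
      consequence = sample(c("nonsynonymous SNV", "UTR3", "splicing"), 1))
    ctl <- dplyr::bind_rows(
      make_control(v, "nNFE", allele_count = rpois(1, 6), sample_size = 51592),
      make_control(v, "AOGC", allele_count = rpois(1, 4), sample_size = 967))
    q_strict <- qualify_variants(v, ctl, strict)$qualifies
    q_lax <- qualify_variants(v, ctl, lax)$qualifies
    expect_false(q_strict && !q_lax)
  }
})
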