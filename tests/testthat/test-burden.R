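qualified_fixture <- function() {
  # three qualifying missense variants in two genes:
  #   KMO v1 carried by two individuals, KMO v2 by one of the same two,
  #   KYNU v3 by one homozygote
  v <- dplyr::bind_rows(
    make_variant(chrom = "chr1", pos = 100L, gene = "KMO",
                 transcript = "NM_003679", samples = "SALS0001:het,SALS0002:het"),
    make_variant(chrom = "chr1", pos = 200L, gene = "KMO",
                 transcript = "NM_003679", samples = "SALS0001:het"),
    make_variant(chrom = "chr2", pos = 300L, gene = "KYNU",
                 transcript = "NM_003937", samples = "SALS0003:hom")
  )
  ctl <- dplyr::bind_rows(
    make_control(v[1, ], "MGRB", carrier_count = 4, sample_size = 1144),
    make_control(v[2, ], "MGRB", carrier_count = 1, sample_size = 1144)
  )
  q <- qualify_variants(v, ctl)
  list(v = v, ctl = ctl, q = q)
}

test_that("counting modes split observations vs carriers", {
  fx <- qualified_fixture()
  carriers <- variant_carriers(fx$q[fx$q$qualifies, ])
  # KMO: three (variant, individual) pairs but two distinct individuals
  expect_equal(count_qualifying(carriers, "KMO", "observations"), 3)
  expect_equal(count_qualifying(carriers, "KMO", "carriers"), 2)
  # a homozygote counts once
  expect_equal(count_qualifying(carriers, "KYNU", "observations"), 1)
  expect_equal(count_qualifying(carriers, "KYNU", "carriers"), 1)
  expect_equal(count_qualifying(carriers, "TDO2"), 0)
  expect_error(count_qualifying(carriers, "NOTAGENE", gene_set = kp_gene_set()),
               class = "kpburden_lookup_error")
})

test_that("burden report builds the right 2x2 tables and percentages", {
  fx <- qualified_fixture()
  b <- burden_report(fx$q, fx$ctl, kp_gene_set(), case_n = 614)
  res <- tidy(b)
  expect_equal(nrow(res), 18)  # 18 genes x 1 dataset
  kmo <- res[res$gene == "KMO", ]
  expect_equal(kmo$case_count, 3)
  expect_equal(kmo$control_count, 5)
  expect_equal(kmo$case_pct, round_half_up(100 * 3 / 614, 2))
  expect_equal(kmo$control_pct, round_half_up(100 * 5 / 1144, 2))
  # independent reference for the same table under the minlike rule
  b_ml <- burden_report(fx$q, fx$ctl, kp_gene_set(), case_n = 614,
                        config = burden_config(method = "minlike"))
  expect_equal(tidy(b_ml)$p_value[tidy(b_ml)$gene == "KMO"],
               stats::fisher.test(matrix(c(3, 611, 5, 1139), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-7)
  # genes without qualifying variants are reported with zero counts, p = 1
  expect_equal(res$case_count[res$gene == "TDO2"], 0)
  expect_equal(res$p_value[res$gene == "TDO2"], 1)
  expect_equal(glance(b)$bonferroni_threshold, 0.05 / 18)
})

test_that("carrier counting mode is one flag away", {
  fx <- qualified_fixture()
  b <- burden_report(fx$q, fx$ctl, kp_gene_set(), case_n = 614,
                     config = burden_config(count_mode = "carriers"))
  expect_equal(tidy(b)$case_count[tidy(b)$gene == "KMO"], 2)
})

test_that("all-no-call control records mark a gene n/a, not zero", {
  fx <- qualified_fixture()
  # KYNU's qualifying variant has an explicit no-call record in MGRB
  nocall <- tibble::tibble(
    dataset_id = "MGRB", chrom = "chr2", pos = 300L, ref = "G", alt = "A",
    carrier_count = NA_real_, allele_count = NA_real_, sample_size = 1144) |>
    kpburden:::validate_control_table()
  ctl <- dplyr::bind_rows(fx$ctl, nocall)
  q <- qualify_variants(fx$v, ctl)
  res <- tidy(burden_report(q, ctl, kp_gene_set(), case_n = 614))
  kynu <- res[res$gene == "KYNU", ]
  expect_true(is.na(kynu$p_value))
  expect_equal(kynu$p_display, "n/a")
  expect_match(kynu$note, "nsufficient data")
  # other genes unaffected
  expect_false(is.na(res$p_value[res$gene == "KMO"]))
})

test_that("significance uses strict inequality against the Bonferroni cut", {
  fx <- qualified_fixture()
  b <- burden_report(fx$q, fx$ctl, kp_gene_set(), case_n = 614)
  res <- tidy(b)
  expect_identical(res$significant,
                   !is.na(res$p_value) & res$p_value < b$threshold)
})

test_that("tidy, glance and autoplot work on the fit", {
  fx <- qualified_fixture()
  b <- burden_report(fx$q, fx$ctl, kp_gene_set(), case_n = 614)
  expect_s3_class(tidy(b), "tbl_df")
  g <- glance(b)
  expect_equal(g$n_genes, 18L)
  expect_equal(g$n_datasets, 1L)
  expect_s3_class(ggplot2::autoplot(b), "ggplot")
  expect_output(print(b), "Gene burden")
})
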