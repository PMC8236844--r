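test_that("novelty allows at most one control carrier", {
  expect_true(is_novel(0, FALSE))
  expect_true(is_novel(1, FALSE))   # "only present in a single individual"
  expect_false(is_novel(3, FALSE))
  # dbSNP entry alone does not veto unless configured to
  expect_true(is_novel(0, TRUE))
  expect_false(is_novel(0, TRUE, dbsnp_vetoes = TRUE))
})

test_that("novelty is monotone in control observations", {
  for (n in 0:5) {
    if (!is_novel(n, FALSE)) {
      expect_false(any(vapply((n + 1):(n + 3), is_novel, logical(1),
                              in_dbsnp = FALSE)))
    }
  }
})

test_that("novelty evidence sums carriers across datasets", {
  v <- make_variant()
  ctl <- dplyr::bind_rows(
    make_control(v, "nNFE", carrier_count = 1, sample_size = 51592),
    make_control(v, "MGRB", carrier_count = 1, sample_size = 1144))
  ev <- novelty_evidence(v, ctl)
  expect_equal(ev$total_control_carriers, 2)
  expect_false(is_novel(ev$total_control_carriers))
  # single MGRB individual, absent elsewhere: novel
  ev1 <- novelty_evidence(v, make_control(v, "MGRB", carrier_count = 1,
                                          sample_size = 1144))
  expect_true(is_novel(ev1$total_control_carriers))
})

test_that("sequencing QC boundaries are inclusive at 25X, 0.35/0.65 and GQ 99", {
  obs <- function(depth, alt_reads, gq, zygosity = "het") {
    tibble::tibble(zygosity = zygosity, depth = depth, alt_reads = alt_reads,
                   gq = gq, qc_evaluable = TRUE)
  }
  qc <- function(o) passes_sequencing_qc(o)

  expect_true(qc(obs(25, 12, 99))$qc_pass)                 # 12/25 = 0.48
  r <- qc(obs(24, 12, 99)); expect_false(r$qc_pass); expect_equal(r$qc_reasons, "depth")
  r <- qc(obs(40, 12, 99)); expect_false(r$qc_pass); expect_equal(r$qc_reasons, "balance")
  expect_true(qc(obs(100, 35, 99))$qc_pass)                # balance exactly 0.35
  expect_true(qc(obs(100, 65, 99))$qc_pass)                # balance exactly 0.65
  expect_false(qc(obs(100, 34, 99))$qc_pass)
  expect_false(qc(obs(100, 66, 99))$qc_pass)
  r <- qc(obs(40, 20, 98)); expect_false(r$qc_pass); expect_equal(r$qc_reasons, "gq")
  expect_true(qc(obs(40, 20, 99))$qc_pass)

  # hom/hemi calls skip the balance window
  expect_true(qc(obs(40, 40, 99, zygosity = "hom"))$qc_pass)
  expect_true(qc(obs(40, 40, 99, zygosity = "hemi"))$qc_pass)

  # unevaluable is a third outcome, not a failure
  r <- passes_sequencing_qc(tibble::tibble(
    zygosity = "het", depth = NA_integer_, alt_reads = NA_integer_,
    gq = NA_integer_, qc_evaluable = FALSE))
  expect_true(is.na(r$qc_pass))
  expect_equal(r$qc_reasons, "unevaluable")

  # multiple failures are all reported
  r <- qc(obs(10, 1, 50))
  expect_equal(r$qc_reasons, "depth,balance,gq")

  expect_error(qc_thresholds(allele_balance_window = c(0.6, 0.4)),
               class = "kpburden_config_error")
})

test_that("novel-variant report recovers planted novels and logs QC exclusions", {
  plan <- tibble::tibble(
    gene = c("GOT2", "KYNU", "HAAO", "WARS", "TPH1", "KMO"),
    consequence_class = c("missense", "missense", "splicing", "missense",
                          "missense", "missense"),
    qc = c("pass", "pass", "pass", "fail_depth", "fail_balance", "fail_gq"),
    latent_deleterious = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  sim <- simulate_cohort(sim_params(seed = 99, n_cases = 120, novel_plan = plan))
  q <- qualify_variants(sim$variants, sim$controls)
  rep <- novel_variant_report(q, sim$observations, sim$controls, sim$dbsnp)

  planted <- sim$truth[sim$truth$planted_novel, ]
  passing <- planted$variant_id[planted$qc_plan == "pass"]
  failing <- planted$variant_id[planted$qc_plan != "pass"]

  expect_setequal(intersect(rep$variant_id, planted$variant_id), passing)
  excluded <- attr(rep, "excluded")
  expect_true(all(failing %in% excluded$variant_id))
  reasons <- setNames(excluded$qc_reasons, excluded$variant_id)
  expect_equal(unname(reasons[planted$variant_id[planted$qc_plan == "fail_depth"]]),
               "depth")
  expect_equal(unname(reasons[planted$variant_id[planted$qc_plan == "fail_balance"]]),
               "balance")
  expect_equal(unname(reasons[planted$variant_id[planted$qc_plan == "fail_gq"]]),
               "gq")
  # non-planted reported novels (if any) must be genuinely novel in truth
  extra <- setdiff(rep$variant_id, planted$variant_id)
  expect_true(all(sim$truth$novel[match(extra, sim$truth$variant_id)]))
})

test_that("empty plan yields an empty report", {
  sim <- simulate_cohort(sim_params(
    seed = 5, n_cases = 40, n_sites_per_gene = 3,
    baseline_carrier_prob = 0, novel_plan = default_novel_plan()[0, ]))
  q <- qualify_variants(sim$variants, sim$controls)
  rep <- novel_variant_report(q, sim$observations, sim$controls, sim$dbsnp)
  expect_equal(nrow(rep), 0)
})
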