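test_that("identical parameters and seed give byte-identical fixtures", {
  p <- sim_params(seed = 13, n_cases = 80, n_sites_per_gene = 5)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  f1 <- write_fixtures(simulate_cohort(p), d1)
  f2 <- write_fixtures(simulate_cohort(p), d2)
  for (nm in names(f1)) {
    expect_identical(unname(tools::md5sum(f1[[nm]])),
                     unname(tools::md5sum(f2[[nm]])), info = nm)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("degenerate or infeasible parameters are rejected", {
  expect_error(sim_params(n_cases = 0), class = "kpburden_config_error")
  expect_error(sim_params(enrichment_or = -2), class = "kpburden_config_error")
  expect_error(sim_params(baseline_carrier_prob = 1.4),
               class = "kpburden_config_error")
  expect_error(sim_params(prediction = list(sensitivity = 2, specificity = 0.9,
                                            missingness = 0)),
               class = "kpburden_config_error")
  # a plan outside the panel
  plan <- tibble::tibble(gene = "SOD1", consequence_class = "missense",
                         qc = "pass", latent_deleterious = TRUE)
  expect_error(simulate_cohort(sim_params(novel_plan = plan)),
               class = "kpburden_config_error")
  # feasible probabilities but impossible expected carrier load
  expect_error(
    simulate_cohort(sim_params(seed = 2, n_cases = 10,
                               baseline_carrier_prob = 0.9,
                               enrichment_or = 5000)),
    class = "kpburden_config_error")
})

test_that("prediction simulation honours degenerate settings", {
  p_perfect <- sim_params(prediction = list(sensitivity = 1, specificity = 1,
                                            missingness = 0))
  withr::with_seed(1, {
    prof <- simulate_predictions(TRUE, p_perfect)
  })
  v <- make_variant()
  for (col in names(prof)) v[[col]] <- prof[[col]]
  expect_equal(score_variants(v)$score, 1)

  p_blind <- sim_params(prediction = list(sensitivity = 1, specificity = 1,
                                          missingness = 1))
  withr::with_seed(1, {
    prof2 <- simulate_predictions(TRUE, p_blind)
  })
  v2 <- make_variant()
  for (col in setdiff(names(prof2), c("revel", "bayesdel", "hsf"))) {
    v2[[col]] <- prof2[[col]]
  }
  s <- score_variants(v2)
  expect_true(is.na(s$score))
  expect_equal(s$n_tools, 0L)
})

test_that("planted flags agree with the pipeline run on written fixtures", {
  paths <- shared_fixture_dir()
  sim <- shared_sim()
  res <- suppressMessages(run_pipeline(pipeline_config(
    annotation = paths$annotation, controls = paths$controls,
    vcf = paths$vcf, dbsnp = paths$dbsnp, gene_set = paths$gene_set,
    case_n = sim$params$n_cases)))
  m <- dplyr::inner_join(sim$truth,
                         res$qualified[, c("variant_id", "qualifies")],
                         by = "variant_id")
  expect_equal(nrow(m), nrow(sim$truth))
  expect_identical(m$qualifies, m$qualifying)
})

test_that("case carrier rates track the generating probabilities", {
  sim <- shared_sim()
  # aggregate qualifying case observations across genes should sit near
  # n_cases * baseline (the default world is null: OR = 1, plus 9 planted)
  per_gene <- sim$gene_truth$qualifying_case_observations
  expected <- sim$params$n_cases * sim$params$baseline_carrier_prob
  planted <- table(sim$params$novel_plan$gene)
  pl <- as.integer(planted[sim$gene_truth$gene])
  pl[is.na(pl)] <- 0L
  adj <- per_gene - pl
  # binomial 99.9% band around the expectation, per gene
  hi <- qbinom(0.9995, sim$params$n_cases,
               sim$params$baseline_carrier_prob * 1.05)
  expect_true(all(adj <= hi + 1))
  expect_gt(sum(adj), 0)
})
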