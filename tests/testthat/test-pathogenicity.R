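test_that("per-tool predictions classify per the dbNSFP conventions", {
  expect_equal(classify_tool_prediction("sift", "D"), "deleterious")
  expect_equal(classify_tool_prediction("sift", "T"), "benign")
  expect_equal(classify_tool_prediction("mutationtaster", "."), "missing")
  expect_equal(classify_tool_prediction("mutationtaster", "A"), "deleterious")
  expect_equal(classify_tool_prediction("polyphen2_hdiv", "P"), "deleterious")
  expect_equal(classify_tool_prediction("mutationassessor", c("H", "M", "L")),
               c("deleterious", "deleterious", "benign"))
  # CADD is numeric with an inclusive phred cutoff of 20
  expect_equal(classify_tool_prediction("cadd_phred", c(35, 20, 19.9, NA)),
               c("deleterious", "deleterious", "benign", "missing"))
  expect_error(classify_tool_prediction("alphamissense", "D"),
               class = "kpburden_config_error")
})

test_that("consensus score is the deleterious fraction over tools with results", {
  s <- consensus_score(c(rep("deleterious", 10), "benign", "benign"))
  expect_equal(s$value, 0.83)
  expect_equal(s$n_with_results, 12)
  expect_equal(s$display, "0.83 (12)")

  s4 <- consensus_score(rep("deleterious", 4))
  expect_equal(s4$value, 1)
  expect_equal(s4$display, "1 (4)")

  for (m in 1:5) expect_equal(consensus_score(rep("benign", m))$value, 0)
  expect_error(consensus_score(rep("missing", 12)),
               class = "kpburden_score_error")
})

test_that("consensus is invariant to order and to added missing tools", {
  calls <- c("deleterious", "benign", "deleterious", "missing")
  set.seed(3)
  for (i in 1:10) {
    expect_equal(consensus_score(sample(calls))$value,
                 consensus_score(calls)$value)
  }
  expect_equal(consensus_score(c(calls, rep("missing", 6)))$value,
               consensus_score(calls)$value)
  # value is 1 iff all tools with results call deleterious
  expect_equal(consensus_score(c("deleterious", rep("missing", 11)))$value, 1)
  expect_lt(consensus_score(c(rep("deleterious", 11), "benign"))$value, 1)
})

test_that("REVEL and BayesDel cutoffs are inclusive", {
  expect_equal(call_revel(c(0.8, 0.1, 0.5)),
               c("Pathogenic", "Benign", "Pathogenic"))
  expect_true(is.na(call_revel(NA_real_)))
  expect_error(call_revel(1.2), class = "kpburden_score_error")

  expect_equal(call_bayesdel(c(0.2, -0.3, -0.057)),
               c("Damaging", "Tolerated", "Damaging"))
})

test_that("splicing variants score over the splice-capable tool set", {
  prof <- make_variant(consequence = "splicing",
                       mutationtaster = "A", cadd_phred = 25,
                       bayesdel = 0.1, hsf = "affected")
  s <- score_splicing(prof)
  expect_equal(s$value, 1)
  expect_equal(s$n_with_results, 4)
  expect_equal(s$display, "1 (4)")

  # 1 deleterious of 2 with results
  prof2 <- make_variant(consequence = "splicing",
                        mutationtaster = "N", cadd_phred = 25)
  s2 <- score_splicing(prof2)
  expect_equal(s2$value, 0.5)
  expect_equal(s2$n_with_results, 2)

  # absent HSF verdict drops out of the denominator
  prof3 <- make_variant(consequence = "splicing",
                        mutationtaster = "A", cadd_phred = 25, bayesdel = 0.1)
  expect_equal(score_splicing(prof3)$n_with_results, 3)
})

test_that("score_variants dispatches splice vs missense consensus", {
  v <- dplyr::bind_rows(
    make_variant(sift = "D", polyphen2_hdiv = "D", polyphen2_hvar = "D",
                 lrt = "D", mutationtaster = "A", mutationassessor = "H",
                 fathmm = "D", provean = "D", metasvm = "D", metalr = "D",
                 mcap = "D", cadd_phred = 30, revel = 0.9, bayesdel = 0.3),
    make_variant(pos = 43010561L, chrom = "chr2", gene = "HAAO",
                 consequence = "splicing", mutationtaster = "A",
                 cadd_phred = 28, bayesdel = 0.05, hsf = "affected")
  )
  s <- score_variants(v)
  expect_equal(s$score, c(1, 1))
  expect_equal(s$n_tools, c(12L, 4L))
  expect_equal(s$revel_call, c("Pathogenic", NA))
  expect_equal(s$bayesdel_call, c("Damaging", "Damaging"))

  # 11 deleterious of 12: printed as 0.92
  v2 <- v[1, ]
  v2$sift <- "T"
  expect_equal(score_variants(v2)$score, 0.92)
  expect_equal(score_variants(v2, use_rounded = FALSE)$score, 11 / 12)
})
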