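#' Parameters for the synthetic cohort generator
#'
#' The defaults state the cohort geometry of the motivating study design:
#' 614 cases against three control datasets — a large external reference
#' panel (`nNFE`, n = 51,592) and two population-specific panels (`AOGC`,
#' n = 967; `MGRB`, n = 1,144) — over the 18-gene candidate panel. Variant
#' counts per gene mirror a candidate-gene screen of this size: the site
#' pool is the union of case- and control-ascertained variants, so rare
#' protein-altering sites (most seen only in the large control panel)
#' dominate it, with a complement of synonymous/UTR/intronic sites.
#'
#' @param seed integer RNG seed; identical parameters and seed give
#'   byte-identical fixtures.
#' @param n_cases case cohort size (default 614).
#' @param controls tibble (`dataset_id`, `sample_size`).
#' @param gene_set a [kp_gene_set()].
#' @param n_sites_per_gene non-intergenic variant sites per gene in the
#'   union pool (default 36).
#' @param fraction_protein_altering fraction of pool sites that are
#'   protein-altering (default 0.65; the union pool is protein-altering
#'   rich because every rare coding site in the large control panel enters
#'   it, while non-coding sites are statistically inert here).
#' @param baseline_carrier_prob per-gene probability that a control
#'   individual carries a qualifying variant (default 0.002, the
#'   mid-range of per-gene control carrier rates in screens of this
#'   geometry); site-level minor allele frequencies are drawn and rescaled
#'   to sum to this, capped at half the strictest MAF gate so qualifying
#'   sites stay rare with near certainty after binomial sampling.
#' @param enrichment_or named per-gene case/control odds ratio for the
#'   qualifying burden (unnamed scalar recycles to all genes; default 1 —
#'   the null).
#' @param prop_deleterious fraction of protein-altering sites whose latent
#'   state is truly deleterious (default 0.3).
#' @param prediction list with per-tool `sensitivity`, `specificity` and
#'   `missingness` of the simulated in-silico predictors.
#' @param novel_plan tibble (`gene`, `consequence_class`, `qc`,
#'   `latent_deleterious`) of planted novel variants; `qc` is one of
#'   `pass`, `fail_depth`, `fail_balance`, `fail_gq`. The default plants
#'   nine novel variants in six genes (two of them splicing), all passing
#'   QC, mirroring the shape of the motivating screen.
#' @param depth_mean mean sequencing depth for ordinary case genotypes.
#' @return list of class `kp_sim_params`.
#' @export
sim_params <- function(seed = 1,
                       n_cases = 614,
                       controls = tibble(
                         dataset_id = c("nNFE", "AOGC", "MGRB"),
                         sample_size = c(51592, 967, 1144)),
                       gene_set = kp_gene_set(),
                       n_sites_per_gene = 36,
                       fraction_protein_altering = 0.65,
                       baseline_carrier_prob = 0.002,
                       enrichment_or = 1,
                       prop_deleterious = 0.3,
                       prediction = list(sensitivity = 0.9, specificity = 0.9,
                                         missingness = 0.05),
                       novel_plan = default_novel_plan(),
                       depth_mean = 35) {
  if (!is_count(n_cases) || n_cases < 1) {
    abort("n_cases must be a positive integer", class = "kpburden_config_error")
  }
  if (any(!is_count(controls$sample_size) | controls$sample_size < 1)) {
    abort("control sample sizes must be positive integers",
          class = "kpburden_config_error")
  }
  if (is.null(names(enrichment_or))) {
    enrichment_or <- setNames(rep_len(enrichment_or, nrow(gene_set)),
                              gene_set$symbol)
  } else {
    full <- setNames(rep(1, nrow(gene_set)), gene_set$symbol)
    full[names(enrichment_or)] <- enrichment_or
    enrichment_or <- full
  }
  if (any(enrichment_or <= 0)) {
    abort("enrichment odds ratios must be positive", class = "kpburden_config_error")
  }
  probs <- c(fraction_protein_altering, baseline_carrier_prob, prop_deleterious,
             prediction$sensitivity, prediction$specificity,
             prediction$missingness)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "kpburden_config_error")
  }
  structure(
    list(seed = seed, n_cases = n_cases, controls = controls,
         gene_set = gene_set, n_sites_per_gene = n_sites_per_gene,
         fraction_protein_altering = fraction_protein_altering,
         baseline_carrier_prob = baseline_carrier_prob,
         enrichment_or = enrichment_or, prop_deleterious = prop_deleterious,
         prediction = prediction, novel_plan = novel_plan,
         depth_mean = depth_mean),
    class = "kp_sim_params")
}

#' Default planted-novel-variant plan
#'
#' Nine novel variants in six genes — two intronic splice-acceptor
#' variants in one gene, the rest missense — each planted in exactly one
#' case individual with clean sequencing support.
#'
#' @return tibble (`gene`, `consequence_class`, `qc`,
#'   `latent_deleterious`).
#' @export
default_novel_plan <- function() {
  tibble(
    gene = c("GOT2", "HAAO", "HAAO", "KYNU", "MAOA", "TPH2",
             "WARS", "WARS", "WARS"),
    consequence_class = c("missense", "splicing", "splicing", "missense",
                          "missense", "missense", "missense", "missense",
                          "missense"),
    qc = "pass",
    latent_deleterious = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                           FALSE, FALSE, FALSE)
  )
}

# representative annotation codes per categorical tool
tool_codes <- function() {
  list(
    sift = c(del = "D", ben = "T"),
    polyphen2_hdiv = c(del = "D", ben = "B"),
    polyphen2_hvar = c(del = "D", ben = "B"),
    lrt = c(del = "D", ben = "N"),
    mutationtaster = c(del = "D", ben = "N"),
    mutationassessor = c(del = "H", ben = "L"),
    fathmm = c(del = "D", ben = "T"),
    provean = c(del = "D", ben = "N"),
    metasvm = c(del = "D", ben = "T"),
    metalr = c(del = "D", ben = "T"),
    mcap = c(del = "D", ben = "T")
  )
}

#' Simulate in-silico prediction columns for one variant
#'
#' Each of the 11 categorical tools goes missing with the configured
#' missingness, otherwise calls deleterious with probability `sensitivity`
#' for a truly deleterious variant and `1 - specificity` otherwise; CADD,
#' REVEL and BayesDel are drawn from class-conditional ranges on either
#' side of their published cutoffs. Splicing variants get splice-capable
#' tools only (MutationTaster, CADD, BayesDel, HSF), with REVEL missing.
#'
#' @param latent_deleterious logical: the variant's true functional state.
#' @param params a [sim_params()] (only the `prediction` block is used).
#' @param splicing simulate a splicing variant's profile.
#' @return one-row tibble of prediction columns.
#' @export
simulate_predictions <- function(latent_deleterious, params = sim_params(),
                                 splicing = FALSE) {
  pr <- params$prediction
  p_del <- if (latent_deleterious) pr$sensitivity else 1 - pr$specificity
  codes <- tool_codes()
  draw_cat <- function(tl) {
    if (runif(1) < pr$missingness) return(NA_character_)
    unname(codes[[tl]][if (runif(1) < p_del) "del" else "ben"])
  }
  draw_cadd <- function() {
    if (runif(1) < pr$missingness) return(NA_real_)
    if (runif(1) < p_del) runif(1, 22, 40) else runif(1, 0.5, 18)
  }
  out <- tibble(.rows = 1)
  if (splicing) {
    for (tl in names(codes)) out[[tl]] <- NA_character_
    out$mutationtaster <- draw_cat("mutationtaster")
    out$cadd_phred <- draw_cadd()
    out$revel <- NA_real_
    out$bayesdel <- if (latent_deleterious) runif(1, 0, 0.4) else runif(1, -0.6, -0.1)
    out$hsf <- if (latent_deleterious) "affected" else "not_affected"
  } else {
    for (tl in names(codes)) out[[tl]] <- draw_cat(tl)
    out$cadd_phred <- draw_cadd()
    out$revel <- if (latent_deleterious) runif(1, 0.55, 0.99) else runif(1, 0.01, 0.45)
    out$bayesdel <- if (latent_deleterious) runif(1, 0, 0.4) else runif(1, -0.6, -0.1)
    out$hsf <- NA_character_
  }
  out
}

#' Simulate a case/control cohort with planted ground truth
#'
#' Generates, per gene: a pool of rare protein-altering sites whose minor
#' allele frequencies sum to the configured per-gene carrier probability
#' (these are the qualifying candidates), one protein-altering site too
#' common for the large-panel MAF gate (exercising the filter), and a
#' complement of synonymous/UTR/intronic sites. Control carrier counts are
#' binomial draws from each site's MAF; case carriers are drawn with the
#' site's odds multiplied by the gene's enrichment odds ratio, so the
#' per-gene case/control odds ratio matches the configuration. Planted
#' novel variants appear in exactly one case and no control, with
#' sequencing support dictated by their QC plan.
#'
#' Ground-truth qualifying/novelty flags are computed arithmetically from
#' the realised tables (not by calling the pipeline), so planted-truth
#' recovery is an end-to-end check.
#'
#' @param params a [sim_params()].
#' @return list of class `kp_simulation`: `variants` (annotation-dialect
#'   tibble), `observations` (per-carrier DP/AD/GQ), `controls`, `dbsnp`,
#'   `truth` (per-site flags), `gene_truth`, `sample_ids`, `params`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "kp_sim_params"))
  withr::with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(params) {
  gs <- params$gene_set
  n_cases <- params$n_cases
  sample_ids <- sprintf("SALS%04d", seq_len(n_cases))
  policy <- maf_policy()
  thr_min <- min(maf_threshold_for(policy, params$controls$dataset_id))

  sites <- purrr::map_dfr(seq_len(nrow(gs)), function(i) {
    g <- gs[i, ]
    n_total <- params$n_sites_per_gene
    n_qual <- max(1, round(n_total * params$fraction_protein_altering))
    n_other <- max(0, n_total - n_qual - 1)
    # rare protein-altering pool: mafs rescaled so carrier probs sum to the
    # per-gene baseline, capped at half the strictest MAF gate so realised
    # control counts almost never breach the rarity threshold
    u <- runif(n_qual)
    maf_q <- pmin(params$baseline_carrier_prob / 2 * u / sum(u), thr_min * 0.5)
    class_q <- sample(c("missense", "splicing", "stopgain", "frameshift_indel"),
                      n_qual, replace = TRUE, prob = c(0.92, 0.04, 0.02, 0.02))
    # one protein-altering site common enough to fail the large-panel gate
    maf_c <- runif(1, thr_min * 5, 0.004)
    # non-protein-altering complement
    class_o <- sample(c("synonymous", "utr3", "utr5", "intronic"),
                      n_other, replace = TRUE, prob = c(0.22, 0.45, 0.18, 0.15))
    maf_o <- exp(runif(n_other, log(1e-5), log(0.004)))
    tibble(
      gene = g$symbol,
      transcript = g$transcript,
      chromosome = g$chromosome,
      consequence_class = c(class_q, "missense", class_o),
      maf = c(maf_q, maf_c, maf_o),
      qualifying_pool = c(rep(TRUE, n_qual), FALSE, rep(FALSE, n_other)),
      planted_novel = FALSE,
      qc_plan = NA_character_,
      latent_deleterious = FALSE
    )
  })
  pa <- is_protein_altering(sites$consequence_class)
  sites$latent_deleterious[pa] <- runif(sum(pa)) < params$prop_deleterious

  # planted novel sites: absent from every control and dbSNP, one carrier
  if (nrow(params$novel_plan)) {
    plan <- params$novel_plan
    bad <- setdiff(plan$gene, gs$symbol)
    if (length(bad)) {
      abort(paste0("novel plan names genes outside the panel: ",
                   paste(bad, collapse = ", ")), class = "kpburden_config_error")
    }
    novel_sites <- plan %>%
      left_join(gs %>% select(symbol, transcript, chromosome),
                by = c(gene = "symbol")) %>%
      mutate(maf = 0, qualifying_pool = TRUE, planted_novel = TRUE,
             qc_plan = qc) %>%
      select(-"qc")
    sites <- bind_rows(sites, novel_sites)
  }

  # positions: unique per gene within a synthetic interval on the gene's
  # chromosome (positions are inert to all statistics)
  sites <- sites %>%
    group_by(gene) %>%
    mutate(pos = sort(sample.int(50000L, n())) +
             1000000L * (10L + match(gene[1], gs$symbol))) %>%
    ungroup()
  alleles <- c("A", "C", "G", "T")
  sites$ref <- sample(alleles, nrow(sites), replace = TRUE)
  sites$alt <- unname(vapply(sites$ref, function(r)
    sample(setdiff(alleles, r), 1), character(1)))
  # frameshift sites get a one-base insertion so indels are represented
  fs <- sites$consequence_class == "frameshift_indel"
  sites$alt[fs] <- paste0(sites$ref[fs], sample(alleles, sum(fs), replace = TRUE))
  sites$variant_id <- variant_id(sites$chromosome, sites$pos, sites$ref, sites$alt)

  # feasibility: per-gene case carrier probability must stay below 1
  or <- params$enrichment_or
  case_prob <- function(maf, gene) {
    q <- 1 - (1 - maf)^2
    odds <- q / (1 - q) * or[gene]
    odds / (1 + odds)
  }
  sites$p_case <- case_prob(sites$maf, sites$gene)
  per_gene <- tapply(sites$p_case, sites$gene, sum)
  if (any(per_gene > 1)) {
    abort("infeasible parameters: expected case carriers exceed the cohort",
          class = "kpburden_config_error")
  }

  # control draws
  controls <- tidyr::expand_grid(
    dataset_id = params$controls$dataset_id,
    variant_id = sites$variant_id) %>%
    left_join(sites %>% select(variant_id, chromosome, pos, ref, alt, maf),
              by = "variant_id") %>%
    left_join(params$controls, by = "dataset_id") %>%
    mutate(
      carrier_count = rbinom(dplyr::n(), sample_size, 1 - (1 - maf)^2),
      allele_count = carrier_count
    ) %>%
    filter(carrier_count > 0) %>%
    rename(chrom = chromosome) %>%
    select(dataset_id, chrom, pos, ref, alt, carrier_count, allele_count,
           sample_size) %>%
    validate_control_table()

  # case draws: binomial carriers per site, distinct individuals
  obs <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    n_carry <- if (s$planted_novel) 1L else rbinom(1, n_cases, s$p_case)
    if (n_carry == 0) return(tibble())
    who <- sample(sample_ids, n_carry)
    zyg <- ifelse(runif(n_carry) < s$maf, "hom", "het")
    draw_obs(s, who, zyg, params)
  })

  # dbSNP: sites observed in any control dataset get an rs identifier
  seen <- unique(controls$variant_id[controls$carrier_count > 0])
  dbsnp <- sites %>%
    filter(variant_id %in% seen) %>%
    mutate(rs_id = sprintf("rs9%07d", row_number())) %>%
    select(variant_id, chrom = chromosome, pos, ref, alt, rs_id)

  # annotation table: all sites (union of case- and control-ascertained),
  # with per-site prediction profiles and the carrier column
  preds <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    if (!pa_or_novel(sites[i, ])) return(blank_predictions())
    simulate_predictions(sites$latent_deleterious[i], params,
                         splicing = sites$consequence_class[i] == "splicing")
  })
  carrier_strings <- obs %>%
    group_by(variant_id) %>%
    summarise(samples = paste0(sample_id, ":", zygosity, collapse = ","),
              .groups = "drop")
  variants <- sites %>%
    mutate(
      consequence = annovar_string(consequence_class),
      cdna_change = paste0("c.", ref, pos %% 10000, alt),
      protein_change = if_else(consequence_class == "missense",
                               paste0("p.X", pos %% 1000, "Y"), NA_character_)
    ) %>%
    bind_cols(preds) %>%
    left_join(carrier_strings, by = "variant_id") %>%
    left_join(dbsnp %>% select(variant_id, rs_id), by = "variant_id") %>%
    rename(chrom = chromosome, dbsnp_id = rs_id) %>%
    mutate(off_target = FALSE) %>%
    select(variant_id, chrom, pos, ref, alt, gene, off_target, transcript,
           consequence, consequence_class, cdna_change, protein_change, dbsnp_id,
           all_of(annotation_tool_columns()),
           all_of(annotation_numeric_columns()), hsf, samples)

  truth <- ground_truth(sites, variants, controls, obs, params, policy)

  structure(
    list(variants = variants, observations = obs, controls = controls,
         dbsnp = dbsnp, truth = truth$site, gene_truth = truth$gene,
         sample_ids = sample_ids, params = params),
    class = "kp_simulation")
}

pa_or_novel <- function(site) {
  is_protein_altering(site$consequence_class) || site$planted_novel
}

blank_predictions <- function() {
  out <- tibble(.rows = 1)
  for (tl in names(tool_codes())) out[[tl]] <- NA_character_
  out$cadd_phred <- NA_real_
  out$revel <- NA_real_
  out$bayesdel <- NA_real_
  out$hsf <- NA_character_
  out
}

annovar_string <- function(class) {
  map <- c(missense = "nonsynonymous SNV", synonymous = "synonymous SNV",
           stopgain = "stopgain", stoploss = "stoploss",
           frameshift_indel = "frameshift insertion",
           inframe_indel = "nonframeshift insertion",
           splicing = "splicing", utr5 = "UTR5", utr3 = "UTR3",
           intronic = "intronic", intergenic = "intergenic", other = "other")
  unname(map[class])
}

# genotype support for one site's carriers, honouring the QC plan of
# planted novel variants
draw_obs <- function(site, who, zyg, params) {
  n <- length(who)
  plan <- site$qc_plan
  if (!is.na(plan)) {
    base <- switch(plan,
      pass = list(dp = sample(30:50, n, replace = TRUE), bal = runif(n, 0.45, 0.55),
                  gq = rep(99L, n)),
      fail_depth = list(dp = sample(15:24, n, replace = TRUE),
                        bal = runif(n, 0.45, 0.55), gq = rep(99L, n)),
      fail_balance = list(dp = sample(30:50, n, replace = TRUE),
                          bal = runif(n, 0.15, 0.25), gq = rep(99L, n)),
      fail_gq = list(dp = sample(30:50, n, replace = TRUE),
                     bal = runif(n, 0.45, 0.55),
                     gq = sample(50:89, n, replace = TRUE)),
      abort(paste0("unknown qc plan: ", plan), class = "kpburden_config_error"))
    dp <- base$dp
    alt_reads <- pmin(dp, pmax(0L, as.integer(round(dp * base$bal))))
    gq <- base$gq
  } else {
    dp <- rpois(n, params$depth_mean)
    alt_reads <- ifelse(zyg == "het", rbinom(n, dp, 0.5), dp)
    gq <- ifelse(runif(n) < 0.97, 99L, sample(60:98, n, replace = TRUE))
  }
  tibble(
    variant_id = site$variant_id, chrom = site$chromosome, pos = site$pos,
    ref = site$ref, alt = site$alt, sample_id = who, zygosity = zyg,
    depth = as.integer(dp), alt_reads = as.integer(alt_reads),
    gq = as.integer(gq), qc_evaluable = TRUE
  )
}

# arithmetic ground truth from the realised tables (independent of the
# pipeline's join machinery)
ground_truth <- function(sites, variants, controls, obs, params, policy) {
  ds <- params$controls$dataset_id
  thr <- maf_threshold_for(policy, ds)
  rare_all <- vapply(sites$variant_id, function(vid) {
    rows <- controls[controls$variant_id == vid, ]
    mafs <- setNames(rep(0, length(ds)), ds)
    mafs[rows$dataset_id] <- rows$allele_count / (2 * rows$sample_size)
    all(mafs <= thr)
  }, logical(1))
  total_carriers <- vapply(sites$variant_id, function(vid)
    sum(controls$carrier_count[controls$variant_id == vid]), numeric(1))
  pa <- is_protein_altering(sites$consequence_class)
  case_obs <- table(factor(obs$variant_id, levels = sites$variant_id))

  site_truth <- tibble(
    variant_id = sites$variant_id,
    gene = sites$gene,
    consequence_class = sites$consequence_class,
    generating_maf = sites$maf,
    latent_deleterious = sites$latent_deleterious,
    planted_novel = sites$planted_novel,
    qc_plan = sites$qc_plan,
    protein_altering = pa,
    qualifying = pa & unname(rare_all),
    total_control_carriers = unname(total_carriers),
    novel = pa & unname(rare_all) & unname(total_carriers) <= 1,
    case_observations = as.integer(case_obs)
  )
  gene_truth <- site_truth %>%
    group_by(gene) %>%
    summarise(qualifying_case_observations = sum(case_observations[qualifying]),
              .groups = "drop") %>%
    mutate(enrichment_or = unname(params$enrichment_or[gene]),
           baseline_carrier_prob = params$baseline_carrier_prob)
  list(site = site_truth, gene = gene_truth)
}

#' Write simulation fixtures to disk
#'
#' Emits every pipeline input in its standard on-disk format: the
#' annotation TSV, the case VCF (GT:AD:DP:GQ for the full cohort), one
#' control frequency TSV covering all datasets, the dbSNP lookup TSV, the
#' gene-set YAML, and the ground truth as JSON. All files re-read cleanly
#' with the package's readers.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return named list of file paths.
#' @export
write_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "kp_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    annotation = file.path(dir, "annotation.tsv"),
    vcf = file.path(dir, "cases.vcf"),
    controls = file.path(dir, "controls.tsv"),
    dbsnp = file.path(dir, "dbsnp.tsv"),
    gene_set = file.path(dir, "gene_set.yaml"),
    truth = file.path(dir, "truth.json")
  )
  write_annotated_variants(sim$variants, paths$annotation)
  write_case_vcf(sim$observations, sim$sample_ids, paths$vcf)
  write_control_frequencies(sim$controls, paths$controls)
  readr::write_tsv(sim$dbsnp %>% select(chrom, pos, ref, alt, rs_id),
                   paths$dbsnp, progress = FALSE)
  write_gene_set(sim$params$gene_set, paths$gene_set)
  jsonlite::write_json(
    list(site = sim$truth, gene = sim$gene_truth,
         n_cases = sim$params$n_cases),
    paths$truth, auto_unbox = TRUE, digits = NA, na = "null")
  paths
}

#' Write a gene set config as YAML
#'
#' @param gene_set a [kp_gene_set()] tibble.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gene_set, path) {
  genes <- purrr::pmap(gene_set, function(symbol, aliases, transcript,
                                          chromosome, pathway_group) {
    list(symbol = symbol, aliases = as.list(aliases), transcript = transcript,
         chromosome = chromosome, pathway_group = pathway_group)
  })
  yaml::write_yaml(list(genes = genes), path)
  invisible(path)
}
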