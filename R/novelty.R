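#' Sequencing-accuracy QC thresholds for novel calls
#'
#' Novel calls are only trusted when the supporting genotype looks clean:
#' base coverage of at least 25x, a heterozygous allele balance within
#' 50:50 +/- 15% (i.e. alternate-read fraction in \[0.35, 0.65\],
#' inclusive), and a genotype quality of 99 (the cap emitted by standard
#' callers; encoded as `>= 99`). The balance window only applies to
#' heterozygous calls — a 50:50 expectation is meaningless for hom/hemi.
#'
#' @param min_depth minimum read depth (default 25).
#' @param allele_balance_window inclusive low/high alternate-read fraction
#'   bounds for het calls (default `c(0.35, 0.65)`).
#' @param min_gq minimum genotype quality (default 99).
#' @return an object of class `kp_qc_thresholds`.
#' @export
qc_thresholds <- function(min_depth = 25, allele_balance_window = c(0.35, 0.65),
                          min_gq = 99) {
  w <- allele_balance_window
  if (length(w) != 2 || !(0 < w[1] && w[1] < 0.5 && 0.5 < w[2] && w[2] < 1)) {
    abort("allele balance window must straddle 0.5 within (0, 1)",
          class = "kpburden_config_error")
  }
  structure(list(min_depth = min_depth, allele_balance_window = w,
                 min_gq = min_gq), class = "kp_qc_thresholds")
}

#' Apply sequencing QC to genotype observations
#'
#' Adds a three-valued QC outcome to each observation: `TRUE` (pass),
#' `FALSE` (fail, with reasons among `depth`, `balance`, `gq`), or `NA`
#' (unevaluable — DP/AD/GQ missing from the call; reason `unevaluable`).
#' All boundaries are inclusive: DP 25, balance 0.35 and 0.65, GQ 99 each
#' pass.
#'
#' @param observations tibble from [read_case_vcf()] (columns `zygosity`,
#'   `depth`, `alt_reads`, `gq`, `qc_evaluable`).
#' @param thresholds a [qc_thresholds()].
#' @return `observations` with added `qc_pass` (logical, `NA` =
#'   unevaluable) and `qc_reasons`.
#' @export
passes_sequencing_qc <- function(observations, thresholds = qc_thresholds()) {
  t <- thresholds
  evaluable <- if ("qc_evaluable" %in% names(observations)) {
    observations$qc_evaluable
  } else {
    !is.na(observations$depth) & !is.na(observations$alt_reads) &
      !is.na(observations$gq)
  }
  balance <- observations$alt_reads / observations$depth
  het <- observations$zygosity == "het"
  ok_depth <- observations$depth >= t$min_depth
  ok_balance <- !het | (balance >= t$allele_balance_window[1] &
                          balance <= t$allele_balance_window[2])
  ok_gq <- observations$gq >= t$min_gq
  pass <- ifelse(evaluable, ok_depth & ok_balance & ok_gq, NA)
  reasons <- purrr::pmap_chr(
    list(evaluable, ok_depth, ok_balance, ok_gq),
    function(ev, d, b, g) {
      if (!ev) return("unevaluable")
      r <- c(if (isFALSE(d)) "depth", if (isFALSE(b)) "balance",
             if (isFALSE(g)) "gq")
      if (length(r)) paste(r, collapse = ",") else NA_character_
    })
  observations %>% mutate(qc_pass = pass, qc_reasons = reasons)
}

#' Summarise control evidence for the novelty call
#'
#' Counts control carriers of each variant across all configured datasets
#' (using carrier counts where available, otherwise allele counts as a
#' conservative stand-in) and flags dbSNP presence, from a supplied lookup
#' table and/or an rs identifier already on the annotation record.
#'
#' @param variants annotated variant tibble.
#' @param controls control frequency tibble.
#' @param dbsnp optional tibble with `chrom`, `pos`, `ref`, `alt` (and
#'   optionally `rs_id`) listing dbSNP entries.
#' @return tibble: `variant_id`, per-dataset carrier total
#'   `total_control_carriers`, `in_dbsnp`.
#' @export
novelty_evidence <- function(variants, controls, dbsnp = NULL) {
  look <- control_lookup(controls, variants)
  totals <- look %>%
    mutate(n_carriers = dplyr::coalesce(carrier_count, allele_count, 0)) %>%
    group_by(variant_id) %>%
    summarise(total_control_carriers = sum(n_carriers), .groups = "drop")
  dbsnp_ids <- character()
  if (!is.null(dbsnp) && nrow(dbsnp)) {
    dbsnp_ids <- variant_id(dbsnp$chrom, dbsnp$pos, dbsnp$ref, dbsnp$alt)
  }
  annotated_rs <- if ("dbsnp_id" %in% names(variants)) {
    variants$variant_id[!is.na(variants$dbsnp_id)]
  } else {
    character()
  }
  tibble(variant_id = unique(variants$variant_id)) %>%
    left_join(totals, by = "variant_id") %>%
    mutate(
      total_control_carriers = dplyr::coalesce(total_control_carriers, 0),
      in_dbsnp = variant_id %in% c(dbsnp_ids, annotated_rs)
    )
}

#' Novelty call from control evidence
#'
#' A variant is novel when it is absent from, or present in at most one
#' individual across, all control datasets. By default the single allowed
#' carrier is summed across datasets (the stricter reading); set
#' `mode = "per_dataset"` to allow one carrier in each dataset. A dbSNP
#' entry alone does not veto novelty unless `dbsnp_vetoes = TRUE` — rs
#' identifiers without frequency evidence exist, so by default dbSNP only
#' matters through the control counts.
#'
#' @param total_control_carriers integer vector (or, in `per_dataset`
#'   mode, the maximum per-dataset carrier count).
#' @param in_dbsnp logical vector.
#' @param max_carriers allowed carriers (default 1).
#' @param dbsnp_vetoes if `TRUE`, any dbSNP entry makes a variant
#'   non-novel.
#' @return logical vector.
#' @export
is_novel <- function(total_control_carriers, in_dbsnp = FALSE,
                     max_carriers = 1, dbsnp_vetoes = FALSE) {
  total_control_carriers <= max_carriers & (!dbsnp_vetoes | !in_dbsnp)
}

#' Report novel qualifying variants (Table-2 style)
#'
#' Runs the tail of the pipeline for novelty: qualifying variants that are
#' novel against the controls/dbSNP and whose every case observation
#' passes sequencing QC are reported with their consensus pathogenicity
#' score, REVEL/BayesDel calls and variant nomenclature. Variants excluded
#' by QC are attached as the `"excluded"` attribute with their reasons.
#'
#' @param qualified output of [qualify_variants()] (must carry prediction
#'   columns).
#' @param observations genotype observations from [read_case_vcf()];
#'   `NULL` skips the QC gate (all novel qualifying variants reported).
#' @param controls control frequency tibble.
#' @param dbsnp optional dbSNP lookup tibble.
#' @param thresholds a [qc_thresholds()].
#' @param tool_map a [tool_prediction_map()].
#' @param dbsnp_vetoes,mode passed to the novelty rule; `mode` is either
#'   `"total"` (default) or `"per_dataset"`.
#' @return tibble with one row per reported variant: `gene`, `position`,
#'   `type`, `transcript`, `cdna_change`, `protein_change`, `score`,
#'   `n_tools`, `score_display`, `revel_call`, `bayesdel_call`,
#'   `sample_id`, `inspect` (placeholder for manual review).
#' @export
novel_variant_report <- function(qualified, observations = NULL, controls,
                                 dbsnp = NULL, thresholds = qc_thresholds(),
                                 tool_map = tool_prediction_map(),
                                 dbsnp_vetoes = FALSE, mode = c("total", "per_dataset")) {
  mode <- match.arg(mode)
  ev <- novelty_evidence(qualified, controls, dbsnp)
  if (mode == "per_dataset") {
    per <- control_lookup(controls, qualified) %>%
      mutate(n_carriers = dplyr::coalesce(carrier_count, allele_count, 0)) %>%
      group_by(variant_id) %>%
      summarise(total_control_carriers = max(n_carriers), .groups = "drop")
    ev <- ev %>% select(-"total_control_carriers") %>%
      left_join(per, by = "variant_id")
  }
  ev$novel <- is_novel(ev$total_control_carriers, ev$in_dbsnp,
                       dbsnp_vetoes = dbsnp_vetoes)
  cand <- qualified %>%
    filter(qualifies, !is.na(samples)) %>%   # must be observed in a case
    left_join(ev %>% select(variant_id, novel), by = "variant_id") %>%
    filter(novel)
  if (!nrow(cand)) {
    out <- empty_novel_report()
    attr(out, "excluded") <- empty_novel_report(excluded = TRUE)
    return(out)
  }

  if (!is.null(observations)) {
    qc <- passes_sequencing_qc(observations, thresholds) %>%
      group_by(variant_id) %>%
      summarise(
        qc_pass = all(qc_pass %in% TRUE),
        qc_reasons = paste(stats::na.omit(unique(qc_reasons)), collapse = ","),
        sample_id = paste(sample_id, collapse = ","),
        .groups = "drop"
      )
    cand <- cand %>% left_join(qc, by = "variant_id") %>%
      mutate(
        qc_pass = dplyr::coalesce(qc_pass, FALSE),
        qc_reasons = if_else(is.na(qc_reasons) | qc_reasons == "",
                             if_else(qc_pass, NA_character_, "no_observation"),
                             qc_reasons)
      )
  } else {
    cand$qc_pass <- TRUE
    cand$qc_reasons <- NA_character_
    cand$sample_id <- NA_character_
  }

  scored <- score_variants(cand, tool_map = tool_map)
  report_cols <- function(x) {
    x %>%
      mutate(
        position = paste0(chrom, ":", pos),
        type = if_else(consequence_class == "splicing", "splicing", "exonic")
      ) %>%
      select(variant_id, gene, position, type, transcript, cdna_change,
             protein_change, score, n_tools, score_display, revel_call,
             bayesdel_call, sample_id, qc_pass, qc_reasons) %>%
      mutate(inspect = NA_character_) %>%
      arrange(gene, position)
  }
  out <- report_cols(scored %>% filter(qc_pass))
  attr(out, "excluded") <- report_cols(scored %>% filter(!qc_pass))
  out
}

empty_novel_report <- function(excluded = FALSE) {
  tibble(
    variant_id = character(), gene = character(), position = character(),
    type = character(), transcript = character(), cdna_change = character(),
    protein_change = character(), score = numeric(), n_tools = integer(),
    score_display = character(), revel_call = character(),
    bayesdel_call = character(), sample_id = character(),
    qc_pass = logical(), qc_reasons = character(), inspect = character()
  )
}
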