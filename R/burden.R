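#' Burden test configuration
#'
#' @param method two-sided exact-test method (default `"central"`; see
#'   [fisher_exact_2x2()]).
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests for the Bonferroni correction; `NULL`
#'   (default) corrects for the number of genes in the panel — not genes
#'   times datasets.
#' @param count_mode `"observations"` counts distinct (variant,
#'   individual) pairs — a homozygote counts once; `"carriers"` counts
#'   distinct individuals with at least one qualifying variant.
#' @param unit `"individuals"` builds 2x2 tables as (count, cohort size -
#'   count); `"alleles"` uses allele counts against `2N` chromosomes (for
#'   allele-count control tables).
#' @return list of class `kp_burden_config`.
#' @export
burden_config <- function(method = c("central", "minlike", "blaker", "greater"),
                          alpha = 0.05, n_tests = NULL,
                          count_mode = c("observations", "carriers"),
                          unit = c("individuals", "alleles")) {
  structure(list(method = match.arg(method), alpha = alpha, n_tests = n_tests,
                 count_mode = match.arg(count_mode), unit = match.arg(unit)),
            class = "kp_burden_config")
}

#' Count qualifying variants for one gene in the case cohort
#'
#' @param carriers long (variant, individual) tibble of qualifying
#'   variants only, as produced by [variant_carriers()] on the qualifying
#'   subset.
#' @param gene gene symbol.
#' @param mode `"observations"` (distinct variant x individual pairs; a
#'   homozygous carrier counts once) or `"carriers"` (distinct
#'   individuals).
#' @param gene_set optional [kp_gene_set()]; when given, an unknown gene
#'   is an error rather than a silent zero.
#' @return integer count.
#' @export
count_qualifying <- function(carriers, gene,
                             mode = c("observations", "carriers"),
                             gene_set = NULL) {
  mode <- match.arg(mode)
  if (!is.null(gene_set) && !gene %in% gene_set$symbol) {
    abort(paste0("unknown gene: ", gene), class = "kpburden_lookup_error")
  }
  sub <- carriers[carriers$gene == gene, , drop = FALSE]
  if (mode == "observations") {
    nrow(distinct(sub, variant_id, sample_id))
  } else {
    n_distinct(sub$sample_id)
  }
}

#' Per-gene case/control burden of qualifying variants
#'
#' For each gene and each control dataset, compares the number of
#' qualifying-variant observations in cases against the control dataset's
#' count with an exact conditional 2x2 test, then applies a Bonferroni
#' correction over the panel. This mirrors the published report layout:
#' one row per gene x dataset with counts, percentages (2 dp of the cohort
#' denominator), the p-value, and the significance call under
#' `p < alpha / n_genes`.
#'
#' Control counts are the summed carrier counts (or allele counts, for
#' `unit = "alleles"`) of the gene's qualifying variants in that dataset.
#' A gene x dataset pair whose qualifying variants are all unascertained
#' in that dataset (no-call records) is reported `n/a` — insufficient
#' data to calculate gene burden — rather than zero.
#'
#' @param qualified output of [qualify_variants()].
#' @param controls control frequency tibble.
#' @param gene_set a [kp_gene_set()]; genes with no qualifying variants
#'   are still reported (zero counts).
#' @param case_n case cohort size (denominator for case percentages).
#' @param config a [burden_config()].
#' @return object of class `kp_burden`: use [tidy()][generics::tidy] for
#'   the per-row results, [glance()][generics::glance] for the test
#'   summary, and `autoplot()` for a significance plot.
#' @export
burden_report <- function(qualified, controls, gene_set = kp_gene_set(),
                          case_n = 614, config = burden_config()) {
  qual <- qualified %>% filter(qualifies)
  carriers <- if (nrow(qual)) variant_carriers(qual) else
    tibble(variant_id = character(), gene = character(), sample_id = character())
  look <- control_lookup(controls, qual$variant_id,
                         datasets = unique(controls$dataset_id)) %>%
    left_join(qual %>% select(variant_id, gene), by = "variant_id")

  sizes <- controls %>% distinct(dataset_id, sample_size)
  grid <- tidyr::expand_grid(gene = gene_set$symbol,
                             dataset_id = sizes$dataset_id) %>%
    left_join(sizes, by = "dataset_id")

  case_counts <- tibble(
    gene = gene_set$symbol,
    case_count = unname(vapply(gene_set$symbol, function(g)
      as.integer(count_qualifying(carriers, g, config$count_mode)), integer(1)))
  )
  control_counts <- look %>%
    group_by(gene, dataset_id) %>%
    summarise(
      control_count = sum(dplyr::coalesce(
        if (config$unit == "alleles") allele_count else
          dplyr::coalesce(carrier_count, allele_count), 0)),
      n_sites = dplyr::n(),
      n_no_data = sum(no_data),
      .groups = "drop"
    )

  n_tests <- config$n_tests %||% nrow(gene_set)
  threshold <- bonferroni_threshold(config$alpha, n_tests)
  case_denom <- if (config$unit == "alleles") 2 * case_n else case_n

  res <- grid %>%
    left_join(case_counts, by = "gene") %>%
    left_join(control_counts, by = c("gene", "dataset_id")) %>%
    mutate(
      control_denom = if (config$unit == "alleles") 2 * sample_size else sample_size,
      insufficient = !is.na(n_no_data) & n_sites > 0 & n_no_data == n_sites,
      control_count = if_else(is.na(control_count), 0, control_count)
    )
  res$p_value <- fisher_exact_2x2(
    res$case_count, case_denom - res$case_count,
    res$control_count, res$control_denom - res$control_count,
    method = config$method)
  res <- res %>%
    mutate(
      case_pct = round_half_up(100 * case_count / case_n, 2),
      control_pct = round_half_up(100 * control_count / sample_size, 2),
      p_value = if_else(insufficient, NA_real_, p_value),
      control_count = if_else(insufficient, NA_real_, control_count),
      control_pct = if_else(insufficient, NA_real_, control_pct),
      p_display = if_else(is.na(p_value), "n/a",
                          ifelse(p_value == 1, "1", sprintf("%.4f", p_value))),
      significant = !is.na(p_value) & p_value < threshold,
      note = if_else(insufficient,
                     "insufficient data available to calculate gene burden",
                     NA_character_)
    ) %>%
    select(gene, dataset_id, case_count, case_pct, control_count, control_pct,
           p_value, p_display, significant, note)

  structure(
    list(results = res, config = config, case_n = case_n,
         n_tests = n_tests, threshold = threshold,
         control_sizes = sizes),
    class = "kp_burden"
  )
}

#' @export
print.kp_burden <- function(x, ...) {
  cat("Gene burden of qualifying variants\n")
  cat("  cases n =", x$case_n, "| datasets:",
      paste0(x$control_sizes$dataset_id, " (n=", x$control_sizes$sample_size, ")",
             collapse = ", "), "\n")
  cat("  method =", x$config$method, "| Bonferroni:", x$config$alpha, "/",
      x$n_tests, "=", signif(x$threshold, 3), "\n\n")
  print(x$results, n = Inf)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a burden fit into its per-(gene, dataset) rows
#'
#' @param x a `kp_burden` object.
#' @param ... unused.
#' @return tibble with one row per gene x control dataset.
#' @method tidy kp_burden
#' @export
tidy.kp_burden <- function(x, ...) x$results

#' One-row summary of a burden fit
#'
#' @param x a `kp_burden` object.
#' @param ... unused.
#' @return tibble with panel size, test configuration and the number of
#'   significant gene x dataset pairs.
#' @method glance kp_burden
#' @export
glance.kp_burden <- function(x, ...) {
  tibble(
    n_genes = n_distinct(x$results$gene),
    n_datasets = nrow(x$control_sizes),
    case_n = x$case_n,
    method = x$config$method,
    alpha = x$config$alpha,
    n_tests = x$n_tests,
    bonferroni_threshold = x$threshold,
    n_significant = sum(x$results$significant, na.rm = TRUE)
  )
}
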