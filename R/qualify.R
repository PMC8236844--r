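#' Minor-allele-frequency rarity policy
#'
#' Rare variants are defined by dataset-specific inclusive MAF thresholds:
#' 0.005 by default, with an override of 0.0001 for the very large gnomAD
#' non-Finnish European cohort (the stricter gate compensates for its
#' sample size).
#'
#' @param default inclusive threshold applied to any dataset without an
#'   override (default 0.005).
#' @param overrides named numeric vector, dataset id -> threshold
#'   (default `c(nNFE = 1e-4)`).
#' @return an object of class `kp_maf_policy`.
#' @export
maf_policy <- function(default = 0.005, overrides = c(nNFE = 1e-4)) {
  thr <- c(default, overrides)
  if (any(thr <= 0 | thr > 0.5)) {
    abort("MAF thresholds must lie in (0, 0.5]", class = "kpburden_config_error")
  }
  structure(list(default = default, overrides = overrides),
            class = "kp_maf_policy")
}

#' @export
print.kp_maf_policy <- function(x, ...) {
  cat("<kp_maf_policy> default <=", x$default, "\n")
  for (d in names(x$overrides)) cat("  ", d, "<=", x$overrides[[d]], "\n")
  invisible(x)
}

#' Threshold applying to a dataset under a policy
#'
#' @param policy a [maf_policy()].
#' @param dataset_id character vector of dataset ids.
#' @return numeric vector of inclusive thresholds.
#' @export
maf_threshold_for <- function(policy, dataset_id) {
  out <- unname(policy$overrides[dataset_id])
  out[is.na(out)] <- policy$default
  out
}

#' Per-dataset rarity of variants
#'
#' A variant is rare in a dataset iff its MAF there is at or below the
#' dataset's threshold (inclusive, "equal to or less than"); a variant
#' absent from a dataset has MAF 0 and is therefore rare. Datasets with an
#' unascertained record (`no_data`) count as rare too — absence of
#' evidence cannot disqualify — but the flag is carried through so burden
#' reporting can mark insufficient data.
#'
#' @param variants annotated variant tibble (or character vector of
#'   `variant_id`s).
#' @param controls control frequency tibble covering one or more datasets.
#' @param policy a [maf_policy()].
#' @return long tibble `variant_id` x `dataset_id` with `maf`, `threshold`,
#'   `rare`, `absent`, `no_data`.
#' @export
is_rare <- function(variants, controls, policy = maf_policy()) {
  control_lookup(controls, variants) %>%
    mutate(
      threshold = maf_threshold_for(policy, dataset_id),
      rare = is.na(maf) | maf <= threshold
    )
}

#' Apply the qualifying-variant filter
#'
#' A variant qualifies for burden analysis iff it is protein-altering
#' (missense, indel, splicing, stop gain/loss) AND rare in every control
#' dataset under the policy's thresholds. Zygosity never disqualifies:
#' both heterozygous and homozygous carriers count. Off-target rows (gene
#' not in the panel) are never qualified and carry the reason
#' `"off_target"`.
#'
#' @param variants annotated variant tibble from [read_annotated_variants()].
#' @param controls control frequency tibble.
#' @param policy a [maf_policy()].
#' @return `variants` with added columns `protein_altering`, `qualifies`,
#'   and `fail_reasons` (comma-joined reason codes, `NA` when qualifying),
#'   plus wide per-dataset rarity columns `rare_in_<dataset>`.
#' @export
qualify_variants <- function(variants, controls, policy = maf_policy()) {
  rar <- is_rare(variants, controls, policy)
  rare_wide <- rar %>%
    select(variant_id, dataset_id, rare) %>%
    tidyr::pivot_wider(names_from = dataset_id, values_from = rare,
                       names_prefix = "rare_in_")
  rare_all <- rar %>%
    group_by(variant_id) %>%
    summarise(
      all_rare = all(rare),
      common_in = paste0("common_in_", dataset_id[!rare], collapse = ","),
      .groups = "drop"
    )
  out <- variants %>%
    mutate(protein_altering = is_protein_altering(consequence_class)) %>%
    left_join(rare_wide, by = "variant_id") %>%
    left_join(rare_all, by = "variant_id")
  out %>%
    mutate(
      all_rare = dplyr::coalesce(all_rare, TRUE),
      qualifies = !off_target & protein_altering & all_rare,
      fail_reasons = dplyr::case_when(
        qualifies ~ NA_character_,
        off_target ~ "off_target",
        TRUE ~ paste0(
          ifelse(protein_altering, "", "not_protein_altering"),
          ifelse(!protein_altering & !all_rare, ",", ""),
          ifelse(all_rare, "", common_in))
      )
    ) %>%
    select(-"all_rare", -"common_in")
}
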