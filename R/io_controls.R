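#' Read a control-cohort frequency table
#'
#' Control datasets (e.g. the gnomAD non-Finnish European non-neurological
#' subset, or population-specific whole-exome/genome panels) are consumed
#' as per-variant summary tables: tab-separated with columns `dataset_id`,
#' `chrom`, `pos`, `ref`, `alt`, `carrier_count`, `allele_count`,
#' `sample_size`. "." marks an unascertained count. Either count column may
#' be absent for a record; a record with both counts missing is treated as
#' "no data" (relevant for the insufficient-data flag in burden reports).
#'
#' MAF is computed as `allele_count / (2 * sample_size)` when the allele
#' count is present; with only a carrier count it is approximated as
#' `carrier_count / (2 * sample_size)` (a lower bound, exact when all
#' carriers are heterozygous).
#'
#' @param path TSV file.
#' @param dataset_id,sample_size optional overrides applied to every record
#'   (useful when the file carries only variant keys and counts).
#' @return tibble with the columns above plus `variant_id` and `maf`.
#' @export
read_control_frequencies <- function(path, dataset_id = NULL, sample_size = NULL) {
  if (!file.exists(path)) {
    abort(paste0("control table not found: ", path), class = "kpburden_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE)
  for (col in c("dataset_id", "carrier_count", "allele_count", "sample_size")) {
    if (!col %in% names(df)) df[[col]] <- "."
  }
  missing_cols <- setdiff(c("chrom", "pos", "ref", "alt"), names(df))
  if (length(missing_cols)) {
    abort(paste0("control table lacks columns: ", paste(missing_cols, collapse = ", ")),
          class = "kpburden_format_error")
  }
  out <- tibble(
    dataset_id = if (!is.null(dataset_id)) dataset_id else dot_to_na(df$dataset_id),
    chrom = normalise_chrom(df$chrom),
    pos = as.integer(suppressWarnings(as.numeric(df$pos))),
    ref = df$ref,
    alt = df$alt,
    carrier_count = numeric_or_na(df$carrier_count),
    allele_count = numeric_or_na(df$allele_count),
    sample_size = if (!is.null(sample_size)) sample_size else numeric_or_na(df$sample_size)
  )
  if (anyNA(out$dataset_id) || anyNA(out$sample_size)) {
    abort("dataset_id and sample_size must be given per record or as arguments",
          class = "kpburden_format_error")
  }
  validate_control_table(out)
}

validate_control_table <- function(out) {
  with_cc <- !is.na(out$carrier_count)
  with_ac <- !is.na(out$allele_count)
  if (any(out$carrier_count[with_cc] < 0) || any(out$allele_count[with_ac] < 0)) {
    abort("negative counts in control table", class = "kpburden_format_error")
  }
  if (any(out$carrier_count[with_cc] > out$sample_size[with_cc])) {
    abort("carrier_count exceeds sample_size", class = "kpburden_format_error")
  }
  if (any(out$allele_count[with_ac] > 2 * out$sample_size[with_ac])) {
    abort("allele_count exceeds 2 * sample_size", class = "kpburden_format_error")
  }
  out %>%
    mutate(
      variant_id = variant_id(chrom, pos, ref, alt),
      maf = dplyr::coalesce(allele_count, carrier_count) / (2 * sample_size)
    ) %>%
    select(variant_id, dplyr::everything())
}

#' Control-table lookup with explicit absence
#'
#' For every (variant, dataset) combination returns the control record;
#' variants absent from a dataset come back with zero counts, `maf = 0`
#' exactly, and `absent = TRUE` — lookup never fails for unseen keys.
#' Records present but with both counts unascertained (".") keep `NA`
#' counts and are flagged `no_data`.
#'
#' @param controls control tibble (rows from one or more datasets,
#'   [read_control_frequencies()] format), or `NULL` for no controls.
#' @param variants tibble with a `variant_id` column (or a character vector
#'   of variant ids).
#' @param datasets dataset ids to cover; defaults to those present in
#'   `controls`.
#' @return long tibble: `variant_id` x `dataset_id` with `carrier_count`,
#'   `allele_count`, `sample_size`, `maf`, `absent`, `no_data`.
#' @export
control_lookup <- function(controls, variants, datasets = NULL) {
  ids <- if (is.character(variants)) variants else variants$variant_id
  if (is.null(controls) || !nrow(controls)) {
    if (is.null(datasets)) return(tibble(
      variant_id = character(), dataset_id = character(),
      carrier_count = numeric(), allele_count = numeric(),
      sample_size = numeric(), maf = numeric(), absent = logical(),
      no_data = logical()))
    controls <- tibble(variant_id = character(), dataset_id = character(),
                       carrier_count = numeric(), allele_count = numeric(),
                       sample_size = numeric(), maf = numeric())
  }
  datasets <- datasets %||% unique(controls$dataset_id)
  sizes <- controls %>% distinct(dataset_id, sample_size)
  recs <- controls %>%
    select(variant_id, dataset_id, carrier_count, allele_count, maf) %>%
    mutate(.present = TRUE)
  tidyr::expand_grid(variant_id = unique(ids), dataset_id = datasets) %>%
    left_join(recs, by = c("variant_id", "dataset_id")) %>%
    left_join(sizes, by = "dataset_id") %>%
    mutate(
      absent = is.na(.present),
      no_data = !absent & is.na(carrier_count) & is.na(allele_count),
      carrier_count = if_else(absent, 0, carrier_count),
      allele_count = if_else(absent, 0, allele_count),
      maf = if_else(absent, 0, maf)
    ) %>%
    select(-".present")
}

#' Write a control frequency table
#'
#' @param controls control tibble in [read_control_frequencies()] layout.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_control_frequencies <- function(controls, path) {
  df <- controls %>%
    select(dataset_id, chrom, pos, ref, alt, carrier_count, allele_count,
           sample_size) %>%
    mutate(across(c(carrier_count, allele_count), ~ na_to_dot(as.character(.x))))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
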