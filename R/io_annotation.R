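# The versioned annotation TSV dialect (v1). Tab-separated, UTF-8, header
# row, "." for missing cells (dbNSFP convention). One row per
# variant-transcript annotation; `samples` lists case carriers as
# "ID:zygosity" pairs separated by commas.
annotation_tool_columns <- function() {
  c("sift", "polyphen2_hdiv", "polyphen2_hvar", "lrt", "mutationtaster",
    "mutationassessor", "fathmm", "provean", "metasvm", "metalr", "mcap")
}

annotation_numeric_columns <- function() {
  c("cadd_phred", "revel", "bayesdel")
}

annotation_columns <- function() {
  c("chrom", "pos", "ref", "alt", "gene", "transcript", "consequence",
    "cdna_change", "protein_change", "dbsnp_id",
    annotation_tool_columns(), annotation_numeric_columns(), "hsf", "samples")
}

#' Read an annotated variant table
#'
#' Reads the package's tab-separated annotation dialect (an
#' ANNOVAR/dbNSFP-style per-variant table, 1-based hg19 coordinates, "."
#' for missing cells) into a tidy tibble: one row per variant, with the
#' twelve per-tool prediction columns, REVEL/BayesDel scores, an optional
#' Human Splicing Finder verdict column, and the case carriers in a
#' `samples` column.
#'
#' Rows whose gene does not resolve in `gene_set` (by symbol or alias) are
#' retained and flagged `off_target = TRUE`; nothing is silently dropped.
#' When a variant carries annotations on several transcripts, the row on
#' the gene's canonical transcript wins; otherwise the most severe
#' consequence across transcripts is kept (collapse is per variant key).
#'
#' @param path TSV file in the dialect above.
#' @param gene_set a [kp_gene_set()] tibble used to resolve gene symbols.
#' @param vocabulary consequence vocabulary, see [consequence_vocabulary()].
#' @param collapse collapse multi-transcript rows to one row per variant
#'   (default `TRUE`).
#' @return tibble with one row per variant (after collapse), columns
#'   `variant_id`, coordinates/alleles, resolved `gene`, `off_target`,
#'   `consequence` (raw string), `consequence_class`, nomenclature,
#'   prediction columns, and `samples`.
#' @export
read_annotated_variants <- function(path, gene_set = kp_gene_set(),
                                    vocabulary = consequence_vocabulary(),
                                    collapse = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path), class = "kpburden_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE)
  mandatory <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    abort(paste0("annotation table lacks mandatory columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "kpburden_format_error")
  }
  for (col in setdiff(annotation_columns(), names(df))) df[[col]] <- "."
  pos <- suppressWarnings(as.numeric(df$pos))
  if (any(is.na(pos) | pos < 1 | pos != round(pos))) {
    abort("malformed coordinates: pos must be a 1-based integer",
          class = "kpburden_format_error")
  }
  if (any(df$ref == df$alt)) {
    abort("malformed variant: ref equals alt", class = "kpburden_format_error")
  }

  out <- tibble(
    chrom = normalise_chrom(df$chrom),
    pos = as.integer(pos),
    ref = df$ref,
    alt = df$alt,
    gene_input = df$gene,
    transcript = dot_to_na(df$transcript),
    consequence = df$consequence,
    cdna_change = dot_to_na(df$cdna_change),
    protein_change = dot_to_na(df$protein_change),
    dbsnp_id = dot_to_na(df$dbsnp_id),
    hsf = dot_to_na(df$hsf),
    samples = dot_to_na(df$samples)
  )
  for (col in annotation_tool_columns()) out[[col]] <- dot_to_na(df[[col]])
  for (col in annotation_numeric_columns()) out[[col]] <- numeric_or_na(df[[col]])

  out$gene <- resolve_gene_symbols(gene_set, out$gene_input)
  out$off_target <- is.na(out$gene)
  out$gene <- ifelse(out$off_target, out$gene_input, out$gene)
  out$consequence_class <- classify_consequence(out$consequence, vocabulary)
  out$variant_id <- variant_id(out$chrom, out$pos, out$ref, out$alt)

  if (collapse) out <- collapse_transcripts(out, gene_set)
  out %>%
    select(variant_id, chrom, pos, ref, alt, gene, off_target, transcript,
           consequence, consequence_class, cdna_change, protein_change,
           dbsnp_id, all_of(annotation_tool_columns()),
           all_of(annotation_numeric_columns()), hsf, samples)
}

# one row per variant key: canonical-transcript row preferred, else most
# severe consequence (stopgain > frameshift > stoploss > splicing >
# missense > inframe > synonymous > UTR > intronic)
collapse_transcripts <- function(variants, gene_set) {
  canonical <- setNames(gene_set$transcript, gene_set$symbol)
  variants %>%
    mutate(
      .canonical = !is.na(transcript) &
        transcript == unname(canonical[gene]) & !is.na(canonical[gene]),
      .severity = consequence_severity(consequence_class)
    ) %>%
    arrange(variant_id, dplyr::desc(.canonical), .severity) %>%
    distinct(variant_id, .keep_all = TRUE) %>%
    select(-".canonical", -".severity")
}

#' Write an annotated variant table
#'
#' Inverse of [read_annotated_variants()]: writes the dialect TSV with "."
#' for missing cells, such that re-reading yields the same records.
#'
#' @param variants tibble as returned by [read_annotated_variants()] (the
#'   resolved `gene` column is written back to `gene`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotated_variants <- function(variants, path) {
  df <- tibble(
    chrom = variants$chrom,
    pos = as.character(variants$pos),
    ref = variants$ref,
    alt = variants$alt,
    gene = variants$gene,
    transcript = na_to_dot(variants$transcript),
    consequence = variants$consequence,
    cdna_change = na_to_dot(variants$cdna_change),
    protein_change = na_to_dot(variants$protein_change),
    dbsnp_id = na_to_dot(variants$dbsnp_id)
  )
  for (col in annotation_tool_columns()) df[[col]] <- na_to_dot(variants[[col]])
  for (col in annotation_numeric_columns()) {
    df[[col]] <- na_to_dot(format(variants[[col]], digits = 15, trim = TRUE,
                                  scientific = FALSE))
    df[[col]][is.na(variants[[col]])] <- "."
  }
  df$hsf <- na_to_dot(variants$hsf)
  df$samples <- na_to_dot(variants$samples)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Expand the carrier column into long observations
#'
#' Turns the `samples` column ("S0001:het,S0002:hom") into one row per
#' (variant, individual) pair.
#'
#' @param variants annotated variant tibble.
#' @return tibble with `variant_id`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `sample_id`, `zygosity`.
#' @export
variant_carriers <- function(variants) {
  variants %>%
    select(variant_id, chrom, pos, ref, alt, gene, samples) %>%
    filter(!is.na(samples)) %>%
    mutate(samples = stringr::str_split(samples, ",")) %>%
    tidyr::unnest(samples) %>%
    tidyr::separate(samples, into = c("sample_id", "zygosity"), sep = ":",
                    fill = "right") %>%
    mutate(zygosity = ifelse(is.na(zygosity), "het", zygosity))
}
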