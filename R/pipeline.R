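#' Pipeline configuration
#'
#' Bundles the input paths and analysis options for [run_pipeline()].
#' The functions themselves are the scripting interface; this object is
#' what a driver script or config file populates.
#'
#' @param annotation path to the annotation TSV.
#' @param controls path(s) to control frequency TSVs.
#' @param vcf optional case VCF (enables the sequencing-QC gate on novel
#'   variants).
#' @param dbsnp optional dbSNP lookup TSV (`chrom`, `pos`, `ref`, `alt`,
#'   `rs_id`).
#' @param gene_set path to a gene-set YAML/JSON, or a [kp_gene_set()]
#'   tibble; default is the packaged 18-gene panel.
#' @param sex optional sample-sex sidecar (TSV with `sample_id`, `sex`).
#' @param policy a [maf_policy()].
#' @param thresholds a [qc_thresholds()].
#' @param test a [burden_config()].
#' @param case_n case cohort size.
#' @param out_dir optional directory: when set, reports are written there
#'   as TSV/JSON alongside a run manifest.
#' @return list of class `kp_pipeline_config`.
#' @export
pipeline_config <- function(annotation, controls, vcf = NULL, dbsnp = NULL,
                            gene_set = NULL, sex = NULL,
                            policy = maf_policy(),
                            thresholds = qc_thresholds(),
                            test = burden_config(), case_n = 614,
                            out_dir = NULL) {
  structure(
    list(annotation = annotation, controls = controls, vcf = vcf,
         dbsnp = dbsnp, gene_set = gene_set, sex = sex, policy = policy,
         thresholds = thresholds, test = test, case_n = case_n,
         out_dir = out_dir),
    class = "kp_pipeline_config")
}

stage_msg <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

stage_abort <- function(stage, e) {
  abort(paste0("[", stage, "] ", conditionMessage(e)),
        class = "kpburden_stage_error")
}

#' Run the full burden pipeline
#'
#' Executes the stages in order — ingest, qualify, novelty/QC, score,
#' burden — and returns the two report tables plus a run manifest with
#' input checksums, parameter values and per-stage record counts.
#' Deterministic for fixed inputs: rerunning yields identical reports.
#' Any stage error aborts with a stage-tagged message.
#'
#' @param config a [pipeline_config()].
#' @return list of class `kp_pipeline`: `burden` (a `kp_burden`),
#'   `novel_report`, `inventory`, `qualified`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "kp_pipeline_config"))

  gs <- tryCatch({
    if (is.null(config$gene_set)) kp_gene_set()
    else if (is.character(config$gene_set)) load_gene_set(config$gene_set)
    else config$gene_set
  }, error = function(e) stage_abort("config", e))

  ing <- tryCatch({
    stage_msg("ingest", "reading ", config$annotation)
    variants <- read_annotated_variants(config$annotation, gs)
    controls <- purrr::map_dfr(config$controls, read_control_frequencies)
    obs <- NULL
    if (!is.null(config$vcf)) {
      sex <- if (!is.null(config$sex))
        readr::read_tsv(config$sex, col_types = "cc", progress = FALSE)
      obs <- read_case_vcf(config$vcf, sex = sex)
    }
    dbsnp <- if (!is.null(config$dbsnp))
      readr::read_tsv(config$dbsnp,
                      col_types = readr::cols(pos = "i", .default = "c"),
                      progress = FALSE)
    stage_msg("ingest", nrow(variants), " variants, ",
              nrow(controls), " control records")
    list(variants = variants, controls = controls, obs = obs, dbsnp = dbsnp)
  }, error = function(e) stage_abort("ingest", e))

  qualified <- tryCatch({
    q <- qualify_variants(ing$variants, ing$controls, config$policy)
    stage_msg("qualify", sum(q$qualifies), " qualifying of ", nrow(q))
    q
  }, error = function(e) stage_abort("qualify", e))

  novel <- tryCatch({
    r <- novel_variant_report(qualified, ing$obs, ing$controls, ing$dbsnp,
                              thresholds = config$thresholds)
    stage_msg("novelty", nrow(r), " novel variants pass QC (",
              nrow(attr(r, "excluded")), " excluded)")
    r
  }, error = function(e) stage_abort("novelty", e))

  burden <- tryCatch({
    b <- burden_report(qualified, ing$controls, gs, case_n = config$case_n,
                       config = config$test)
    stage_msg("burden", sum(b$results$significant, na.rm = TRUE),
              " significant gene x dataset pairs")
    b
  }, error = function(e) stage_abort("burden", e))

  inventory <- variant_inventory(ing$variants)

  manifest <- list(
    inputs = tibble(
      path = unlist(config[c("annotation", "controls", "vcf", "dbsnp", "sex")],
                    use.names = FALSE),
      md5 = unname(tools::md5sum(unlist(
        config[c("annotation", "controls", "vcf", "dbsnp", "sex")],
        use.names = FALSE)))),
    parameters = list(
      case_n = config$case_n,
      maf_default = config$policy$default,
      maf_overrides = as.list(config$policy$overrides),
      qc = unclass(config$thresholds),
      test = unclass(config$test),
      n_genes = nrow(gs)),
    counts = list(
      variants = nrow(ing$variants),
      control_records = nrow(ing$controls),
      observations = if (is.null(ing$obs)) 0L else nrow(ing$obs),
      qualifying = sum(qualified$qualifies),
      novel_reported = nrow(novel))
  )

  out <- structure(
    list(burden = burden, novel_report = novel, inventory = inventory,
         qualified = qualified, manifest = manifest),
    class = "kp_pipeline")
  if (!is.null(config$out_dir)) write_reports(out, config$out_dir)
  out
}

write_reports <- function(pipeline, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(pipeline$burden$results, file.path(out_dir, "burden.tsv"),
                   progress = FALSE)
  jsonlite::write_json(pipeline$burden$results,
                       file.path(out_dir, "burden.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  readr::write_tsv(pipeline$novel_report, file.path(out_dir, "novel_variants.tsv"),
                   progress = FALSE)
  readr::write_tsv(pipeline$inventory, file.path(out_dir, "inventory.tsv"),
                   progress = FALSE)
  jsonlite::write_json(pipeline$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' Variant inventory by consequence class
#'
#' Counts distinct non-intergenic variant sites per consequence class
#' across the panel — the study-style inventory ("50 synonymous, 76
#' nonsynonymous, ..."). Every ingested on-target site lands in exactly
#' one class.
#'
#' @param variants annotated variant tibble.
#' @return tibble (`consequence_class`, `n`) covering every class (zeros
#'   included), intergenic sites excluded from the total.
#' @export
variant_inventory <- function(variants) {
  on_target <- variants %>%
    filter(!off_target, consequence_class != "intergenic") %>%
    distinct(variant_id, consequence_class)
  tibble(consequence_class = setdiff(consequence_classes(), "intergenic")) %>%
    left_join(count(on_target, consequence_class), by = "consequence_class") %>%
    mutate(n = dplyr::coalesce(n, 0L))
}
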