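#' Read case genotype observations from a VCF
#'
#' Parses a VCF 4.2 file (via `VariantAnnotation`) and returns one row per
#' non-reference genotype call: the variant key plus the per-sample fields
#' the novelty QC needs (depth `DP`, alternate reads from `AD`, genotype
#' quality `GQ`) and a derived zygosity.
#'
#' Zygosity is `het` for 0/1-style calls, `hom` for 1/1, and `hemi` for
#' haploid calls; when `sex` metadata is supplied, X-chromosome calls in
#' males are treated as hemizygous. Without sex metadata X calls are
#' treated as diploid. Records lacking any of DP/AD/GQ are flagged
#' `qc_evaluable = FALSE` rather than dropped.
#'
#' @param path VCF file with FORMAT fields GT (and ideally AD, DP, GQ).
#' @param sex optional named character vector or two-column data frame
#'   (`sample_id`, `sex`) with values `"male"`/`"female"`.
#' @return tibble with columns `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `zygosity`, `depth`, `alt_reads`, `gq`, `qc_evaluable`.
#' @export
read_case_vcf <- function(path, sex = NULL) {
  if (!file.exists(path)) {
    abort(paste0("VCF not found: ", path), class = "kpburden_io_error")
  }
  if (is.data.frame(sex)) sex <- setNames(as.character(sex$sex), sex$sample_id)

  vcf <- VariantAnnotation::readVcf(path, genome = "hg19")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- normalise_chrom(as.character(GenomeInfoDb::seqnames(rr)))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))

  g <- VariantAnnotation::geno(vcf)
  gt <- g$GT
  samples <- colnames(gt)
  has <- function(field) field %in% names(g)

  rows <- purrr::map_dfr(seq_along(samples), function(j) {
    s <- samples[j]
    gts <- gt[, j]
    carrier <- !gts %in% c("0/0", "0|0", "0", ".", "./.", ".|.")
    idx <- which(carrier)
    if (!length(idx)) return(tibble())
    depth <- if (has("DP")) suppressWarnings(as.integer(g$DP[idx, j])) else NA_integer_
    gq <- if (has("GQ")) suppressWarnings(as.integer(g$GQ[idx, j])) else NA_integer_
    altr <- if (has("AD")) {
      AD <- g$AD
      if (is.list(AD)) {
        # list matrix (ragged AD)
        vapply(AD[idx, j], function(ad) {
          if (length(ad) >= 2 && !is.na(ad[2])) as.integer(ad[2]) else NA_integer_
        }, integer(1))
      } else {
        # dense array: variants x samples x alleles
        suppressWarnings(as.integer(AD[idx, j, 2]))
      }
    } else {
      rep(NA_integer_, length(idx))
    }
    tibble(
      chrom = chrom[idx], pos = pos[idx], ref = ref[idx], alt = alt[idx],
      sample_id = s, gt = gts[idx],
      depth = depth, alt_reads = altr, gq = gq
    )
  })
  if (!nrow(rows)) {
    return(tibble(variant_id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), sample_id = character(),
                  zygosity = character(), depth = integer(), alt_reads = integer(),
                  gq = integer(), qc_evaluable = logical()))
  }

  alleles <- stringr::str_split(rows$gt, "[/|]")
  n_alleles <- lengths(alleles)
  n_alt <- purrr::map_int(alleles, ~ sum(.x != "0" & .x != "."))
  zyg <- case_when(
    n_alleles == 1L ~ "hemi",
    n_alt >= 2L ~ "hom",
    TRUE ~ "het"
  )
  if (!is.null(sex)) {
    male <- !is.na(sex[rows$sample_id]) & sex[rows$sample_id] == "male"
    zyg[male & rows$chrom == "chrX"] <- "hemi"
  }
  rows %>%
    mutate(
      variant_id = variant_id(chrom, pos, ref, alt),
      zygosity = zyg,
      qc_evaluable = !is.na(depth) & !is.na(alt_reads) & !is.na(gq)
    ) %>%
    select(variant_id, chrom, pos, ref, alt, sample_id, zygosity, depth,
           alt_reads, gq, qc_evaluable)
}

#' Write case observations as a VCF fixture
#'
#' Emits a minimal VCF 4.2 with GT:AD:DP:GQ genotypes for every sample in
#' `sample_ids` (non-carriers get `0/0`), readable by [read_case_vcf()].
#' Used by the synthetic-cohort generator; not a general-purpose VCF writer.
#'
#' @param observations tibble with `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `zygosity`, `depth`, `alt_reads`, `gq`.
#' @param sample_ids full cohort sample ids (VCF columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_case_vcf <- function(observations, sample_ids, path) {
  obs <- observations %>%
    mutate(variant_id = variant_id(chrom, pos, ref, alt))
  sites <- obs %>%
    distinct(variant_id, chrom, pos, ref, alt) %>%
    arrange(chrom, pos, ref, alt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  gt_for <- function(zyg) switch(zyg, het = "0/1", hom = "1/1", hemi = "1", "0/1")
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    site <- sites[i, ]
    cells <- rep("0/0:.,.:.:.", length(sample_ids))
    names(cells) <- sample_ids
    here <- obs[obs$variant_id == site$variant_id, ]
    for (k in seq_len(nrow(here))) {
      o <- here[k, ]
      ad <- if (is.na(o$depth) || is.na(o$alt_reads)) ".,." else
        paste(o$depth - o$alt_reads, o$alt_reads, sep = ",")
      cells[o$sample_id] <- paste(
        gt_for(o$zygosity), ad,
        ifelse(is.na(o$depth), ".", o$depth),
        ifelse(is.na(o$gq), ".", o$gq), sep = ":")
    }
    paste(c(site$chrom, site$pos, ".", site$ref, site$alt, ".", "PASS", ".",
            "GT:AD:DP:GQ", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}
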