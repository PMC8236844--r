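# Shared fixtures and independent oracles, built in code at test time.

# --- tiny annotated-variant builder ---------------------------------------

# a one-row annotated variant with sensible defaults; prediction cells all
# missing unless overridden
make_variant <- function(chrom = "chr16", pos = 58756092L, ref = "G", alt = "A",
                         gene = "GOT2", transcript = "NM_002080",
                         consequence = "nonsynonymous SNV",
                         samples = "SALS0001:het", dbsnp_id = NA_character_,
                         ...) {
  v <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    gene = gene, off_target = FALSE, transcript = transcript,
    consequence = consequence,
    consequence_class = classify_consequence(consequence),
    cdna_change = NA_character_, protein_change = NA_character_,
    dbsnp_id = dbsnp_id,
    sift = NA_character_, polyphen2_hdiv = NA_character_,
    polyphen2_hvar = NA_character_, lrt = NA_character_,
    mutationtaster = NA_character_, mutationassessor = NA_character_,
    fathmm = NA_character_, provean = NA_character_,
    metasvm = NA_character_, metalr = NA_character_, mcap = NA_character_,
    cadd_phred = NA_real_, revel = NA_real_, bayesdel = NA_real_,
    hsf = NA_character_, samples = samples
  )
  dots <- list(...)
  for (nm in names(dots)) v[[nm]] <- dots[[nm]]
  v$variant_id <- variant_id(v$chrom, v$pos, v$ref, v$alt)
  dplyr::relocate(v, variant_id)
}

# a control record for one variant in one dataset
make_control <- function(v, dataset_id, allele_count = NA, carrier_count = NA,
                         sample_size) {
  tibble::tibble(
    dataset_id = dataset_id, chrom = v$chrom, pos = v$pos, ref = v$ref,
    alt = v$alt, carrier_count = as.numeric(carrier_count),
    allele_count = as.numeric(allele_count), sample_size = sample_size
  ) |> kpburden:::validate_control_table()
}

# --- independent exact-test oracle ----------------------------------------

# brute-force enumeration of the hypergeometric support with plain choose()
# arithmetic (no dhyper/phyper), summing point masses per method definition
oracle_fisher <- function(a, b, c, d, method, eps = 1e-7) {
  N <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  supp <- max(0, r1 - (N - c1)):min(r1, c1)
  pm <- choose(c1, supp) * choose(N - c1, r1 - supp) / choose(N, r1)
  obs <- match(a, supp)
  lower <- cumsum(pm)
  upper <- rev(cumsum(rev(pm)))
  p <- switch(method,
    greater = upper[obs],
    central = min(1, 2 * min(lower[obs], upper[obs])),
    minlike = sum(pm[pm <= pm[obs] * (1 + eps)]),
    blaker = {
      acc <- pmin(lower, upper)
      sum(pm[acc <= acc[obs] * (1 + eps)])
    })
  min(1, p)
}

# --- shared synthetic cohort ----------------------------------------------

# one moderate-scale simulation reused across test files (memoised)
.shared <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.shared$sim)) {
    .shared$sim <- simulate_cohort(sim_params(seed = 42))
  }
  .shared$sim
}

shared_fixture_dir <- function() {
  if (is.null(.shared$dir)) {
    dir <- file.path(tempdir(), "kpburden-shared-fixtures")
    .shared$paths <- write_fixtures(shared_sim(), dir)
    .shared$dir <- dir
  }
  .shared$paths
}

# the printed burden table of the motivating study: per-gene qualifying
# counts and printed percentages for cases (n = 614) and the three control
# datasets (nNFE 51,592; AOGC 967; MGRB 1,144). NA marks the unpopulated
# (insufficient-data) cells.
printed_burden_table <- function() {
  tibble::tribble(
    ~gene,    ~sals, ~sals_pct, ~nnfe, ~nnfe_pct, ~aogc, ~aogc_pct, ~mgrb, ~mgrb_pct,
    "AFMID",      8,    "1.30",   155,    "0.30",     9,    "0.93",    11,    "0.96",
    "HAAO",       7,    "1.14",    97,    "0.19",     3,    "0.31",    18,    "1.57",
    "KYAT1",     11,    "1.79",   173,    "0.34",     8,    "0.83",    15,    "1.31",
    "TPH1",       8,    "1.30",   121,    "0.23",     8,    "0.83",    12,    "1.05",
    "WARS",       8,    "1.30",   146,    "0.28",     6,    "0.62",    19,    "1.66",
    "AADAT",      1,    "0.16",    80,    "0.16",     2,    "0.21",     3,    "0.26",
    "ACMSD",      2,    "0.33",   110,    "0.21",     1,    "0.10",     4,    "0.35",
    "DDC",        4,    "0.65",   171,    "0.33",     5,    "0.52",     6,    "0.52",
    "GOT2",       1,    "0.16",   111,    "0.22",     4,    "0.41",     4,    "0.35",
    "IDO1",       6,    "0.98",   152,    "0.29",     4,    "0.41",     4,    "0.35",
    "IDO2",       3,    "0.49",   129,    "0.25",     7,    "0.72",     8,    "0.70",
    "KMO",        7,    "1.14",   126,    "0.24",     6,    "0.62",    10,    "0.87",
    "KYAT3",      5,    "0.81",   129,    "0.25",     2,    "0.21",    11,    "0.96",
    "KYNU",       2,    "0.33",   170,    "0.33",     7,    "0.72",     7,    "0.61",
    "MAOA",       3,    "0.49",    60,    "0.12",     3,    "0.31",     1,    "0.09",
    "QPRT",       2,    "0.33",    90,    "0.17",    NA,        NA,    17,    "1.49",
    "TDO2",       4,    "0.65",   138,    "0.27",     4,    "0.41",    12,    "1.05",
    "TPH2",       2,    "0.33",   134,    "0.26",     6,    "0.62",     1,    "0.09"
  )
}

cohort_sizes <- c(sals = 614, nnfe = 51592, aogc = 967, mgrb = 1144)
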