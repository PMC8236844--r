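#' Load a candidate gene set from a YAML or JSON config
#'
#' A gene set defines the candidate panel: one row per gene with its HGNC
#' symbol, any aliases (e.g. `CCBL1` for `KYAT1`), the canonical RefSeq
#' transcript the analysis is pinned to, the chromosome, and the pathway
#' group (`protein_synthesis`, `serotonin` or `kynurenine`).
#'
#' @param path path to a YAML (or JSON) file with a top-level `genes` list;
#'   each entry needs `symbol`, `transcript`, `chromosome` and
#'   `pathway_group`, and may carry `aliases`.
#' @return a tibble of class `kp_gene_set` with columns `symbol`, `aliases`
#'   (list column), `transcript`, `chromosome`, `pathway_group`.
#' @examples
#' gs <- kp_gene_set()
#' nrow(gs)  # 18
#' gene_lookup(gs, "CCBL1")$symbol  # "KYAT1"
#' @export
load_gene_set <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("gene set config not found: ", path), class = "kpburden_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  genes <- raw[["genes"]]
  if (is.null(genes) || length(genes) == 0) {
    abort("gene set config contains no genes", class = "kpburden_config_error")
  }
  gs <- purrr::map_dfr(genes, function(g) {
    for (f in c("symbol", "transcript", "chromosome", "pathway_group")) {
      if (is.null(g[[f]]) || !nzchar(g[[f]])) {
        abort(paste0("gene entry missing field '", f, "'"),
              class = "kpburden_config_error")
      }
    }
    tibble(
      symbol = as.character(g$symbol),
      aliases = list(as.character(unlist(g$aliases %||% character()))),
      transcript = as.character(g$transcript),
      chromosome = normalise_chrom(g$chromosome),
      pathway_group = as.character(g$pathway_group)
    )
  })
  validate_gene_set(gs)
}

#' The default 18-gene tryptophan-metabolism panel
#'
#' One gene covering tryptophan incorporation into proteins (*WARS*), four
#' serotonin-synthesis genes (*DDC*, *MAOA*, *TPH1*, *TPH2*) and thirteen
#' kynurenine-pathway genes, each pinned to its canonical RefSeq transcript.
#'
#' @return a `kp_gene_set` tibble with 18 rows.
#' @export
kp_gene_set <- function() {
  load_gene_set(system.file("extdata", "kp_gene_set.yaml", package = "kpburden"))
}

validate_gene_set <- function(gs) {
  groups <- c("protein_synthesis", "serotonin", "kynurenine")
  if (anyDuplicated(gs$symbol)) {
    abort(paste0("duplicate gene symbol: ",
                 paste(unique(gs$symbol[duplicated(gs$symbol)]), collapse = ", ")),
          class = "kpburden_config_error")
  }
  bad <- setdiff(unique(gs$pathway_group), groups)
  if (length(bad)) {
    abort(paste0("unknown pathway_group: ", paste(bad, collapse = ", ")),
          class = "kpburden_config_error")
  }
  ali <- unlist(gs$aliases)
  if (anyDuplicated(ali) || any(ali %in% gs$symbol)) {
    abort("aliases must map to exactly one symbol", class = "kpburden_config_error")
  }
  structure(gs, class = c("kp_gene_set", class(tibble())))
}

#' Look up one gene by symbol or alias
#'
#' @param gene_set a `kp_gene_set` tibble.
#' @param name a symbol or alias, e.g. `"CCBL1"`.
#' @return the matching one-row tibble, or an error if the name is unknown.
#' @export
gene_lookup <- function(gene_set, name) {
  sym <- resolve_gene_symbols(gene_set, name)
  if (is.na(sym)) {
    abort(paste0("gene '", name, "' is not in the gene set"),
          class = "kpburden_lookup_error")
  }
  gene_set[gene_set$symbol == sym, , drop = FALSE]
}

#' Resolve gene names (symbols or aliases) to canonical symbols
#'
#' Vectorised; names that resolve to nothing return `NA`, which downstream
#' readers translate into the off-target flag rather than dropping rows.
#'
#' @inheritParams gene_lookup
#' @param names character vector of symbols/aliases.
#' @return character vector of canonical symbols (`NA` where unresolved).
#' @export
resolve_gene_symbols <- function(gene_set, names) {
  map <- c(
    setNames(gene_set$symbol, gene_set$symbol),
    setNames(rep(gene_set$symbol, lengths(gene_set$aliases)), unlist(gene_set$aliases))
  )
  unname(map[as.character(names)])
}
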