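#' Consequence classes recognised by the qualifying filter
#'
#' @return character vector of the internal consequence vocabulary, ordered
#'   from most to least severe (used when collapsing multi-transcript
#'   annotations to the canonical transcript).
#' @export
consequence_classes <- function() {
  c("stopgain", "frameshift_indel", "stoploss", "splicing", "missense",
    "inframe_indel", "synonymous", "utr5", "utr3", "intronic", "other",
    "intergenic")
}

#' Load a consequence vocabulary (annotation dialect -> class)
#'
#' The shipped default covers the ANNOVAR refGene vocabulary
#' ("nonsynonymous SNV", "UTR3", "frameshift insertion", ...) plus common
#' Sequence Ontology terms; it is an editable YAML table so other dialects
#' can be mapped without code changes.
#'
#' @param path YAML file with a `vocabulary` mapping; default is the
#'   packaged table.
#' @return named character vector: raw string (lower-cased) -> class.
#' @export
consequence_vocabulary <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "consequence_vocabulary.yaml", package = "kpburden")
  raw <- yaml::read_yaml(path)$vocabulary
  vocab <- vapply(raw, as.character, character(1))
  bad <- setdiff(unique(vocab), consequence_classes())
  if (length(bad)) {
    abort(paste0("vocabulary maps to unknown class: ", paste(bad, collapse = ", ")),
          class = "kpburden_config_error")
  }
  setNames(unname(vocab), tolower(names(vocab)))
}

#' Classify raw consequence strings
#'
#' Total function: every input gets exactly one class, with unknown strings
#' mapping to `"other"`. Matching trims whitespace and ignores case.
#'
#' @param raw_consequence character vector of annotation-dialect strings.
#' @param vocabulary named vector from [consequence_vocabulary()].
#' @return character vector of consequence classes.
#' @examples
#' classify_consequence(c("nonsynonymous SNV", "UTR3", "banana"))
#' @export
classify_consequence <- function(raw_consequence,
                                 vocabulary = consequence_vocabulary()) {
  key <- tolower(trimws(as.character(raw_consequence)))
  out <- unname(vocabulary[key])
  out[is.na(out)] <- "other"
  out
}

#' Is a consequence class protein-altering?
#'
#' Protein-altering classes are the ones eligible to qualify for burden
#' analysis: missense, stop gain/loss, frameshift and in-frame indels, and
#' splicing. Synonymous, UTR, intronic and intergenic variants never
#' qualify regardless of frequency.
#'
#' @param class character vector of consequence classes.
#' @return logical vector.
#' @export
is_protein_altering <- function(class) {
  class %in% c("missense", "stopgain", "stoploss", "frameshift_indel",
               "inframe_indel", "splicing")
}

# severity rank for multi-transcript collapse: lower = more severe
consequence_severity <- function(class) {
  match(class, consequence_classes())
}
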