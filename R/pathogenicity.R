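#' The twelve dbNSFP prediction tools of the consensus score
#'
#' @return character vector of tool column names: SIFT, PolyPhen2 (HDIV
#'   and HVAR), LRT, MutationTaster, MutationAssessor, FATHMM, PROVEAN,
#'   MetaSVM, MetaLR, M-CAP and CADD (phred-scaled).
#' @export
prediction_tools <- function() {
  c(annotation_tool_columns(), "cadd_phred")
}

#' Load the per-tool deleterious-call mapping
#'
#' The mapping follows dbNSFP conventions (SIFT `D`; PolyPhen2 `D`/`P`;
#' MutationTaster `A`/`D`; MutationAssessor `H`/`M`; CADD phred >= 20, a
#' configurable cutoff since CADD has no categorical output; ...). It is
#' shipped as an editable YAML table; pass a path to use a custom mapping.
#'
#' @param path YAML file; default is the packaged table.
#' @return list of class `kp_tool_map` with elements `tools` and
#'   `splice_tools`, each a named list of `kind`/`deleterious`/`cutoff`.
#' @export
tool_prediction_map <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "tool_prediction_map.yaml", package = "kpburden")
  raw <- yaml::read_yaml(path)
  structure(list(tools = raw$tools, splice_tools = raw$splice_tools),
            class = "kp_tool_map")
}

#' Classify one tool's raw prediction
#'
#' Deterministic, total over raw values: "." or `NA` is `missing`;
#' categorical tools return `deleterious` for values in their deleterious
#' set and `benign` for any other observed value; numeric tools compare
#' against their cutoff (inclusive).
#'
#' @param tool a tool id present in the mapping (e.g. `"sift"`,
#'   `"cadd_phred"`).
#' @param raw character or numeric vector of raw annotation values.
#' @param map a [tool_prediction_map()].
#' @param splice use the splice-tool section of the mapping.
#' @return character vector in `c("deleterious", "benign", "missing")`.
#' @export
classify_tool_prediction <- function(tool, raw, map = tool_prediction_map(),
                                     splice = FALSE) {
  spec <- if (splice) map$splice_tools[[tool]] else map$tools[[tool]]
  if (is.null(spec)) {
    abort(paste0("unknown prediction tool: ", tool), class = "kpburden_config_error")
  }
  if (identical(spec$kind, "numeric")) {
    val <- numeric_or_na(raw)
    out <- ifelse(is.na(val), "missing",
                  ifelse(val >= spec$cutoff, "deleterious", "benign"))
  } else {
    val <- dot_to_na(raw)
    out <- ifelse(is.na(val), "missing",
                  ifelse(val %in% spec$deleterious, "deleterious", "benign"))
  }
  out
}

#' Consensus pathogenicity score from tool calls
#'
#' The score is the fraction of tools returning a deleterious call among
#' the tools that returned any call, rounded half-away-from-zero to two
#' decimals; a score of 1 means every tool with a result predicted a
#' deleterious effect. Undefined (error) when no tool returned a result.
#'
#' @param calls character vector of `deleterious`/`benign`/`missing` calls
#'   (tool order is irrelevant; missing entries do not enter the
#'   denominator).
#' @return list with `value` (rounded), `value_raw` (unrounded fraction),
#'   `n_deleterious`, `n_with_results`, and `display` like `"0.83 (12)"`.
#' @examples
#' consensus_score(c(rep("deleterious", 10), "benign", "benign"))$value  # 0.83
#' @export
consensus_score <- function(calls) {
  n_res <- sum(calls != "missing")
  if (n_res == 0) {
    abort("consensus score undefined: no tool returned a result",
          class = "kpburden_score_error")
  }
  n_del <- sum(calls == "deleterious")
  raw <- n_del / n_res
  val <- round_half_up(raw, 2)
  list(value = val, value_raw = raw, n_deleterious = n_del,
       n_with_results = n_res,
       display = paste0(format_score(val), " (", n_res, ")"))
}

# "1" not "1.00", "0.5" not "0.50": trailing zeros are trimmed the way
# published score tables are printed
format_score <- function(x) {
  sub("\\.?0+$", "", sprintf("%.2f", x))
}

#' REVEL pathogenicity call
#'
#' @param score numeric REVEL score(s) in \[0, 1\]; `NA` allowed.
#' @param cutoff inclusive pathogenic cutoff (default 0.5).
#' @return `"Pathogenic"`/`"Benign"` (`NA` for missing scores).
#' @export
call_revel <- function(score, cutoff = 0.5) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    abort("REVEL scores must lie in [0, 1]", class = "kpburden_score_error")
  }
  ifelse(is.na(score), NA_character_,
         ifelse(score >= cutoff, "Pathogenic", "Benign"))
}

#' BayesDel deleteriousness call
#'
#' @param score numeric BayesDel score(s); `NA` allowed.
#' @param cutoff inclusive damaging cutoff (default -0.057).
#' @return `"Damaging"`/`"Tolerated"` (`NA` for missing scores).
#' @export
call_bayesdel <- function(score, cutoff = -0.057) {
  ifelse(is.na(score), NA_character_,
         ifelse(score >= cutoff, "Damaging", "Tolerated"))
}

#' Consensus score for a splicing variant
#'
#' Splicing variants have no missense predictions, so their consensus runs
#' over the splice-capable tool set: NNSplice via MutationTaster, CADD,
#' BayesDel, and an optional imported Human Splicing Finder verdict
#' (`hsf` column, value `affected`); tools without results drop out of the
#' denominator.
#'
#' @param profile one-row tibble (or list) carrying `mutationtaster`,
#'   `cadd_phred`, `bayesdel` and optionally `hsf`.
#' @param map a [tool_prediction_map()].
#' @return a [consensus_score()] result list.
#' @export
score_splicing <- function(profile, map = tool_prediction_map()) {
  tools <- names(map$splice_tools)
  calls <- vapply(tools, function(tl) {
    if (is.null(profile[[tl]])) return("missing")
    classify_tool_prediction(tl, profile[[tl]], map, splice = TRUE)
  }, character(1))
  consensus_score(calls)
}

#' Score variants with the consensus, REVEL and BayesDel calls
#'
#' Vectorised scoring for an annotated variant tibble: splicing variants
#' use the splice-tool consensus, everything else the 12-tool missense
#' consensus; variants with no tool results get `NA` scores rather than an
#' error.
#'
#' @param variants annotated variant tibble with prediction columns.
#' @param tool_map a [tool_prediction_map()].
#' @param use_rounded if `FALSE`, `score` carries the unrounded fraction
#'   (the rounded value is always in `score_display`).
#' @return `variants` with added `score`, `n_tools`, `score_display`,
#'   `revel_call`, `bayesdel_call`.
#' @export
score_variants <- function(variants, tool_map = tool_prediction_map(),
                           use_rounded = TRUE) {
  scored <- purrr::map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    res <- tryCatch({
      if (v$consequence_class == "splicing") {
        score_splicing(v, tool_map)
      } else {
        calls <- vapply(prediction_tools(), function(tl)
          classify_tool_prediction(tl, v[[tl]], tool_map), character(1))
        consensus_score(calls)
      }
    }, kpburden_score_error = function(e) NULL)
    if (is.null(res)) {
      list(value = NA_real_, value_raw = NA_real_, n_with_results = 0L,
           display = NA_character_)
    } else {
      res
    }
  })
  variants %>%
    mutate(
      score = vapply(scored, function(s)
        if (use_rounded) s$value else s$value_raw, numeric(1)),
      n_tools = vapply(scored, function(s) as.integer(s$n_with_results),
                       integer(1)),
      score_display = vapply(scored, function(s) s$display, character(1)),
      revel_call = call_revel(revel),
      bayesdel_call = call_bayesdel(bayesdel)
    )
}
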