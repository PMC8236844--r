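#' Exact conditional test for a 2x2 table
#'
#' Exact test of association in a 2x2 table `(a, b; c, d)` (cases with /
#' without the variant, controls with / without), conditioning on both
#' margins so the first cell follows a hypergeometric distribution. Three
#' two-sided definitions are supported, plus the one-sided enrichment
#' test:
#'
#' * `central`: twice the smaller tail probability, capped at 1 — the
#'   "central" Fisher test, the default of the exact-2x2 family of tests
#'   and of this package.
#' * `minlike`: the sum of the probabilities of all outcomes no more
#'   likely than the observed one (the classic `fisher.test` definition).
#' * `blaker`: Blaker's acceptability method — the observed minimal tail
#'   plus the largest opposite tail not exceeding it.
#' * `greater`: one-sided probability of `a` or more case variants.
#'
#' Probabilities are computed with log-space hypergeometric mass
#' (`dhyper`/`phyper`), with a relative tolerance of 1e-7 when comparing
#' point masses, so the test is numerically stable for large control
#' denominators.
#'
#' @param a,b,c,d non-negative integer vectors (recycled): cases with the
#'   qualifying count, case remainder, control count, control remainder.
#' @param method two-sided method, or `"greater"`.
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' fisher_exact_2x2(1, 613, 80, 51512)            # 1 (central)
#' fisher_exact_2x2(2, 612, 170, 51422, "blaker") # 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             method = c("central", "minlike", "blaker", "greater")) {
  method <- match.arg(method)
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, len); b <- rep_len(b, len)
  c <- rep_len(c, len); d <- rep_len(d, len)
  if (!all(is_count(a) & is_count(b) & is_count(c) & is_count(d))) {
    abort("2x2 table entries must be non-negative integers",
          class = "kpburden_test_error")
  }
  m <- a + c   # column-1 margin: total carriers
  n <- b + d
  k <- a + b   # row-1 margin: case denominator
  if (method %in% c("central", "greater")) {
    # tail probabilities only: fully vectorised
    lower <- phyper(a, m, n, k)
    upper <- phyper(a - 1, m, n, k, lower.tail = FALSE)
    p <- if (method == "greater") upper else pmin(1, 2 * pmin(lower, upper))
    return(pmax(pmin(p, 1), .Machine$double.xmin))
  }
  vapply(seq_len(len), function(i)
    fisher_enum_p(a[i], m[i], n[i], k[i], method), numeric(1))
}

# enumeration over the hypergeometric support for minlike / blaker
fisher_enum_p <- function(a, m, n, k, method, eps = 1e-7) {
  supp <- max(0, k - n):min(k, m)
  pm <- dhyper(supp, m, n, k)
  obs <- which(supp == a)
  if (method == "minlike") {
    p <- sum(pm[pm <= pm[obs] * (1 + eps)])
  } else { # blaker: acceptability = smaller of the two tails at each outcome
    lower <- cumsum(pm)
    upper <- rev(cumsum(rev(pm)))
    accept <- pmin(lower, upper)
    p <- sum(pm[accept <= accept[obs] * (1 + eps)])
  }
  max(min(p, 1), .Machine$double.xmin)
}

#' Per-test Bonferroni threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests; the default candidate panel runs 18
#'   genes, giving 0.05 / 18 = 0.00278 (3 s.f.).
#' @return `alpha / n_tests`.
#' @examples
#' signif(bonferroni_threshold(0.05, 18), 3)  # 0.00278
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 18) {
  if (alpha <= 0 || alpha >= 1 || n_tests < 1) {
    abort("need alpha in (0,1) and n_tests >= 1", class = "kpburden_test_error")
  }
  alpha / n_tests
}
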