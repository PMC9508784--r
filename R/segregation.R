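# Genetic-model arithmetic: chi-square goodness of fit for two-class
# segregation ratios and the expected SNP-indices of the two-bulk F2
# recessive design.

#' Chi-square goodness of fit for a two-class segregation ratio
#'
#' Pearson's chi-square with df = 1 against an expected `r1:r2` ratio, e.g.
#' weeping:standard against 1:3. No continuity correction by default — the
#' plain statistic is the one conventionally reported for Mendelian ratio
#' tests (56:210 against 1:3 gives 2.2); set `correct = TRUE` for the Yates
#' correction.
#'
#' @param observed Length-2 counts `(n_class1, n_class2)`.
#' @param ratio Length-2 positive expected ratio `(r1, r2)` (default `c(1, 3)`).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A one-row tibble: `n1`, `n2`, `ratio`, `chi2`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_ratio(c(56, 210), c(1, 3))
chi_square_ratio <- function(observed, ratio = c(1, 3), correct = FALSE) {
  stopifnot(length(observed) == 2, length(ratio) == 2)
  if (any(observed < 0) || sum(observed) <= 0) stop("`observed` must be non-negative counts with a positive total")
  if (any(ratio <= 0)) stop("`ratio` terms must be positive (zero expected class)")
  expected <- sum(observed) * ratio / sum(ratio)
  dev <- abs(observed - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  tibble::tibble(
    n1 = observed[1], n2 = observed[2],
    ratio = paste0(ratio[1], ":", ratio[2]),
    chi2 = chi2, df = 1L,
    p_value = pchisq(chi2, df = 1, lower.tail = FALSE)
  )
}

#' Expected bulk SNP-indices under a cross design
#'
#' For the two-bulk F2 recessive design: the mutant (weeping) bulk contains
#' only aa individuals, so its expected index is aa/Aa = 1; the other bulk
#' is the AA:Aa = 1:2 mixture, so its expected index is AA/(AA + 2Aa) = 1/3;
#' the expected Delta(SNP-index) is 1 - 1/3 = 2/3.
#'
#' @param design Currently only `"f2_recessive"`.
#' @return A one-row tibble: `design`, `index_mutant_bulk`,
#'   `index_other_bulk`, `delta`.
#' @export
#' @examples
#' expected_indices()
expected_indices <- function(design = "f2_recessive") {
  if (!identical(design, "f2_recessive")) {
    stop("unknown design '", design, "'; supported: f2_recessive")
  }
  tibble::tibble(
    design = design,
    index_mutant_bulk = 1,
    index_other_bulk = 1 / 3,
    delta = 1 - 1 / 3
  )
}
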