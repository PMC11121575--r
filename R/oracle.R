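#' Brute-force Fisher exact test oracle (small tables)
#'
#' Independent reference implementation used to validate
#' [fisher_exact_pvalue()]: enumerates every 2x2 table compatible with the
#' observed margins and sums point probabilities in 80-bit extended
#' precision, with binomial coefficients built by multiplicative
#' recurrences rather than log-gamma. Restricted to total counts
#' `N = a+b+c+d <= 200`.
#'
#' @inheritParams fisher_exact_pvalue
#' @return Scalar p-value.
#' @examples
#' fisher_bruteforce_oracle(2, 0, 0, 2, alternative = "greater")  # 1/6
#' @export
fisher_bruteforce_oracle <- function(a, b, c, d,
                                     alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == 1L, length(b) == 1L, length(c) == 1L, length(d) == 1L)
  oracle_fisher_cpp(as.integer(a), as.integer(b), as.integer(c),
                    as.integer(d), alternative)
}
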