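#' Audic-Claverie conditional count probability
#'
#' Probability of observing `y` reads for a transcript in a library of
#' total size `n2`, conditional on having observed `x` reads for the same
#' transcript in a library of total size `n1`, under the null hypothesis
#' that the transcript is equally abundant in both libraries:
#'
#' \deqn{p(y|x) = (n2/n1)^y \frac{(x+y)!}{x!\,y!\,(1+n2/n1)^{x+y+1}}}
#'
#' This is a negative binomial pmf with size \eqn{x+1} and success
#' probability \eqn{n1/(n1+n2)}; the implementation evaluates it in log
#' space through `lgamma`, so it remains finite far below the double
#' underflow threshold of a term-by-term product.
#'
#' @param y Non-negative integer count(s) in the second library.
#' @param x Non-negative integer count(s) in the conditioning library.
#' @param n1 Positive total read count of the conditioning library.
#' @param n2 Positive total read count of the second library.
#' @param log If `TRUE` return the natural-log probability.
#' @return Probability (or log-probability) vector; `sum(p(y|x))` over all
#'   `y >= 0` is 1.
#' @examples
#' ac_pmf(0, 0, 1000, 1000)  # 0.5
#' ac_pmf(1, 1, 1000, 1000)  # 0.25
#' @export
ac_pmf <- function(y, x, n1, n2, log = FALSE) {
  stopifnot(length(n1) == 1, length(n2) == 1)
  if (!is.finite(n1) || !is.finite(n2) || n1 <= 0 || n2 <= 0)
    stop("library totals n1 and n2 must be positive")
  if (any(y < 0) || any(x < 0) || any(y != floor(y)) || any(x != floor(x)))
    stop("counts x and y must be non-negative integers")
  r <- n2 / n1
  lp <- y * base::log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
  if (log) lp else exp(lp)
}

#' Log lower-tail sum of the Audic-Claverie distribution
#'
#' Computes `log( sum_{y'=0..y} p(y'|x) )` by accumulating the log-space
#' pmf terms with the log-sum-exp trick. This is the one-tailed p-value of
#' the conditional count test when `x` is the larger of the two observed
#' counts.
#'
#' @inheritParams ac_pmf
#' @return Natural-log tail probability, same length as `y`/`x` recycling.
#' @keywords internal
ac_logp_tail <- function(y, x, n1, n2) {
  n <- max(length(y), length(x))
  y <- rep_len(y, n); x <- rep_len(x, n)
  vapply(seq_len(n), function(i) {
    lt <- ac_pmf(0:y[i], x[i], n1, n2, log = TRUE)
    m <- max(lt)
    m + base::log(sum(exp(lt - m)))
  }, numeric(1))
}

#' Differential-expression test for one or more transcripts
#'
#' One-tailed Audic-Claverie test between two libraries. For each
#' transcript the side with the larger raw count is taken as the
#' conditioning side (count `x`, library total `n1`); the p-value is the
#' lower-tail sum over the other side's count. Ties in raw counts
#' condition on the library with the larger total (and on "D" when the
#' totals are also equal), keeping the test exactly symmetric under a
#' swap of the two libraries. Direction of change is decided
#' on relative frequencies (`hits/total`), which the test itself does not
#' use; in the rare case where raw counts and relative frequencies
#' disagree on which library is ahead, both facts are kept and a warning
#' is issued.
#'
#' @param hits_d,hits_l Non-negative integer count vectors (same length),
#'   reads per contig in the first ("D", e.g. competent) and second ("L",
#'   e.g. light-induced) libraries.
#' @param n_d,n_l Positive totals of the two libraries. These must be the
#'   full library totals even when testing a subset of contigs.
#' @param contig_id Optional identifiers; defaults to `contig1..n`.
#' @param alpha Significance threshold; a contig is flagged significant
#'   when `p_value < alpha` (strict).
#' @return A data frame of class `ac_de` with columns `contig_id`,
#'   `hits_d`, `hits_l`, `rel_d`, `rel_l`, `direction` ("down" = more
#'   abundant in D, "up" = more abundant in L, "tie"), `ratio` (majority
#'   over minority relative frequency, `Inf` when the minority count is
#'   0, 1 at a tie), `p_value`, `log10_p` and `significant`. `log10_p` is
#'   the primary record of very small p-values (e.g. below 1e-300, where
#'   `p_value` itself underflows).
#' @examples
#' ac_test(c(68, 1), c(2, 37), n_d = 125456, n_l = 99632)
#' @export
ac_test <- function(hits_d, hits_l, n_d, n_l,
                    contig_id = NULL, alpha = 0.05) {
  stopifnot(length(hits_d) == length(hits_l))
  if (n_d < 1 || n_l < 1) stop("library totals must be >= 1")
  if (any(hits_d < 0) || any(hits_l < 0))
    stop("negative hit counts are not allowed")
  if (any(hits_d > n_d) || any(hits_l > n_l))
    stop("a single contig's count exceeds its library total")
  n <- length(hits_d)
  if (is.null(contig_id)) contig_id <- paste0("contig", seq_len(n))

  rel_d <- hits_d / n_d
  rel_l <- hits_l / n_l
  direction <- ifelse(rel_d > rel_l, "down", ifelse(rel_l > rel_d, "up", "tie"))

  # cross-product form keeps mathematically equal ratios exactly equal in
  # floating point (e.g. counts (18,1) and (90,5) share one ratio)
  ratio <- rep(1, n)
  dn <- direction == "down"; up <- direction == "up"
  ratio[dn] <- (hits_d[dn] * n_l) / (hits_l[dn] * n_d)
  ratio[up] <- (hits_l[up] * n_d) / (hits_d[up] * n_l)

  # conditioning side = larger raw count; a raw-count tie conditions on
  # the larger-total side so that swapping the two libraries gives the
  # identical p-value (with equal totals the sides are interchangeable)
  cond_d <- hits_d > hits_l | (hits_d == hits_l & n_d >= n_l)
  x  <- ifelse(cond_d, hits_d, hits_l)
  y  <- ifelse(cond_d, hits_l, hits_d)
  log_p <- numeric(n)
  for (side in c(TRUE, FALSE)) {
    idx <- which(cond_d == side & !(hits_d == 0 & hits_l == 0))
    if (length(idx))
      log_p[idx] <- ac_logp_tail(y[idx], x[idx],
                                 if (side) n_d else n_l,
                                 if (side) n_l else n_d)
  }
  zero <- hits_d == 0 & hits_l == 0
  log_p[zero] <- 0
  direction[zero] <- "tie"

  disagree <- (hits_d > hits_l & direction == "up") |
    (hits_l > hits_d & direction == "down")
  if (any(disagree))
    warning(sum(disagree), " contig(s) where the raw-count majority and the ",
            "relative-frequency majority point to different libraries; ",
            "conditioning followed raw counts, direction followed ",
            "relative frequencies")

  out <- data.frame(
    contig_id = as.character(contig_id),
    hits_d = as.integer(hits_d), hits_l = as.integer(hits_l),
    rel_d = rel_d, rel_l = rel_l,
    direction = direction, ratio = ratio,
    p_value = exp(log_p), log10_p = log_p / base::log(10),
    stringsAsFactors = FALSE
  )
  out <- classify_de(out, alpha = alpha)
  class(out) <- c("ac_de", "data.frame")
  out
}

#' Flag significant differential expression
#'
#' @param de A data frame with a `p_value` column (as from [ac_test()]).
#' @param alpha Threshold in (0,1); significance is the strict inequality
#'   `p_value < alpha`.
#' @return `de` with its `significant` column (re)computed.
#' @export
classify_de <- function(de, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  de$significant <- de$p_value < alpha
  de
}

#' @export
print.ac_de <- function(x, ...) {
  cat(sprintf("Audic-Claverie DE results: %d contigs, %d significant (%d up, %d down)\n",
              nrow(x), sum(x$significant),
              sum(x$significant & x$direction == "up"),
              sum(x$significant & x$direction == "down")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
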