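#' Audic-Claverie probability mass function
#'
#' Probability of observing `y` reads for a feature in library 2 given `x`
#' reads in library 1, for libraries of `n1` and `n2` total reads, under
#' the Poisson model for digital expression data:
#' \deqn{P(y \mid x) = \left(\frac{N_2}{N_1}\right)^y
#'   \frac{(x+y)!}{x!\,y!}
#'   \left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)}}
#' Evaluated in log space; equals the negative-binomial pmf with
#' `size = x + 1` and success probability \eqn{N_1/(N_1+N_2)}, so
#' \eqn{\sum_y P(y|x) = 1}.
#'
#' @param x,y Non-negative integer counts (vectorised; recycled).
#' @param n1,n2 Positive library totals.
#' @return Numeric vector of probabilities.
#' @export
ac_pmf <- function(x, y, n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library sizes must be positive")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  logr <- log(n2) - log(n1)
  ## log1p(exp(logr)) computed stably for extreme ratios
  log1pr <- ifelse(logr > 30, logr, log1p(exp(logr)))
  exp(y * logr + lchoose(x + y, y) - (x + y + 1) * log1pr)
}

## inclusive upper conditional tail sum_{y' >= y} ac_pmf(x, y', n1, n2),
## by direct summation with a tail cut-off well below double precision
#' @noRd
ac_upper_tail <- function(x, y, n1, n2) {
  r <- n2 / n1
  mu <- (x + 1) * r
  ymax <- ceiling(mu + 40 * sqrt(mu * (1 + r) + 1) + 50)
  if (y > ymax) {
    ## deep in the upper tail: sum forward until terms vanish
    yy <- y
    tot <- 0
    repeat {
      block <- yy:(yy + 511)
      vals <- ac_pmf(x, block, n1, n2)
      tot <- tot + sum(vals)
      if (vals[length(vals)] < tot * 1e-18 + 1e-300) break
      yy <- yy + 512
    }
    return(min(tot, 1))
  }
  ## complement of the finite lower part (y' < y)
  lower <- if (y == 0) 0 else sum(ac_pmf(x, 0:(y - 1), n1, n2))
  max(min(1 - lower, 1), sum(ac_pmf(x, y, n1, n2)))
}

#' Audic-Claverie exact test
#'
#' Exact test comparing one feature's counts between two sequencing
#' libraries. One-sided p-values are inclusive cumulative tails of
#' [ac_pmf()]; `"greater"` is the tail over counts at least `y` in library
#' 2 given `x`, `"less"` the tail over counts at least `x` in library 1
#' given `y` (the exchanged orientation). The two-sided p-value is
#' `min(1, 2 * min(greater, less))`, which is exactly invariant under
#' exchanging the two libraries and coincides with the conditional
#' (binomial) exact test for two Poisson libraries.
#'
#' @param x,y Observed counts (vectorised; recycled to common length).
#' @param n1,n2 Library totals.
#' @param alternative `"two.sided"` (default), `"greater"` (feature higher
#'   in library 2), or `"less"`.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' ac_test(0, 20, 1e6, 1e6)           # strong enrichment in library 2
#' ac_test(5, 5, 1e6, 1e6)            # identical counts: p = 1
#' @export
ac_test <- function(x, y, n1, n2,
                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  vapply(seq_len(n), function(i) {
    up <- ac_upper_tail(x[i], y[i], n1[i], n2[i])
    lo <- ac_upper_tail(y[i], x[i], n2[i], n1[i])
    switch(alternative,
      greater   = up,
      less      = lo,
      two.sided = min(1, 2 * min(up, lo))
    )
  }, numeric(1))
}

#' Log2 fold change with conditional pseudocount
#'
#' `log2(mean_tum / mean_ctr)`; when either mean is zero the pseudocount
#' is added to both means before taking the ratio.
#'
#' @param mean_tum,mean_ctr Non-negative group means (vectorised).
#' @param pseudocount Non-negative value added to both means when either
#'   is zero (default 1).
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(mean_tum, mean_ctr, pseudocount = 1) {
  if (any(mean_tum < 0) || any(mean_ctr < 0)) stop("means must be non-negative")
  n <- max(length(mean_tum), length(mean_ctr))
  mean_tum <- rep_len(mean_tum, n); mean_ctr <- rep_len(mean_ctr, n)
  zero <- mean_tum == 0 | mean_ctr == 0
  if (any(zero & mean_tum == 0 & mean_ctr == 0 & pseudocount == 0))
    stop("both means zero with zero pseudocount")
  num <- ifelse(zero, mean_tum + pseudocount, mean_tum)
  den <- ifelse(zero, mean_ctr + pseudocount, mean_ctr)
  log2(num / den)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wrapper over [stats::p.adjust()] with input
#' validation); order-preserving and never below the raw p-value.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression thresholds
#'
#' @param min_abs_log2fc Minimum absolute log2 fold change for a call
#'   (default 1, i.e. fold change 2).
#' @param max_p Maximum p-value for a call (default 0.05; the call uses
#'   `p <= max_p`).
#' @param use_adjusted Use BH-adjusted p-values for calling (default TRUE).
#' @return List of class `de_thresholds`.
#' @export
de_thresholds <- function(min_abs_log2fc = 1, max_p = 0.05,
                          use_adjusted = TRUE) {
  if (min_abs_log2fc < 0) stop("min_abs_log2fc must be >= 0")
  if (!(max_p > 0 && max_p < 1)) stop("max_p must lie in (0, 1)")
  structure(list(min_abs_log2fc = min_abs_log2fc, max_p = max_p,
                 use_adjusted = isTRUE(use_adjusted)),
            class = "de_thresholds")
}

#' Call differential expression between two conditions
#'
#' Counts are pooled (summed) within each condition — the Audic-Claverie
#' statistic is a two-library test — with pooled library sizes as totals.
#' Group means are library-size-normalised (counts per million of the
#' pooled library); direction is `up`/`down`/`ns` at the supplied
#' thresholds, with `up` meaning higher in the tumour condition.
#'
#' @param counts A [count_matrix()] whose condition labels contain exactly
#'   two levels.
#' @param thresholds A [de_thresholds()].
#' @param control,tumour Condition labels; defaults are the first and
#'   second unique label in `counts$condition`.
#' @param pseudocount Passed to [log2_fold_change()].
#' @return data.frame of class `de_result` with columns `feature_id`,
#'   `mean_ctr`, `mean_tum`, `log2fc`, `p_raw`, `p_adj`, `direction`.
#' @export
call_differential <- function(counts, thresholds = de_thresholds(),
                              control = NULL, tumour = NULL,
                              pseudocount = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  lev <- unique(counts$condition)
  if (length(lev) != 2) stop("exactly two conditions required")
  control <- control %||% lev[1]
  tumour <- tumour %||% lev[2]
  ctr <- counts$condition == control
  tum <- counts$condition == tumour
  if (!any(ctr) || !any(tum)) stop("each condition needs >= 1 sample")
  n1 <- sum(counts$library_sizes[ctr])
  n2 <- sum(counts$library_sizes[tum])
  if (n1 <= 0 || n2 <= 0) stop("a condition has zero total library size")
  x <- rowSums(counts$counts[, ctr, drop = FALSE])
  y <- rowSums(counts$counts[, tum, drop = FALSE])
  mean_ctr <- 1e6 * x / n1
  mean_tum <- 1e6 * y / n2
  p_raw <- ac_test(x, y, n1, n2, alternative = "two.sided")
  p_adj <- bh_adjust(p_raw)
  log2fc <- log2_fold_change(mean_tum, mean_ctr, pseudocount = pseudocount)
  p_use <- if (thresholds$use_adjusted) p_adj else p_raw
  direction <- rep("ns", length(x))
  sig <- p_use <= thresholds$max_p & abs(log2fc) >= thresholds$min_abs_log2fc
  direction[sig & log2fc > 0] <- "up"
  direction[sig & log2fc < 0] <- "down"
  out <- data.frame(
    feature_id = rownames(counts$counts),
    mean_ctr = mean_ctr, mean_tum = mean_tum,
    log2fc = log2fc, p_raw = p_raw, p_adj = p_adj,
    direction = direction,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("de_result", "data.frame")
  out
}
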