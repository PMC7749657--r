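## Hypergeometric gene-set overlap test.
##
## Null model: draw |set_b| labels without replacement from a universe of N
## labels of which |set_a| are "successes"; the p-value is the upper tail
## P(X >= k) of the overlap count, summed in log space so that extreme tails
## (p ~ 1e-13 and below) keep full relative precision.

#' Upper-tail hypergeometric probability
#'
#' \deqn{P(X \ge k) = \sum_{j=k}^{\min(K, n)}
#'   \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}}}
#' for a draw of `n` items without replacement from a universe of `N` items
#' containing `K` successes. The tail is inclusive of `k` and is accumulated
#' from log-probabilities (log-sum-exp).
#'
#' @param N Universe size.
#' @param K Number of successes in the universe (`K <= N`).
#' @param n Draw size (`n <= N`).
#' @param k Observed overlap (`0 <= k <= min(K, n)`).
#' @return Probability in (0, 1].
#' @examples
#' hypergeometric_upper(22277, 144, 90, 12)
#' @export
hypergeometric_upper <- function(N, K, n, k) {
  N <- check_count(N, "N", lower = 1L)
  K <- check_count(K, "K")
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  if (K > N) stop_field("K", "must not exceed N")
  if (n > N) stop_field("n", "must not exceed N")
  if (k > min(K, n)) stop_field("k", "must not exceed min(K, n)")
  if (k == 0L) return(1)
  j <- k:min(K, n)
  logp <- stats::dhyper(j, m = K, n = N - K, k = n, log = TRUE)
  min(exp(log_sum_exp(logp)), 1)
}

#' Test the overlap of two gene sets against a universe
#'
#' Restricts both sets to the universe (labels outside it are dropped with a
#' notice), counts the overlap `k = |A intersect B|` and computes the
#' upper-tail hypergeometric probability of an overlap at least that large,
#' plus the overlap as a percentage of set B.
#'
#' @param set_a,set_b Character vectors of gene labels (duplicates ignored).
#' @param universe Character vector of all eligible labels, e.g. the
#'   detection-filtered transcript ids.
#' @return Object of class `overlap_result`: `universe_size`, `set_a_size`,
#'   `set_b_size`, `overlap`, `overlap_fraction_of_b` (percent),
#'   `p_upper`, `overlap_genes`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe is empty", call. = FALSE)
  if (!length(set_a) || !length(set_b)) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  a_in <- set_a[set_a %in% universe]
  b_in <- set_b[set_b %in% universe]
  dropped <- (length(set_a) - length(a_in)) + (length(set_b) - length(b_in))
  if (dropped > 0L) {
    message(sprintf("dropping %d set labels outside the universe", dropped))
  }
  if (!length(a_in) || !length(b_in)) {
    stop("a gene set is empty after restriction to the universe",
         call. = FALSE)
  }
  ov <- intersect(a_in, b_in)
  structure(
    list(universe_size = length(universe),
         set_a_size = length(a_in), set_b_size = length(b_in),
         overlap = length(ov),
         overlap_fraction_of_b = 100 * length(ov) / length(b_in),
         p_upper = hypergeometric_upper(length(universe), length(a_in),
                                        length(b_in), length(ov)),
         overlap_genes = sort(ov)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d/%d of set B in set A (%.1f%%), universe %d, set A %d\n  P(X >= %d) = %s\n",
    x$overlap, x$set_b_size, x$overlap_fraction_of_b, x$universe_size,
    x$set_a_size, x$overlap, format(signif(x$p_upper, 2), scientific = TRUE)))
  invisible(x)
}
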