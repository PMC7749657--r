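## Genome-wide correlation screen of expression patterns against the IC50
## profile of a small cell-line panel.
##
## With only a handful of cell lines the null distribution of the Spearman
## correlation is discrete, so nominal p-values from large-sample formulas
## are misleading. The screen therefore enumerates the exact permutation
## null of the rank correlation (all n! reorderings of the profile) whenever
## n is small enough, and falls back to the t-approximation above a cap.

#' Construct a transcript x cell-line expression matrix with detection calls
#'
#' @param values Numeric matrix, transcripts in rows (rownames = transcript
#'   ids), cell lines in columns (colnames = line labels).
#' @param calls Character matrix of the same shape with per-cell detection
#'   calls: `"P"` (present), `"M"` (marginal) or `"A"` (absent). Defaults to
#'   all-`"P"` when omitted.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, calls = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_field("values", "must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_field("values", "must have transcript rownames and cell-line colnames")
  }
  if (anyDuplicated(colnames(values))) {
    stop_field("values", "cell-line labels must be unique")
  }
  if (is.null(calls)) {
    calls <- matrix("P", nrow(values), ncol(values),
                    dimnames = dimnames(values))
  }
  if (!is.matrix(calls) || !identical(dim(calls), dim(values))) {
    stop_field("calls", "must be a character matrix matching 'values'")
  }
  if (!all(calls %in% c("P", "M", "A"))) {
    stop_field("calls", "entries must be one of 'P', 'M', 'A'")
  }
  dimnames(calls) <- dimnames(values)
  structure(list(values = values, calls = calls),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d transcripts x %d cell lines (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}

subset_expression <- function(x, keep) {
  expression_matrix(x$values[keep, , drop = FALSE],
                    x$calls[keep, , drop = FALSE])
}

#' Filter transcripts by detection call
#'
#' Retains exactly those transcripts whose detection call is in `accepted`
#' in ALL cell lines; transcripts with a non-significant detection level
#' (call `"A"`) in any line are excluded by default. Row order is preserved.
#'
#' @param x An [expression_matrix()].
#' @param accepted Calls that count as reliably detected (default
#'   `c("P", "M")`).
#' @return Filtered `expression_matrix`.
#' @export
filter_by_detection <- function(x, accepted = c("P", "M")) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!all(accepted %in% c("P", "M", "A")) || length(accepted) < 1L) {
    stop_field("accepted", "must be a non-empty subset of {'P','M','A'}")
  }
  keep <- rowSums(matrix(x$calls %in% accepted, nrow(x$calls))) == ncol(x$calls)
  if (!any(keep)) {
    stop("no transcripts pass the detection filter; relax 'accepted'",
         call. = FALSE)
  }
  subset_expression(x, keep)
}

## Null distribution of the correlation between a fixed vector y and every
## permutation of itself, against externally supplied x-scores. Returns the
## n! x n matrix of permuted y-ranks (ties: the observed tied rank multiset
## is permuted, which weights multiset permutations correctly).
permuted_rank_matrix <- function(y) {
  ry <- rank(y)
  idx <- all_permutations(length(y))
  matrix(ry[idx], nrow(idx))
}

## Correlations of one centered/scaled score vector against the rows of a
## permuted-score matrix; sd of permuted rows equals sd(ry) (multiset fixed).
null_correlations <- function(rx, ry_perm) {
  n <- length(rx)
  sx <- stats::sd(rx)
  sy <- stats::sd(ry_perm[1L, ])
  as.vector(ry_perm %*% (rx - mean(rx))) / ((n - 1) * sx * sy)
}

P_EPS <- 1e-8  # tolerance when comparing discrete correlation values

#' Spearman correlation with an exact permutation p-value
#'
#' Computes the Spearman rank correlation of `x` and `y` (average ranks on
#' ties, product-moment correlation of the ranks) and, for small `n`, exact
#' one- and two-sided p-values by full enumeration of all `n!` permutations
#' of `y`'s ranks. `p_one_sided_pos` is the null probability of a
#' correlation at least as large as the observed one (inclusive);
#' `p_one_sided_neg` and `p_two_sided` analogously. Above `exact_cap` the
#' t-approximation is used and a notice is emitted.
#'
#' If either input is constant the correlation is undefined; the result
#' carries `rho = 0`, p-values of 1 and `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, no missing values.
#' @param exact_cap Largest `n` for which the exact null is enumerated
#'   (default 8; `8! = 40320` permutations).
#' @return Object of class `gene_correlation`: list with `rho`,
#'   `p_one_sided_pos`, `p_one_sided_neg`, `p_two_sided`, `n`, `method`
#'   (`"exact"` or `"t_approx"`), `degenerate`.
#' @examples
#' spearman_exact(1:5, c(10, 20, 30, 40, 50))  # rho = 1, p_pos = 1/120
#' @export
spearman_exact <- function(x, y, exact_cap = 8) {
  if (length(x) != length(y)) stop_field("y", "must match length of 'x'")
  n <- length(x)
  if (n < 3L) stop_field("x", "needs at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop_field("x", "missing values are not allowed")
  exact_cap <- check_count(exact_cap, "exact_cap", lower = 3L)

  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (degenerate) {
    return(structure(list(rho = 0, p_one_sided_pos = 1, p_one_sided_neg = 1,
                          p_two_sided = 1, n = n, method = "degenerate",
                          degenerate = TRUE),
                     class = "gene_correlation"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)

  if (n <= exact_cap) {
    ry_perm <- permuted_rank_matrix(y)
    rho_null <- null_correlations(rx, ry_perm)
    p_pos <- mean(rho_null >= rho - P_EPS)
    p_neg <- mean(rho_null <= rho + P_EPS)
    p_two <- mean(abs(rho_null) >= abs(rho) - P_EPS)
    method <- "exact"
  } else {
    message(sprintf(
      "n = %d exceeds the exact-enumeration cap (%d); using t-approximation",
      n, exact_cap))
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p_pos <- stats::pt(tt, df = n - 2, lower.tail = FALSE)
    p_neg <- stats::pt(tt, df = n - 2, lower.tail = TRUE)
    p_two <- 2 * min(p_pos, p_neg)
    method <- "t_approx"
  }
  structure(list(rho = rho, p_one_sided_pos = p_pos, p_one_sided_neg = p_neg,
                 p_two_sided = min(p_two, 1), n = n, method = method,
                 degenerate = FALSE),
            class = "gene_correlation")
}

#' @export
print.gene_correlation <- function(x, ...) {
  cat(sprintf(
    "rho = %.4f (n = %d, %s): p+ = %.4g, p- = %.4g, p2 = %.4g%s\n",
    x$rho, x$n, x$method, x$p_one_sided_pos, x$p_one_sided_neg,
    x$p_two_sided, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

## Align matrix columns to profile cell lines by case-folded exact label
## match; error names the unmatched labels.
align_to_profile <- function(x, profile) {
  mat_lines <- colnames(x$values)
  prof_lines <- profile$cell_line
  idx <- match(tolower(prof_lines), tolower(mat_lines))
  if (anyNA(idx)) {
    missing_in_mat <- prof_lines[is.na(idx)]
    stop(sprintf("cell lines missing from expression matrix: %s",
                 paste(missing_in_mat, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(tolower(mat_lines), tolower(prof_lines))
  if (length(extra)) {
    stop(sprintf("cell lines missing from IC50 profile: %s",
                 paste(mat_lines[tolower(mat_lines) %in% extra],
                       collapse = ", ")), call. = FALSE)
  }
  expression_matrix(x$values[, idx, drop = FALSE],
                    x$calls[, idx, drop = FALSE])
}

#' Genome-wide correlation screen against an IC50 profile
#'
#' Correlates every transcript's cross-line expression pattern with the
#' normalized IC50 profile and selects transcripts that correlate
#' significantly positively or negatively. The correlation is Spearman by
#' default with exact permutation p-values (see [spearman_exact()]); with
#' `method = "pearson"` the product-moment correlation of the raw values is
#' used, with the same exact permutation null. At the default one-sided
#' sidedness, `positive_set` collects transcripts with `rho > 0` and
#' `p_one_sided_pos <= alpha`, `negative_set` symmetrically. No multiple
#' testing correction is applied by default (nominal p-values);
#' `p_adjust = "BH"` applies Benjamini-Hochberg within each tail.
#'
#' Transcripts with missing values among the aligned lines are dropped with
#' a notice. Transcripts with a constant pattern (or a constant profile) are
#' degenerate: `rho = 0`, `p = 1`, never selected.
#'
#' @param x Detection-filtered [expression_matrix()].
#' @param profile [build_profile()] result; columns are aligned to the
#'   profile's cell lines by case-insensitive label match (error if the sets
#'   differ).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param sidedness `"one_sided"` (default) or `"two_sided"`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param exact_cap Passed to the exact-null enumeration (default 8).
#' @return List with `result` (class `screen_result`: counts, the two gene
#'   sets, alpha, sidedness) and `correlations` (per-transcript data.frame
#'   with `rho` and the three p-values).
#' @export
genome_screen <- function(x, profile, alpha = 0.05,
                          sidedness = c("one_sided", "two_sided"),
                          method = c("spearman", "pearson"),
                          p_adjust = c("none", "BH"), exact_cap = 8) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(profile, "ic50_profile"))
  sidedness <- match.arg(sidedness)
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)

  n_input <- nrow(x$values)
  x <- align_to_profile(x, profile)
  ok <- rowSums(is.na(x$values)) == 0L
  if (any(!ok)) {
    message(sprintf("dropping %d transcripts with missing values",
                    sum(!ok)))
    x <- subset_expression(x, ok)
  }
  vals <- x$values
  m <- nrow(vals); n <- ncol(vals)
  y <- profile$n_ic50

  score_row <- function(v) if (method == "spearman") rank(v) else v
  y_score <- score_row(y)

  if (stats::sd(y_score) == 0) {
    ## Degenerate profile: every correlation undefined, both sets empty.
    corr <- data.frame(transcript_id = rownames(vals), rho = 0,
                       p_one_sided_pos = 1, p_one_sided_neg = 1,
                       p_two_sided = 1, n = n, degenerate = TRUE,
                       stringsAsFactors = FALSE)
  } else if (n <= exact_cap) {
    ## Vectorized exact screen: one permuted-score matrix for the shared
    ## profile, correlated against every transcript at once.
    idx <- all_permutations(n)
    y_perm <- matrix(y_score[idx], nrow(idx))          # n! x n
    X <- t(apply(vals, 1L, score_row))                  # m x n scores
    xc <- X - rowMeans(X)
    sx <- sqrt(rowSums(xc^2) / (n - 1))
    degenerate <- sx == 0
    sx[degenerate] <- 1
    yc <- y_perm - rowMeans(y_perm)
    sy <- stats::sd(y_score)
    ## m x n! matrix of null correlations per transcript.
    rho_null <- (xc %*% t(yc)) / ((n - 1) * outer(sx, rep(sy, nrow(yc))))
    rho_obs <- (xc %*% (y_score - mean(y_score))) / ((n - 1) * sx * sy)
    rho_obs <- as.vector(rho_obs)
    p_pos <- rowMeans(rho_null >= rho_obs - P_EPS)
    p_neg <- rowMeans(rho_null <= rho_obs + P_EPS)
    p_two <- rowMeans(abs(rho_null) >= abs(rho_obs) - P_EPS)
    rho_obs[degenerate] <- 0
    p_pos[degenerate] <- 1; p_neg[degenerate] <- 1; p_two[degenerate] <- 1
    corr <- data.frame(transcript_id = rownames(vals), rho = rho_obs,
                       p_one_sided_pos = p_pos, p_one_sided_neg = p_neg,
                       p_two_sided = pmin(p_two, 1), n = n,
                       degenerate = degenerate, stringsAsFactors = FALSE)
  } else {
    res <- apply(vals, 1L, function(v) {
      g <- suppressMessages(spearman_exact(v, y, exact_cap = exact_cap))
      c(g$rho, g$p_one_sided_pos, g$p_one_sided_neg, g$p_two_sided,
        as.numeric(g$degenerate))
    })
    corr <- data.frame(transcript_id = rownames(vals), rho = res[1, ],
                       p_one_sided_pos = res[2, ], p_one_sided_neg = res[3, ],
                       p_two_sided = res[4, ], n = n,
                       degenerate = res[5, ] > 0, stringsAsFactors = FALSE)
  }
  rownames(corr) <- NULL

  p_pos_sel <- corr$p_one_sided_pos
  p_neg_sel <- corr$p_one_sided_neg
  p_two_sel <- corr$p_two_sided
  if (p_adjust == "BH") {
    p_pos_sel <- stats::p.adjust(p_pos_sel, method = "BH")
    p_neg_sel <- stats::p.adjust(p_neg_sel, method = "BH")
    p_two_sel <- stats::p.adjust(p_two_sel, method = "BH")
  }
  if (sidedness == "one_sided") {
    pos <- corr$rho > 0 & p_pos_sel <= alpha
    neg <- corr$rho < 0 & p_neg_sel <= alpha
  } else {
    pos <- corr$rho > 0 & p_two_sel <= alpha
    neg <- corr$rho < 0 & p_two_sel <= alpha
  }
  result <- structure(
    list(n_input = n_input, n_filtered = nrow(corr),
         positive_set = corr$transcript_id[pos],
         negative_set = corr$transcript_id[neg],
         alpha = alpha, sidedness = sidedness, method = method,
         p_adjust = p_adjust),
    class = "screen_result")
  list(result = result, correlations = corr)
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "screen: %d/%d transcripts screened (%s %s, alpha = %g%s)\n  %d positive, %d negative\n",
    x$n_filtered, x$n_input, x$sidedness, x$method, x$alpha,
    if (x$p_adjust == "BH") ", BH-adjusted" else "",
    length(x$positive_set), length(x$negative_set)))
  invisible(x)
}

#' Correlate a predefined gene signature with one or more IC50 profiles
#'
#' Restricts the correlation screen to the genes of a signature (for
#' example, an epithelial-mesenchymal transition signature) and reports, per
#' profile, each gene's correlation with the profile plus the fraction of
#' signature genes reaching significance — so that the same signature can be
#' contrasted across compounds' susceptibility profiles.
#'
#' @param signature Character vector of gene labels.
#' @param x An [expression_matrix()] whose rownames include the signature
#'   labels.
#' @param profiles A single `ic50_profile` or a named list of them (names =
#'   profile labels, e.g. compounds).
#' @param alpha,sidedness,method,exact_cap As in [genome_screen()].
#' @param collapse If `TRUE` (default) and a label matches several rows
#'   (e.g. multiple probes per gene), the row with the largest mean
#'   expression is used.
#' @return List with `table` (gene x profile correlations, columns
#'   `profile`, `gene`, `rho`, p-values, `significant`) and `summary`
#'   (per-profile `n_found`, `n_significant`, `fraction_significant`,
#'   `missing` genes).
#' @export
signature_correlation <- function(signature, x, profiles, alpha = 0.05,
                                  sidedness = c("one_sided", "two_sided"),
                                  method = c("spearman", "pearson"),
                                  exact_cap = 8, collapse = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  sidedness <- match.arg(sidedness)
  method <- match.arg(method)
  if (inherits(profiles, "ic50_profile")) profiles <- list(profile = profiles)
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  if (is.null(names(profiles))) {
    names(profiles) <- paste0("profile", seq_along(profiles))
  }
  signature <- unique(as.character(signature))
  found <- signature[signature %in% rownames(x$values)]
  missing <- setdiff(signature, found)
  if (!length(found)) {
    stop(sprintf("no signature gene found in the matrix; missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  keep <- rownames(x$values) %in% found
  xs <- subset_expression(x, keep)
  if (collapse && anyDuplicated(rownames(xs$values))) {
    means <- rowMeans(xs$values)
    ord <- order(rownames(xs$values), -means)
    first <- !duplicated(rownames(xs$values)[ord])
    xs <- subset_expression(xs, sort(seq_len(nrow(xs$values))[ord][first]))
  }

  rows <- list(); summ <- list()
  for (pname in names(profiles)) {
    prof <- profiles[[pname]]
    aligned <- align_to_profile(xs, prof)
    sc <- genome_screen(aligned, prof, alpha = alpha, sidedness = sidedness,
                        method = method, exact_cap = exact_cap)
    tab <- sc$correlations
    sig <- tab$transcript_id %in%
      c(sc$result$positive_set, sc$result$negative_set)
    rows[[pname]] <- data.frame(profile = pname, gene = tab$transcript_id,
                                rho = tab$rho,
                                p_one_sided_pos = tab$p_one_sided_pos,
                                p_one_sided_neg = tab$p_one_sided_neg,
                                p_two_sided = tab$p_two_sided,
                                significant = sig, stringsAsFactors = FALSE)
    summ[[pname]] <- data.frame(profile = pname, n_found = nrow(tab),
                                n_significant = sum(sig),
                                fraction_significant = sum(sig) / nrow(tab),
                                stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       summary = do.call(rbind, c(summ, make.row.names = FALSE)),
       missing = missing)
}

#' Order cell lines by the expression of one gene
#'
#' Sorts the panel by a single gene's expression, descending by default —
#' e.g. ranking lines from most epithelial to most mesenchymal by E-cadherin
#' (CDH1) expression. Ties keep the input column order (stable sort).
#'
#' @param x An [expression_matrix()].
#' @param gene Transcript/gene label present in the matrix.
#' @param decreasing Sort direction (default `TRUE`).
#' @return Character vector of cell-line labels.
#' @export
rank_lines_by_gene <- function(x, gene, decreasing = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!gene %in% rownames(x$values)) {
    stop(sprintf("gene '%s' not found in the expression matrix", gene),
         call. = FALSE)
  }
  v <- x$values[gene, ]
  ord <- order(if (decreasing) -v else v)  # radix: stable on ties
  colnames(x$values)[ord]
}
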