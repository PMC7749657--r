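make_matrix <- function(values, calls = NULL, lines = paste0("L", 1:5)) {
  m <- matrix(values, ncol = length(lines), byrow = TRUE,
              dimnames = list(sprintf("G%02d", seq_len(length(values) / length(lines))),
                              lines))
  cm <- if (is.null(calls)) NULL else
    matrix(calls, ncol = length(lines), byrow = TRUE, dimnames = dimnames(m))
  expression_matrix(m, cm)
}

test_that("the detection filter keeps transcripts called P/M in every line", {
  x <- make_matrix(rep(1, 15),
                   calls = c("P", "P", "M", "P", "P",
                             "P", "P", "A", "P", "P",
                             "M", "M", "M", "M", "M"))
  kept <- filter_by_detection(x)
  expect_identical(rownames(kept$values), c("G01", "G03"))
  expect_identical(rownames(filter_by_detection(x, c("P", "M", "A"))$values),
                   rownames(x$values))
  expect_error(filter_by_detection(x, accepted = "A"), "relax")
})

test_that("shrinking the accepted call set weakly shrinks the filtered set", {
  withr::with_seed(21, {
    for (i in 1:10) {
      calls <- sample(c("P", "M", "A"), 40 * 5, replace = TRUE,
                      prob = c(0.6, 0.25, 0.15))
      x <- make_matrix(rnorm(200), calls = calls)
      all3 <- rownames(filter_by_detection(x, c("P", "M", "A"))$values)
      pm <- tryCatch(rownames(filter_by_detection(x, c("P", "M"))$values),
                     error = function(e) character(0))
      p <- tryCatch(rownames(filter_by_detection(x, "P")$values),
                    error = function(e) character(0))
      expect_true(all(pm %in% all3))
      expect_true(all(p %in% pm))
    }
  })
})

test_that("exact Spearman p-values match brute-force enumeration", {
  r <- spearman_exact(1:5, c(10, 20, 30, 40, 50))
  expect_equal(r$rho, 1)
  expect_equal(r$p_one_sided_pos, 1 / 120)

  rev <- spearman_exact(1:5, c(50, 40, 30, 20, 10))
  expect_equal(rev$rho, -1)
  expect_equal(rev$p_one_sided_neg, 1 / 120)

  # rho = 0.9 arises from one adjacent transposition; inclusive tail
  # (identity + 4 transpositions) gives 5/120, confirmed by the oracle
  y <- c(1, 2, 3, 5, 4)
  r9 <- spearman_exact(1:5, y)
  expect_equal(r9$rho, 0.9)
  expect_equal(r9$p_one_sided_pos, oracle_spearman_p_pos(1:5, y))
  expect_equal(r9$p_one_sided_pos, 5 / 120)

  # random inputs, including ties, against the oracle
  withr::with_seed(31, {
    for (i in 1:15) {
      n <- sample(3:6, 1)
      x <- sample(1:4, n, replace = TRUE)
      yy <- rnorm(n)
      if (sd(x) == 0) next
      r <- spearman_exact(x, yy)
      expect_equal(r$p_one_sided_pos, oracle_spearman_p_pos(x, yy))
      expect_equal(r$rho, cor(x, yy, method = "spearman"))
    }
  })
})

test_that("the enumerated null is a symmetric probability distribution", {
  rho_null <- oracle_spearman_null(5)
  expect_length(rho_null, 120)
  expect_equal(mean(rho_null >= 1 - 1e-8), 1 / 120)
  expect_equal(sort(rho_null), sort(-rho_null))
  # the two-sided p dominates the one-sided p of the observed direction
  withr::with_seed(8, {
    for (i in 1:10) {
      r <- spearman_exact(rnorm(5), rnorm(5))
      expect_gte(r$p_two_sided + 1e-12,
                 min(r$p_one_sided_pos, r$p_one_sided_neg))
      expect_true(r$p_two_sided > 0 && r$p_two_sided <= 1)
    }
  })
})

test_that("degenerate inputs yield rho 0 with p 1", {
  r <- spearman_exact(rep(2, 5), rnorm(5))
  expect_true(r$degenerate)
  expect_equal(r$rho, 0)
  expect_equal(r$p_two_sided, 1)
})

test_that("above the enumeration cap the t-approximation takes over", {
  withr::with_seed(14, {
    x <- rnorm(12); y <- x + rnorm(12, 0, 0.7)
  })
  expect_message(r <- spearman_exact(x, y), "t-approximation")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE,
                                  alternative = "greater"))
  expect_equal(r$p_one_sided_pos, unname(ct$p.value), tolerance = 1e-10)
})

test_that("the genome screen recovers planted sets exactly on clean data", {
  sim <- simulate_expression(expression_sim_config(
    n_transcripts = 300, n_planted_positive = 20, n_planted_negative = 10,
    pattern_noise_sd = 0, frac_absent_calls = 0, seed = 17))
  prof <- build_profile(setNames(sim$signature * 40 + 5,
                                 names(sim$signature)))
  sc <- genome_screen(sim$matrix, prof)
  expect_setequal(sc$result$positive_set,
                  sim$truth$transcript_id[sim$truth$planted == "positive"])
  expect_setequal(sc$result$negative_set,
                  sim$truth$transcript_id[sim$truth$planted == "negative"])
  expect_length(intersect(sc$result$positive_set, sc$result$negative_set), 0)
})

test_that("screen selections are invariant to transcript row order", {
  sim <- simulate_expression(expression_sim_config(
    n_transcripts = 100, n_planted_positive = 8, n_planted_negative = 4,
    pattern_noise_sd = 0.3, frac_absent_calls = 0, seed = 23))
  prof <- build_profile(setNames(sim$signature + 1, names(sim$signature)))
  sc1 <- genome_screen(sim$matrix, prof)
  perm <- withr::with_seed(2, sample(nrow(sim$matrix$values)))
  shuffled <- expression_matrix(sim$matrix$values[perm, ],
                                sim$matrix$calls[perm, ])
  sc2 <- genome_screen(shuffled, prof)
  expect_setequal(sc1$result$positive_set, sc2$result$positive_set)
  expect_setequal(sc1$result$negative_set, sc2$result$negative_set)
})

test_that("a tied profile or an unattainable alpha empties both gene sets", {
  x <- make_matrix(rnorm(50, 7))
  tied <- data.frame(cell_line = paste0("L", 1:5), ic50 = 1, n_ic50 = 0,
                     rank = 3)
  class(tied) <- c("ic50_profile", "data.frame")
  sc <- genome_screen(x, tied)
  expect_length(sc$result$positive_set, 0)
  expect_length(sc$result$negative_set, 0)

  prof <- build_profile(setNames(c(1, 2, 3, 4, 5), paste0("L", 1:5)))
  sc2 <- genome_screen(x, prof, alpha = 1 / 240)  # below the 1/120 floor
  expect_length(sc2$result$positive_set, 0)
  expect_length(sc2$result$negative_set, 0)
})

test_that("screen alignment errors name the unmatched cell lines", {
  x <- make_matrix(rnorm(10), lines = c("La", "Lb", "Lc", "Ld", "Le"))
  prof <- build_profile(setNames(1:5, c("La", "Lb", "Lc", "Ld", "OTHER")))
  expect_error(genome_screen(x, prof), "OTHER")
  # case-folded labels align fine
  prof2 <- build_profile(setNames(1:5, c("LA", "LB", "LC", "LD", "LE")))
  expect_silent(genome_screen(x, prof2))
})

test_that("signature scoring reports per-profile correlations and fractions", {
  sim <- simulate_expression(expression_sim_config(
    n_transcripts = 60, n_planted_positive = 5, pattern_noise_sd = 0,
    frac_absent_calls = 0, seed = 29))
  planted <- sim$truth$transcript_id
  prof <- build_profile(setNames(sim$signature + 2, names(sim$signature)))
  rev_prof <- build_profile(setNames(max(sim$signature) - sim$signature + 2,
                                     names(sim$signature)))
  out <- signature_correlation(planted[1], sim$matrix,
                               list(fwd = prof, rev = rev_prof))
  fwd <- out$table[out$table$profile == "fwd", ]
  rev <- out$table[out$table$profile == "rev", ]
  expect_true(fwd$significant)
  expect_equal(fwd$rho, 1)
  expect_equal(rev$rho, -1)
  expect_true(rev$p_one_sided_neg <= 0.05 && rev$p_one_sided_pos > 0.05)

  multi <- signature_correlation(c(planted, "NOT_A_GENE"), sim$matrix, prof)
  expect_identical(multi$missing, "NOT_A_GENE")
  s <- multi$summary
  expect_equal(s$fraction_significant, s$n_significant / s$n_found)
  expect_true(all(s$fraction_significant >= 0 & s$fraction_significant <= 1))

  expect_error(signature_correlation("NOPE", sim$matrix, prof), "NOPE")
})

test_that("cell lines rank by single-gene expression with stable ties", {
  x <- make_matrix(c(5, 3, 4, 2, 1))
  expect_identical(rank_lines_by_gene(x, "G01"),
                   c("L1", "L3", "L2", "L4", "L5"))
  tied <- make_matrix(c(5, 3, 3, 2, 1))
  expect_identical(rank_lines_by_gene(tied, "G01"),
                   c("L1", "L2", "L3", "L4", "L5"))
  one <- expression_matrix(matrix(1, 1, 1, dimnames = list("G1", "L1")))
  expect_identical(rank_lines_by_gene(one, "G1"), "L1")
  expect_error(rank_lines_by_gene(x, "MISSING"), "MISSING")
})
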