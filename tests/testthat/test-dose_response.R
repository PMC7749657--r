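test_that("background subtraction is elementwise with floor clipping", {
  expect_equal(subtract_background(matrix(c(500, 300), 1), 100),
               matrix(c(400, 200), 1))
  raw <- matrix(c(500, 300), 1)
  expect_identical(subtract_background(raw, 0), raw)
  expect_warning(out <- subtract_background(matrix(50), 100, floor = 1),
                 "clipped")
  expect_equal(out, matrix(1))
})

test_that("series construction rejects an untreated reference below background", {
  expect_error(
    dose_response_series("L1", doses = c(0, 10), raw_intensities = matrix(1:2, 1),
                         background = 100, reference_intensity = -5),
    "reference signal below background")
})

test_that("viability normalization follows the percent-of-untreated definition", {
  series <- dose_response_series(
    "L1", doses = c(0, 10, 20),
    raw_intensities = rbind(c(1000, 400, 600), c(1000, 600, 400)),
    background = 0, reference_intensity = 1000)
  nr <- normalize_viability(series)
  expect_equal(nr$nI[1, ], c(100, 40, 60), ignore_attr = TRUE)
  expect_equal(nr$nI[2, ], c(100, 60, 40), ignore_attr = TRUE)
  # replicate average at each dose
  expect_equal(nr$anI, c(100, 50, 50), ignore_attr = TRUE)
  expect_identical(nr$n_replicates, 2L)
})

test_that("the Hill function hits its plateaus and midpoint and decreases", {
  expect_equal(hill_function(0, 10, 100, 50, 1.5), 100)
  expect_equal(hill_function(50, 10, 100, 50, 1.5), 55)
  expect_equal(hill_function(1e6 * 50, 10, 100, 50, 1.5), 10,
               tolerance = 1e-5)
  # strict monotone decrease over random valid parameter draws
  withr::with_seed(99, {
    for (i in 1:25) {
      mn <- runif(1, 0, 40); mx <- mn + runif(1, 10, 120)
      ic50 <- 10^runif(1, -2, 3); h <- runif(1, 0.1, 8)
      d <- sort(10^runif(20, -3, 4))
      v <- hill_function(d, mn, mx, ic50, h)
      # strictly decreasing up to floating-point saturation at the plateaus
      expect_true(all(diff(v) <= 0))
      expect_lt(v[20], v[1])
    }
  })
})

test_that("the Hill fit recovers noiseless parameters and ignores row order", {
  doses <- c(0, geometric_ladder(50, 8))
  anI <- hill_function(doses, 10, 100, 50, 1.5)
  mk <- function(d, y) {
    structure(list(cell_line = "L1", compound = "CPD", timepoint_h = 24,
                   doses = d, nI = matrix(y, 1), anI = y, n_replicates = 1L),
              class = "normalized_response")
  }
  fit <- fit_hill(mk(doses, anI))
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 - 50) / 50, 0.01)
  expect_lt(abs(fit$hill - 1.5) / 1.5, 0.01)
  expect_lt(abs(fit$min - 10), 0.1)
  expect_lt(abs(fit$max - 100), 0.1)
  # midpoint identity of the fitted curve
  expect_equal(hill_function(fit$ic50, fit$min, fit$max, fit$ic50, fit$hill),
               (fit$min + fit$max) / 2)

  ord <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  fit2 <- fit_hill(mk(doses[ord], anI[ord]))
  expect_equal(fit2$ic50, fit$ic50, tolerance = 1e-8)
  expect_equal(fit2$hill, fit$hill, tolerance = 1e-8)
})

test_that("fit errors on too few doses and on flat responses", {
  flat <- structure(list(cell_line = "L", compound = "C", timepoint_h = 24,
                         doses = c(0, 1, 2, 4, 8),
                         nI = matrix(rep(80, 5), 1), anI = rep(80, 5),
                         n_replicates = 1L), class = "normalized_response")
  expect_error(fit_hill(flat), "no dose dependence")
  few <- structure(list(cell_line = "L", compound = "C", timepoint_h = 24,
                        doses = c(0, 1, 2, 4),
                        nI = matrix(c(100, 80, 50, 20), 1),
                        anI = c(100, 80, 50, 20), n_replicates = 1L),
                   class = "normalized_response")
  expect_error(fit_hill(few), "4 distinct non-zero doses")
})

test_that("fits are invariant to intensity scale and equivariant to dose units", {
  doses <- c(0, geometric_ladder(20, 8))
  raw <- rbind(hill_function(doses, 5, 100, 20, 2) * 50,
               hill_function(doses, 5, 100, 20, 2) * 50 * 1.02)
  base <- dose_response_series("L1", doses = doses, raw_intensities = raw,
                               background = 0, reference_intensity = 5000)
  scaled <- dose_response_series("L1", doses = doses,
                                 raw_intensities = raw * 7.5,
                                 background = 0,
                                 reference_intensity = 5000 * 7.5)
  nb <- normalize_viability(base); ns <- normalize_viability(scaled)
  expect_equal(nb$nI, ns$nI)
  expect_equal(nb$anI, ns$anI)
  fb <- fit_hill(nb); fs <- fit_hill(ns)
  expect_equal(fb$ic50, fs$ic50)

  # rescaling doses rescales IC50, leaves shape parameters unchanged
  c_fac <- 1000  # uM -> nM
  rescaled <- dose_response_series("L1", doses = doses * c_fac,
                                   raw_intensities = raw, background = 0,
                                   reference_intensity = 5000)
  fr <- fit_hill(normalize_viability(rescaled))
  expect_equal(fr$ic50 / c_fac, fb$ic50, tolerance = 1e-6)
  expect_equal(fr$hill, fb$hill, tolerance = 1e-6)
  expect_equal(fr$min, fb$min, tolerance = 1e-6)
  expect_equal(fr$max, fb$max, tolerance = 1e-6)
})

test_that("replicate noise leaves the median IC50 error under 10%", {
  doses <- c(0, geometric_ladder(50, 8))
  errs <- withr::with_seed(123, vapply(1:20, function(i) {
    nI <- t(replicate(3, hill_function(doses, 10, 100, 50, 1.5) +
                        rnorm(length(doses), 0, 2)))
    nr <- structure(list(cell_line = "L", compound = "C", timepoint_h = 24,
                         doses = doses, nI = nI, anI = colMeans(nI),
                         n_replicates = 3L), class = "normalized_response")
    fit <- fit_hill(nr)
    abs(fit$ic50 - 50) / 50
  }, numeric(1)))
  expect_lt(median(errs), 0.10)
})

test_that("profiles normalize to [0,1] and rank ascending with average ties", {
  prof <- build_profile(c(A = 10, B = 20, C = 30, D = 40, E = 50))
  expect_equal(prof$n_ic50, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(prof$rank, 1:5)

  expect_warning(tied <- build_profile(c(A = 7, B = 7)), "equal")
  expect_equal(tied$rank, c(1.5, 1.5))
  expect_equal(tied$n_ic50, c(0, 0))

  withr::with_seed(4, {
    for (i in 1:10) {
      v <- rnorm(5)
      names(v) <- paste0("L", 1:5)
      p <- build_profile(v)
      expect_true(all(p$n_ic50 >= 0 & p$n_ic50 <= 1))
      expect_identical(sum(p$n_ic50 == 0), 1L)
      expect_identical(sum(p$n_ic50 == 1), 1L)
    }
  })
})

test_that("non-converged fits are excluded from profiles with a warning", {
  good <- structure(list(ic50 = 10, converged = TRUE), class = "hill_fit")
  good2 <- structure(list(ic50 = 30, converged = TRUE), class = "hill_fit")
  bad <- structure(list(ic50 = 99, converged = FALSE), class = "hill_fit")
  expect_warning(prof <- build_profile(list(A = good, B = good2, C = bad)),
                 "non-converged")
  expect_identical(prof$cell_line, c("A", "B"))
})

test_that("timepoint aggregation is idempotent and re-normalizes interior patterns", {
  p <- build_profile(c(A = 1, B = 3, C = 10))
  expect_equal(aggregate_timepoints(list(p, p, p))$n_ic50, p$n_ic50)

  mk <- function(nv) {
    out <- data.frame(cell_line = c("A", "B", "C"), ic50 = nv, n_ic50 = nv,
                      rank = rank(nv))
    class(out) <- c("ic50_profile", "data.frame")
    out
  }
  agg <- aggregate_timepoints(list(mk(c(0, 0.2, 1)), mk(c(0, 0.4, 1)),
                                   mk(c(0, 0.6, 1))))
  expect_equal(agg$n_ic50, c(0, 0.4, 1))

  # opposing two-line patterns average to a constant -> warning path
  two <- function(nv) {
    out <- data.frame(cell_line = c("A", "B"), ic50 = nv, n_ic50 = nv,
                      rank = rank(nv))
    class(out) <- c("ic50_profile", "data.frame")
    out
  }
  expect_warning(flat <- aggregate_timepoints(list(two(c(0, 1)),
                                                   two(c(1, 0)))),
                 "equal")
  expect_equal(flat$n_ic50, c(0, 0))

  expect_error(aggregate_timepoints(list(p, two(c(0, 1)))), "mismatch")
})
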