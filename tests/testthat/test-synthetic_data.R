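test_that("noiseless plate wells reproduce the Hill model exactly", {
  cfg <- plate_sim_config(
    cell_lines = c("L1", "L2"),
    true_hill_params = list(L1 = c(min = 10, max = 100, ic50 = 50, hill = 1.5),
                            L2 = c(min = 5, max = 100, ic50 = 20, hill = 2)),
    dose_ladder = c(0, 12.5, 25, 50, 100, 200), n_replicates = 2,
    noise_sd = 0, background_level = 100, reference_intensity = 10000,
    timepoints_h = 24, seed = 3)
  plate <- simulate_plate(cfg)

  # dose 0: intensity = background + reference * max / 100 exactly
  d0 <- plate$intensity[plate$cell_line == "L1" & plate$well_type == "untreated"]
  expect_equal(d0, rep(100 + 10000 * 100 / 100, 2))

  # blank wells carry pure background
  expect_equal(plate$intensity[plate$well_type == "blank"], rep(100, 4))

  # at the true IC50, normalized viability equals the Hill midpoint
  series <- series_from_plate(plate, "L1", "CPD", 24)
  nr <- normalize_viability(series)
  expect_equal(nr$anI[nr$doses == 50], (10 + 100) / 2, ignore_attr = TRUE)
})

test_that("plate simulation is deterministic given the seed", {
  cfg <- plate_sim_config(
    cell_lines = "L1",
    true_hill_params = list(L1 = c(min = 10, max = 100, ic50 = 50, hill = 1.5)),
    noise_sd = 150, seed = 42)
  expect_identical(simulate_plate(cfg), simulate_plate(cfg))
})

test_that("plate config validation names the offending field", {
  params_ok <- list(L1 = c(min = 10, max = 100, ic50 = 50, hill = 1.5))
  expect_error(plate_sim_config("L1", list(L1 = c(min = 10, max = 100,
                                                  ic50 = -1, hill = 1))),
               "true_hill_params")
  expect_error(plate_sim_config("L1", params_ok,
                                dose_ladder = c(10, 5)), "dose_ladder")
  expect_error(plate_sim_config("L1", params_ok, n_replicates = 0),
               "n_replicates")
  expect_error(plate_sim_config("L1", params_ok, noise_sd = -1), "noise_sd")
})

test_that("noiseless plates round-trip through the Hill fit within 1%", {
  params <- toy_panel_params()
  for (cl in names(params)) {
    p <- params[[cl]]
    cfg <- plate_sim_config(
      cell_lines = cl, true_hill_params = params[cl],
      dose_ladder = c(0, geometric_ladder(p[["ic50"]], n = 9)),
      noise_sd = 0, timepoints_h = 24, seed = 1)
    series <- series_from_plate(simulate_plate(cfg), cl, "CPD", 24)
    fit <- fit_hill(normalize_viability(series))
    expect_true(fit$converged)
    expect_lt(abs(fit$ic50 - p[["ic50"]]) / p[["ic50"]], 0.01)
  }
})

test_that("planted expression patterns are perfectly rank-concordant at zero noise", {
  cfg <- expression_sim_config(
    n_transcripts = 120, n_planted_positive = 15, n_planted_negative = 10,
    pattern_noise_sd = 0, frac_absent_calls = 0, seed = 5)
  sim <- simulate_expression(cfg)
  pos <- sim$truth$transcript_id[sim$truth$planted == "positive"]
  neg <- sim$truth$transcript_id[sim$truth$planted == "negative"]
  rho <- apply(sim$matrix$values[pos, , drop = FALSE], 1,
               stats::cor, y = sim$signature, method = "spearman")
  expect_equal(unname(rho), rep(1, length(pos)))
  rho_neg <- apply(sim$matrix$values[neg, , drop = FALSE], 1,
                   stats::cor, y = sim$signature, method = "spearman")
  expect_equal(unname(rho_neg), rep(-1, length(neg)))
})

test_that("expression simulator handles empty truth and invalid configs", {
  sim <- simulate_expression(expression_sim_config(n_transcripts = 50,
                                                   seed = 2))
  expect_identical(nrow(sim$truth), 0L)
  expect_error(expression_sim_config(n_transcripts = 10,
                                     n_planted_positive = 8,
                                     n_planted_negative = 5),
               "exceed")
  expect_error(expression_sim_config(frac_absent_calls = 1),
               "frac_absent_calls")
})

test_that("expression simulation is deterministic and calls have P/M/A structure", {
  cfg <- expression_sim_config(n_transcripts = 80, n_planted_positive = 5,
                               frac_absent_calls = 0.3, seed = 9)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$matrix$calls %in% c("P", "M", "A")))
  expect_gt(mean(s1$matrix$calls == "A"), 0.2)  # near the configured 0.3
})

test_that("near-unit turning persistence yields straight tracks with the expected statistic", {
  cfg <- track_sim_config(n_cells = 3, total_time = 400, frame_interval = 20,
                          speed_mean = 0.5,
                          turning_persistence = 1 - 1e-12, seed = 7)
  tracks <- tracks_from_table(simulate_tracks(cfg), t_max = 400)
  for (tr in tracks) {
    p <- track_persistence(tr)
    expect_equal(as.numeric(p), sqrt((tr$times[length(tr$times)] - tr$times[1]) / 400),
                 tolerance = 1e-6)
  }
})

test_that("zero speed gives stationary tracks with zero speed statistic", {
  cfg <- track_sim_config(n_cells = 2, total_time = 100, frame_interval = 20,
                          speed_mean = 0, seed = 1)
  tab <- simulate_tracks(cfg)
  expect_true(all(tab$x_um == 0) && all(tab$y_um == 0))
  tracks <- tracks_from_table(tab, t_max = 100)
  expect_equal(unname(vapply(tracks, track_speed, numeric(1))), c(0, 0))
})

test_that("without dropout every track spans the full acquisition", {
  cfg <- track_sim_config(n_cells = 5, total_time = 200, frame_interval = 20,
                          dropout_prob = 0, seed = 3)
  tab <- simulate_tracks(cfg)
  expect_true(all(table(tab$track_id) == 200 / 20 + 1))
  expect_identical(simulate_tracks(cfg), simulate_tracks(cfg))
})

test_that("simulated gene sets carry exactly the planted overlap", {
  uni <- sprintf("G%03d", 1:200)
  sets <- simulate_gene_sets(uni, n_a = 40, n_b = 25, n_overlap = 7,
                             seed = 11)
  expect_length(sets$set_a, 40)
  expect_length(sets$set_b, 25)
  expect_length(intersect(sets$set_a, sets$set_b), 7)
  expect_error(simulate_gene_sets(uni, 40, 25, 30, seed = 1), "n_overlap")
})
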