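## End-to-end orchestration: plates -> IC50 profiles -> expression screen ->
## gene-set overlap -> motility, with every warning routed into both a
## plain-text log and the JSON summaries, and atomic, timestamp-free outputs
## so repeated runs are byte-identical.

## Runs an expression, capturing warnings/messages into a character log
## without suppressing errors.
collect_conditions <- function(expr) {
  log <- character(0)
  value <- withCallingHandlers(
    expr,
    warning = function(w) {
      log <<- c(log, paste0("warning: ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      log <<- c(log, paste0("note: ", trimws(conditionMessage(m))))
      invokeRestart("muffleMessage")
    })
  list(value = value, log = log)
}

#' Assemble a dose-response series from a plate table
#'
#' Extracts one (cell line, compound, timepoint) series from a plate table:
#' the background is the mean blank-well intensity, the reference intensity
#' is the mean untreated intensity minus background, and the replicate x
#' dose matrix collects the sample and untreated wells.
#'
#' @param plate Plate data frame (see [read_plate_csv()]).
#' @param cell_line,compound,timepoint_h Series selectors.
#' @return A [dose_response_series()].
#' @export
series_from_plate <- function(plate, cell_line, compound, timepoint_h) {
  sel <- plate$cell_line == cell_line & plate$compound == compound &
    plate$timepoint_h == timepoint_h
  sub <- plate[sel, , drop = FALSE]
  if (!nrow(sub)) {
    stop(sprintf("no plate rows for (%s, %s, %s h)", cell_line, compound,
                 timepoint_h), call. = FALSE)
  }
  blanks <- sub$intensity[sub$well_type == "blank"]
  background <- if (length(blanks)) mean(blanks) else 0
  wells <- sub[sub$well_type != "blank", , drop = FALSE]
  doses <- sort(unique(wells$dose_uM))
  reps <- sort(unique(wells$replicate))
  raw <- matrix(NA_real_, length(reps), length(doses))
  for (i in seq_along(reps)) {
    for (j in seq_along(doses)) {
      v <- wells$intensity[wells$replicate == reps[i] &
                             wells$dose_uM == doses[j]]
      if (length(v) != 1L) {
        stop(sprintf(
          "plate is not a complete replicate x dose grid at (%s, %s, %s h), replicate %s, dose %g",
          cell_line, compound, timepoint_h, reps[i], doses[j]),
          call. = FALSE)
      }
      raw[i, j] <- v
    }
  }
  untreated <- wells$intensity[wells$well_type == "untreated"]
  if (!length(untreated)) {
    stop(sprintf("no untreated wells for (%s, %s, %s h)", cell_line,
                 compound, timepoint_h), call. = FALSE)
  }
  dose_response_series(
    cell_line = cell_line, compound = compound, timepoint_h = timepoint_h,
    doses = doses, raw_intensities = raw, background = background,
    reference_intensity = mean(untreated) - background)
}

#' Fit IC50 profiles for every compound and timepoint in a plate table
#'
#' For each (cell line, compound, timepoint) series: normalize to percent of
#' untreated, fit the Hill sigmoid, and per (compound, timepoint) build the
#' normalized/ranked IC50 profile; per compound, additionally the
#' timepoint-averaged profile. Writes `fits.tsv`, one
#' `profile_<compound>_<tp>h.tsv` per timepoint, a
#' `profile_<compound>_avg.tsv`, an `ic50.json` summary and `ic50_log.txt`.
#'
#' @param plate Plate data frame or path to a plate CSV.
#' @param out_dir Output directory (created if missing).
#' @param pooled,floor Passed to [fit_hill()] / [normalize_viability()].
#' @return Invisibly, a list with `fits` (data frame), `profiles` (nested
#'   list: compound -> timepoint label -> `ic50_profile`), `avg_profiles`
#'   (compound -> `ic50_profile`), `files`, `log`.
#' @export
run_ic50 <- function(plate, out_dir, pooled = FALSE, floor = 1e-6) {
  if (is.character(plate)) plate <- read_plate_csv(plate)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  run <- collect_conditions({
    fit_rows <- list(); profiles <- list(); avg_profiles <- list()
    for (cpd in unique(plate$compound)) {
      profiles[[cpd]] <- list()
      tps <- sort(unique(plate$timepoint_h[plate$compound == cpd]))
      for (tp in tps) {
        fits <- list()
        lines <- unique(plate$cell_line[plate$compound == cpd &
                                          plate$timepoint_h == tp])
        for (cl in lines) {
          series <- series_from_plate(plate, cl, cpd, tp)
          fit <- fit_hill(normalize_viability(series, floor = floor),
                          pooled = pooled)
          fits[[cl]] <- fit
          fit_rows[[length(fit_rows) + 1L]] <- data.frame(
            cell_line = cl, compound = cpd, timepoint_h = tp,
            min = fit$min, max = fit$max, ic50_uM = fit$ic50,
            hill = fit$hill, rss = fit$rss, converged = fit$converged,
            stringsAsFactors = FALSE)
        }
        profiles[[cpd]][[paste0(tp, "h")]] <- build_profile(fits)
      }
      avg_profiles[[cpd]] <- aggregate_timepoints(unname(profiles[[cpd]]))
    }
    list(fits = do.call(rbind, fit_rows), profiles = profiles,
         avg_profiles = avg_profiles)
  })

  res <- run$value
  files <- c(fits = file.path(out_dir, "fits.tsv"))
  write_tsv_atomic(res$fits, files[["fits"]])
  for (cpd in names(res$profiles)) {
    for (tp in names(res$profiles[[cpd]])) {
      f <- file.path(out_dir, sprintf("profile_%s_%s.tsv", cpd, tp))
      write_tsv_atomic(as.data.frame(res$profiles[[cpd]][[tp]]), f)
      files[[sprintf("profile_%s_%s", cpd, tp)]] <- f
    }
    f <- file.path(out_dir, sprintf("profile_%s_avg.tsv", cpd))
    write_tsv_atomic(as.data.frame(res$avg_profiles[[cpd]]), f)
    files[[sprintf("profile_%s_avg", cpd)]] <- f
  }
  summary <- list(
    step = "ic50",
    n_fits = nrow(res$fits), n_converged = sum(res$fits$converged),
    compounds = names(res$profiles), warnings = as.list(run$log))
  files[["json"]] <- file.path(out_dir, "ic50.json")
  write_json_atomic(summary, files[["json"]])
  files[["log"]] <- file.path(out_dir, "ic50_log.txt")
  write_atomic(function(tmp) writeLines(run$log, tmp), files[["log"]])

  invisible(c(res, list(files = files, log = run$log)))
}

#' Screen an expression matrix against an IC50 profile and test overlaps
#'
#' Applies the detection filter, runs [genome_screen()] against the profile,
#' and tests the resulting positive set against each supplied reference gene
#' set with [overlap_test()] (universe = the detection-filtered transcript
#' ids unless `universe` is given). Writes `correlations.tsv` and a
#' `screen.json` summary carrying the screen parameters, selected gene
#' lists, overlap results (N, K, n, k, p) and every warning, plus
#' `screen_log.txt`.
#'
#' @param x An [expression_matrix()] or path to an expression TSV.
#' @param profile An `ic50_profile` or path to a profile TSV written by
#'   [run_ic50()].
#' @param reference_sets Named list of character vectors or gene-set file
#'   paths (may be empty).
#' @param out_dir Output directory.
#' @param alpha,sidedness,method,p_adjust,exact_cap See [genome_screen()].
#' @param accepted Detection calls accepted by [filter_by_detection()].
#' @param universe Optional character vector or file overriding the overlap
#'   universe.
#' @return Invisibly, a list with `screen` (the [genome_screen()] output),
#'   `overlaps` (named list of `overlap_result`), `files`, `log`.
#' @export
run_screen <- function(x, profile, reference_sets = list(), out_dir,
                       alpha = 0.05, sidedness = "one_sided",
                       method = "spearman", p_adjust = "none",
                       exact_cap = 8, accepted = c("P", "M"),
                       universe = NULL) {
  if (is.character(x)) x <- read_expression_tsv(x)
  if (is.character(profile)) {
    tab <- utils::read.delim(profile, stringsAsFactors = FALSE)
    profile <- structure(tab, class = c("ic50_profile", "data.frame"))
  }
  if (length(reference_sets)) {
    reference_sets <- lapply(reference_sets, function(s) {
      if (is.character(s) && length(s) == 1L && file.exists(s)) {
        read_gene_set(s)
      } else as.character(s)
    })
    if (is.null(names(reference_sets))) {
      names(reference_sets) <- paste0("set", seq_along(reference_sets))
    }
    if (any(!lengths(reference_sets))) {
      stop("empty reference gene set supplied", call. = FALSE)
    }
  }
  if (is.character(universe) && length(universe) == 1L &&
      file.exists(universe)) {
    universe <- read_gene_set(universe)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  run <- collect_conditions({
    filtered <- filter_by_detection(x, accepted = accepted)
    sc <- genome_screen(filtered, profile, alpha = alpha,
                        sidedness = sidedness, method = method,
                        p_adjust = p_adjust, exact_cap = exact_cap)
    sc$result$n_input <- nrow(x$values)
    uni <- if (is.null(universe)) rownames(filtered$values) else universe
    overlaps <- list()
    for (nm in names(reference_sets)) {
      overlaps[[nm]] <- overlap_test(sc$result$positive_set,
                                     reference_sets[[nm]], uni)
    }
    list(screen = sc, overlaps = overlaps)
  })
  res <- run$value

  files <- c(correlations = file.path(out_dir, "correlations.tsv"))
  write_tsv_atomic(res$screen$correlations, files[["correlations"]])
  summary <- list(
    step = "screen",
    params = list(alpha = alpha, sidedness = sidedness, method = method,
                  p_adjust = p_adjust, accepted = paste(accepted,
                                                        collapse = ",")),
    n_input = res$screen$result$n_input,
    n_filtered = res$screen$result$n_filtered,
    positive_set = as.list(res$screen$result$positive_set),
    negative_set = as.list(res$screen$result$negative_set),
    overlaps = lapply(res$overlaps, function(o) {
      list(N = o$universe_size, K = o$set_a_size, n = o$set_b_size,
           k = o$overlap, overlap_fraction_of_b = o$overlap_fraction_of_b,
           p_upper = o$p_upper, genes = as.list(o$overlap_genes))
    }),
    warnings = as.list(run$log))
  files[["json"]] <- file.path(out_dir, "screen.json")
  write_json_atomic(summary, files[["json"]])
  files[["log"]] <- file.path(out_dir, "screen_log.txt")
  write_atomic(function(tmp) writeLines(run$log, tmp), files[["log"]])

  invisible(c(res, list(files = files, log = run$log)))
}

#' Summarize migration statistics from a track table
#'
#' Computes per-track speed and persistence and per-condition summaries,
#' writing `tracks_per_track.tsv`, `tracks_per_condition.tsv` and
#' `motility.json`.
#'
#' @param tracks Track data frame or path to a track CSV.
#' @param out_dir Output directory.
#' @param t_max Maximal possible tracking time in minutes.
#' @param condition_map Optional data frame (`track_id`, `condition`)
#'   assigning tracks to conditions; unmapped tracks go to `"all"`.
#' @return Invisibly, the [summarize_condition()] result plus `files`.
#' @export
run_motility <- function(tracks, out_dir, t_max = 2880,
                         condition_map = NULL) {
  if (is.character(tracks)) tracks <- read_tracks_csv(tracks)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tl <- tracks_from_table(tracks, t_max = t_max)
  grouping <- rep("all", length(tl))
  if (!is.null(condition_map)) {
    idx <- match(names(tl), condition_map$track_id)
    grouping[!is.na(idx)] <- condition_map$condition[idx[!is.na(idx)]]
  }
  res <- summarize_condition(tl, grouping)
  files <- c(per_track = file.path(out_dir, "tracks_per_track.tsv"),
             per_condition = file.path(out_dir, "tracks_per_condition.tsv"),
             json = file.path(out_dir, "motility.json"))
  write_tsv_atomic(res$per_track, files[["per_track"]])
  write_tsv_atomic(res$per_condition, files[["per_condition"]])
  write_json_atomic(list(step = "motility", t_max = t_max,
                         n_tracks = nrow(res$per_track),
                         per_condition = res$per_condition),
                    files[["json"]])
  invisible(c(res, list(files = files)))
}

## Default study conditions for the synthetic end-to-end fixture: a
## five-line NSCLC-style panel measured at 24/48/72 h in triplicate. One
## compound has a flat susceptibility pattern with a single resistant
## outlier; the reference compound grades monotonically across the panel.
default_panel <- function() {
  list(
    cell_lines = c("H1650", "H1975", "A549", "H838", "H2030"),
    sil = list(H1650 = c(min = 10, max = 100, ic50 = 48, hill = 1.6),
               H1975 = c(min = 12, max = 100, ic50 = 55, hill = 1.4),
               A549 = c(min = 8, max = 100, ic50 = 62, hill = 1.8),
               H838 = c(min = 15, max = 100, ic50 = 170, hill = 1.3),
               H2030 = c(min = 10, max = 100, ic50 = 52, hill = 1.5)),
    wfa = list(H1650 = c(min = 5, max = 100, ic50 = 0.6, hill = 1.5),
               H1975 = c(min = 6, max = 100, ic50 = 1.0, hill = 1.4),
               A549 = c(min = 5, max = 100, ic50 = 1.7, hill = 1.6),
               H838 = c(min = 7, max = 100, ic50 = 2.6, hill = 1.3),
               H2030 = c(min = 5, max = 100, ic50 = 4.0, hill = 1.5)))
}

#' Run the full synthetic-study pipeline
#'
#' Generates the complete synthetic study under a single seed — dose-response
#' plates for a test compound and a reference compound on a five-line panel,
#' an expression matrix whose planted transcripts follow the test compound's
#' true normalized IC50 signature, a reference gene set with a planted
#' overlap, and cell tracks — then executes IC50 fitting, the correlation
#' screen, the overlap test and the motility summary, and writes a
#' `summary.json` tying the artifacts together. All inputs land under
#' `<out_dir>/inputs`, outputs under `<out_dir>`. Given the same seed the
#' whole output tree is byte-identical across runs.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed; the per-generator seeds are derived from
#'   it.
#' @param n_transcripts Synthetic transcript-universe size (default 2000;
#'   planted: 60 positive, 40 negative).
#' @param alpha,sidedness,method See [genome_screen()].
#' @param noise_sd Plate noise (fluorescence units; default 2% of the
#'   untreated reference intensity).
#' @return Invisibly, a list with the step results and `files`.
#' @export
run_all <- function(out_dir, seed = 1L, n_transcripts = 2000,
                    alpha = 0.05, sidedness = "one_sided",
                    method = "spearman", noise_sd = 200) {
  seed <- check_count(seed, "seed")
  dir.create(file.path(out_dir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  panel <- default_panel()

  ## Inputs -----------------------------------------------------------------
  plates <- rbind(
    simulate_plate(plate_sim_config(
      cell_lines = panel$cell_lines, true_hill_params = panel$sil,
      noise_sd = noise_sd, compound = "SIL", seed = seed)),
    simulate_plate(plate_sim_config(
      cell_lines = panel$cell_lines, true_hill_params = panel$wfa,
      dose_ladder = c(0, 0.125 * 2^(0:6)), noise_sd = noise_sd,
      compound = "WFA", seed = seed + 1L)))
  plate_file <- file.path(out_dir, "inputs", "plate.csv")
  write_plate_csv(plates, plate_file)

  sil_ic50 <- vapply(panel$sil, `[[`, numeric(1), "ic50")
  signature <- (sil_ic50 - min(sil_ic50)) / (max(sil_ic50) - min(sil_ic50))
  expr <- simulate_expression(expression_sim_config(
    n_transcripts = n_transcripts, cell_lines = panel$cell_lines,
    planted_signature = unname(signature),
    n_planted_positive = 60, n_planted_negative = 40,
    pattern_noise_sd = 0.05, frac_absent_calls = 0.05, seed = seed + 2L))
  expr_file <- file.path(out_dir, "inputs", "expression.tsv")
  write_expression_tsv(expr$matrix, expr_file)
  truth_file <- file.path(out_dir, "inputs", "truth.tsv")
  write_tsv_atomic(expr$truth, truth_file)

  planted_pos <- expr$truth$transcript_id[expr$truth$planted == "positive"]
  other <- setdiff(rownames(expr$matrix$values), expr$truth$transcript_id)
  reference_set <- c(planted_pos[seq_len(12)],
                     withr::with_seed(seed + 3L, sample(other, 78)))
  refset_file <- file.path(out_dir, "inputs", "reference_set.txt")
  write_gene_set(reference_set, refset_file)

  tracks <- simulate_tracks(track_sim_config(
    n_cells = 100, speed_mean = 0.3, turning_persistence = 0.6,
    dropout_prob = 0.01, seed = seed + 4L))
  tracks_file <- file.path(out_dir, "inputs", "tracks.csv")
  write_tracks_csv(tracks, tracks_file)

  ## Analysis ---------------------------------------------------------------
  ic50 <- run_ic50(plate_file, out_dir)
  screen <- run_screen(expr_file, ic50$avg_profiles[["SIL"]],
                       reference_sets = list(reference = refset_file),
                       out_dir = out_dir, alpha = alpha,
                       sidedness = sidedness, method = method)
  motility <- run_motility(tracks_file, out_dir)

  summary <- list(
    seed = seed,
    params = list(n_transcripts = n_transcripts, alpha = alpha,
                  sidedness = sidedness, method = method,
                  noise_sd = noise_sd),
    inputs = list(plate = basename(plate_file),
                  expression = basename(expr_file),
                  truth = basename(truth_file),
                  reference_set = basename(refset_file),
                  tracks = basename(tracks_file)),
    ic50 = list(n_fits = nrow(ic50$fits),
                n_converged = sum(ic50$fits$converged)),
    screen = list(n_positive = length(screen$screen$result$positive_set),
                  n_negative = length(screen$screen$result$negative_set),
                  overlap_k = screen$overlaps$reference$overlap,
                  overlap_p = screen$overlaps$reference$p_upper),
    motility = list(n_tracks = nrow(motility$per_track)),
    warnings = as.list(c(ic50$log, screen$log)))
  summary_file <- file.path(out_dir, "summary.json")
  write_json_atomic(summary, summary_file)

  invisible(list(ic50 = ic50, screen = screen, motility = motility,
                 truth = expr$truth,
                 files = c(plate = plate_file, expression = expr_file,
                           truth = truth_file, reference_set = refset_file,
                           tracks = tracks_file, summary = summary_file)))
}
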