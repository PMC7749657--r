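## Seeded generators for every input the pipeline consumes: plate-reader
## dose-response tables, planted-signal expression matrices with detection
## calls, gene sets, and persistent-random-walk cell tracks. All generators
## are deterministic given their config seed and leave the caller's RNG
## state untouched.

#' Configuration for the plate-reader simulator
#'
#' Ground truth for each cell line is a four-parameter Hill curve (see
#' [hill_function()]); the simulator emits raw fluorescence intensities on
#' the plate scale: `background + reference x anI(dose)/100 + noise`.
#'
#' @param cell_lines Character vector of line labels.
#' @param true_hill_params Named list (one entry per cell line) of numeric
#'   vectors `c(min=, max=, ic50=, hill=)` — plateaus in percent of
#'   untreated, IC50 in uM, Hill coefficient unitless.
#' @param dose_ladder Doses in uM including 0 for the untreated wells;
#'   strictly increasing. Default: 0 plus a two-fold ladder 6.25-400 uM.
#' @param n_replicates Wells per (line, dose), `>= 1` (default 3, matching a
#'   triplicate assay).
#' @param noise_sd Additive Gaussian noise sd on raw intensity (fluorescence
#'   units), or relative sd when `noise_model = "multiplicative"`.
#' @param background_level Blank-well intensity (fluorescence units).
#' @param reference_intensity Untreated signal scale above background
#'   (fluorescence units).
#' @param noise_model `"additive"` (default) or `"multiplicative"`
#'   (intensity scaled by `1 + N(0, noise_sd)`).
#' @param compound Compound label stamped on the rows (default `"CPD"`).
#' @param timepoints_h Exposure durations in hours (default `c(24, 48, 72)`).
#' @param seed Integer RNG seed.
#' @return Object of class `plate_sim_config`.
#' @export
plate_sim_config <- function(cell_lines, true_hill_params,
                             dose_ladder = c(0, 6.25 * 2^(0:6)),
                             n_replicates = 3, noise_sd = 0,
                             background_level = 100,
                             reference_intensity = 10000,
                             noise_model = c("additive", "multiplicative"),
                             compound = "CPD", timepoints_h = c(24, 48, 72),
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (!is.character(cell_lines) || !length(cell_lines) ||
      anyDuplicated(cell_lines)) {
    stop_field("cell_lines", "must be unique non-empty labels")
  }
  if (!is.list(true_hill_params) ||
      !setequal(names(true_hill_params), cell_lines)) {
    stop_field("true_hill_params", "must be a list named by cell line")
  }
  for (cl in cell_lines) {
    p <- true_hill_params[[cl]]
    if (!is.numeric(p) || !all(c("min", "max", "ic50", "hill") %in% names(p))) {
      stop_field("true_hill_params",
                 sprintf("entry '%s' needs named min, max, ic50, hill", cl))
    }
    if (p[["ic50"]] <= 0) stop_field("true_hill_params",
                                     sprintf("'%s': ic50 must be > 0", cl))
    if (p[["hill"]] <= 0) stop_field("true_hill_params",
                                     sprintf("'%s': hill must be > 0", cl))
    if (p[["min"]] < 0 || p[["min"]] >= p[["max"]]) {
      stop_field("true_hill_params",
                 sprintf("'%s': need 0 <= min < max", cl))
    }
  }
  check_doses(dose_ladder, "dose_ladder")
  n_replicates <- check_count(n_replicates, "n_replicates", lower = 1L)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(background_level, "background_level", lower = 0)
  check_scalar_number(reference_intensity, "reference_intensity", lower = 0,
                      strict_lower = TRUE)
  if (!is.numeric(timepoints_h) || !length(timepoints_h) ||
      any(timepoints_h <= 0)) {
    stop_field("timepoints_h", "must be positive durations in hours")
  }
  seed <- check_count(seed, "seed")
  structure(list(cell_lines = cell_lines,
                 true_hill_params = true_hill_params[cell_lines],
                 dose_ladder = dose_ladder, n_replicates = n_replicates,
                 noise_sd = noise_sd, background_level = background_level,
                 reference_intensity = reference_intensity,
                 noise_model = noise_model, compound = compound,
                 timepoints_h = timepoints_h, seed = seed),
            class = "plate_sim_config")
}

#' Simulate a plate-reader viability table
#'
#' Generates one raw-intensity row per well. Sample wells at dose `D` read
#' `background + reference x anI(D)/100 + noise` with `anI` the line's true
#' Hill curve; wells at dose 0 are the untreated reference (`well_type`
#' `"untreated"`); blank wells carry background plus noise. Deterministic
#' given `config$seed`.
#'
#' @param config A [plate_sim_config()].
#' @return Data frame with columns `cell_line`, `compound`, `timepoint_h`,
#'   `dose_uM`, `replicate`, `well_type` (`"sample"`, `"untreated"`,
#'   `"blank"`) and `intensity`.
#' @export
simulate_plate <- function(config) {
  stopifnot(inherits(config, "plate_sim_config"))
  withr::with_seed(config$seed, {
    rows <- list()
    for (tp in config$timepoints_h) {
      for (cl in config$cell_lines) {
        p <- config$true_hill_params[[cl]]
        anI <- hill_function(config$dose_ladder, p[["min"]], p[["max"]],
                             p[["ic50"]], p[["hill"]])
        for (r in seq_len(config$n_replicates)) {
          signal <- config$background_level +
            config$reference_intensity * anI / 100
          intensity <- apply_noise(signal, config$noise_sd,
                                   config$noise_model)
          rows[[length(rows) + 1L]] <- data.frame(
            cell_line = cl, compound = config$compound, timepoint_h = tp,
            dose_uM = config$dose_ladder, replicate = r,
            well_type = ifelse(config$dose_ladder == 0, "untreated", "sample"),
            intensity = intensity, stringsAsFactors = FALSE)
        }
        ## One blank well per (line, timepoint, replicate): background only.
        blank <- apply_noise(rep(config$background_level,
                                 config$n_replicates),
                             config$noise_sd, config$noise_model)
        rows[[length(rows) + 1L]] <- data.frame(
          cell_line = cl, compound = config$compound, timepoint_h = tp,
          dose_uM = NA_real_, replicate = seq_len(config$n_replicates),
          well_type = "blank", intensity = blank, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

## Plate readers report non-negative fluorescence; noisy values are clipped
## at zero.
apply_noise <- function(signal, noise_sd, noise_model) {
  if (noise_sd == 0) return(signal)
  eps <- stats::rnorm(length(signal), 0, noise_sd)
  pmax(if (noise_model == "additive") signal + eps else signal * (1 + eps), 0)
}

#' Configuration for the planted-signal expression simulator
#'
#' Emulates a transcript x cell-line microarray matrix with P/M/A detection
#' calls in which a known subset of transcripts carries a cross-line pattern
#' rank-concordant (or anti-concordant) with a planted susceptibility
#' signature.
#'
#' @param n_transcripts Number of transcripts (default 22277, the size of a
#'   typical single-array transcript universe).
#' @param cell_lines Cell-line labels (default `LINE1..LINE5`).
#' @param planted_signature Per-line susceptibility values the planted
#'   patterns follow; distinct values required. Default `seq(0, 1)` over the
#'   lines.
#' @param n_planted_positive,n_planted_negative Counts of transcripts whose
#'   expression pattern is concordant / anti-concordant with the signature.
#' @param pattern_noise_sd Gaussian sd perturbing planted patterns (on the
#'   simulated log-intensity scale, whose typical biological spread here is
#'   1 unit).
#' @param frac_absent_calls Probability any transcript x line cell is called
#'   `"A"`; remaining calls are split P/M (85/15).
#' @param null_guard_alpha Non-planted transcripts are redrawn until their
#'   exact one-sided p against the signature exceeds this level in both
#'   directions, so the planted truth table is unambiguous at the screen's
#'   operating threshold (default 0.05; set `NULL` to disable and obtain
#'   fully exchangeable null rows).
#' @param seed Integer RNG seed.
#' @return Object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_transcripts = 22277,
                                  cell_lines = paste0("LINE", 1:5),
                                  planted_signature = NULL,
                                  n_planted_positive = 0,
                                  n_planted_negative = 0,
                                  pattern_noise_sd = 0,
                                  frac_absent_calls = 0,
                                  null_guard_alpha = 0.05,
                                  seed = 1L) {
  n_transcripts <- check_count(n_transcripts, "n_transcripts", lower = 1L)
  if (!is.character(cell_lines) || length(cell_lines) < 2L ||
      anyDuplicated(cell_lines)) {
    stop_field("cell_lines", "must be >= 2 unique labels")
  }
  if (is.null(planted_signature)) {
    planted_signature <- seq(0, 1, length.out = length(cell_lines))
  }
  if (!is.numeric(planted_signature) ||
      length(planted_signature) != length(cell_lines)) {
    stop_field("planted_signature", "must have one value per cell line")
  }
  if (anyDuplicated(planted_signature)) {
    stop_field("planted_signature", "values must be distinct")
  }
  n_planted_positive <- check_count(n_planted_positive, "n_planted_positive")
  n_planted_negative <- check_count(n_planted_negative, "n_planted_negative")
  if (n_planted_positive + n_planted_negative > n_transcripts) {
    stop_field("n_planted_positive",
               "planted counts exceed n_transcripts")
  }
  check_scalar_number(pattern_noise_sd, "pattern_noise_sd", lower = 0)
  check_scalar_number(frac_absent_calls, "frac_absent_calls", lower = 0,
                      upper = 1, strict_upper = TRUE)
  if (!is.null(null_guard_alpha)) {
    check_scalar_number(null_guard_alpha, "null_guard_alpha", lower = 0,
                        upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  }
  seed <- check_count(seed, "seed")
  structure(list(n_transcripts = n_transcripts, cell_lines = cell_lines,
                 planted_signature = planted_signature,
                 n_planted_positive = n_planted_positive,
                 n_planted_negative = n_planted_negative,
                 pattern_noise_sd = pattern_noise_sd,
                 frac_absent_calls = frac_absent_calls,
                 null_guard_alpha = null_guard_alpha, seed = seed),
            class = "expression_sim_config")
}

#' Simulate an expression matrix with a planted IC50-correlated subset
#'
#' Planted-positive transcripts get a cross-line pattern that is a strictly
#' increasing affine transform of the planted signature (Spearman rho = +1
#' before noise); planted-negative transcripts the reverse; all other
#' transcripts are pattern-free. When `null_guard_alpha` is set, pattern-free
#' rows are rejection-sampled so none of them reaches exact one-sided
#' significance against the signature — the returned truth table is then the
#' unique correct answer for a screen at that level. Detection calls are
#' drawn independently per cell.
#'
#' @param config An [expression_sim_config()].
#' @return List with `matrix` (an [expression_matrix()]), `truth` (data
#'   frame `transcript_id`, `planted` in `"positive"`/`"negative"`) and
#'   `signature` (named planted signature).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  m <- config$n_transcripts
  lines <- config$cell_lines
  n <- length(lines)
  sig <- config$planted_signature
  ids <- sprintf("TX%06d", seq_len(m))
  n_pos <- config$n_planted_positive
  n_neg <- config$n_planted_negative

  withr::with_seed(config$seed, {
    values <- matrix(NA_real_, m, n, dimnames = list(ids, lines))
    sig_std <- as.vector(scale(sig))  # unit-variance pattern template

    planted_rows <- function(k, direction) {
      if (k == 0L) return(NULL)
      ## Strictly increasing affine map of the signature per transcript:
      ## intercept = baseline abundance, positive slope = pattern strength.
      a <- stats::rnorm(k, mean = 7, sd = 1.5)
      b <- stats::runif(k, 0.5, 2)
      base <- outer(direction * b, sig_std) + a
      base + matrix(stats::rnorm(k * n, 0, config$pattern_noise_sd), k, n)
    }
    if (n_pos > 0L) values[seq_len(n_pos), ] <- planted_rows(n_pos, +1)
    if (n_neg > 0L) {
      values[n_pos + seq_len(n_neg), ] <- planted_rows(n_neg, -1)
    }

    n_null <- m - n_pos - n_neg
    if (n_null > 0L) {
      null_row <- function() stats::rnorm(n, mean = 7, sd = 1.5)
      guard <- config$null_guard_alpha
      rows <- matrix(stats::rnorm(n_null * n, 7, 1.5), n_null, n)
      if (!is.null(guard) && n <= 8L) {
        ## Reject null rows whose exact one-sided p (either direction)
        ## against the signature would reach the guard level.
        ry_perm <- permuted_rank_matrix(sig)
        bad_row <- function(v) {
          if (stats::sd(v) == 0) return(FALSE)
          rv <- rank(v)
          rho_null <- null_correlations(rv, ry_perm)
          rho <- stats::cor(rv, rank(sig))
          mean(rho_null >= rho - P_EPS) <= guard ||
            mean(rho_null <= rho + P_EPS) <= guard
        }
        for (i in seq_len(n_null)) {
          tries <- 0L
          while (bad_row(rows[i, ]) && tries < 1000L) {
            rows[i, ] <- null_row()
            tries <- tries + 1L
          }
        }
      }
      values[n_pos + n_neg + seq_len(n_null), ] <- rows
    }

    fa <- config$frac_absent_calls
    calls <- matrix(
      sample(c("A", "P", "M"), m * n, replace = TRUE,
             prob = c(fa, (1 - fa) * 0.85, (1 - fa) * 0.15)),
      m, n, dimnames = list(ids, lines))

    truth <- data.frame(
      transcript_id = ids[seq_len(n_pos + n_neg)],
      planted = rep(c("positive", "negative"), c(n_pos, n_neg)),
      stringsAsFactors = FALSE)

    list(matrix = expression_matrix(values, calls), truth = truth,
         signature = stats::setNames(sig, lines))
  })
}

#' Configuration for the cell-track simulator
#'
#' Persistent random walk observed at fixed frame intervals, with optional
#' early track termination emulating cells lost by the tracker.
#'
#' @param n_cells Number of tracks.
#' @param frame_interval Minutes between frames (default 20).
#' @param total_time Acquisition duration in minutes (default 2880 = 48 h);
#'   must be a multiple of `frame_interval`.
#' @param speed_mean Mean cell speed in um/min.
#' @param speed_sd Between-cell sd of speed in um/min (default 0: all cells
#'   share `speed_mean`).
#' @param turning_persistence Correlation of successive step directions in
#'   \[0, 1): step headings follow a wrapped-Gaussian turn-angle model with
#'   `E[cos(turn)] = turning_persistence`; 0 = uncorrelated headings,
#'   values near 1 = nearly straight paths.
#' @param dropout_prob Per-frame probability (from the third frame on) that
#'   the track ends early; every track keeps at least 2 points.
#' @param seed Integer RNG seed.
#' @return Object of class `track_sim_config`.
#' @export
track_sim_config <- function(n_cells, frame_interval = 20,
                             total_time = 2880, speed_mean = 0.5,
                             speed_sd = 0, turning_persistence = 0.5,
                             dropout_prob = 0, seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells", lower = 1L)
  check_scalar_number(frame_interval, "frame_interval", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(total_time, "total_time", lower = frame_interval)
  if (abs(total_time / frame_interval -
          round(total_time / frame_interval)) > 1e-9) {
    stop_field("total_time", "must be a multiple of frame_interval")
  }
  check_scalar_number(speed_mean, "speed_mean", lower = 0)
  check_scalar_number(speed_sd, "speed_sd", lower = 0)
  check_scalar_number(turning_persistence, "turning_persistence", lower = 0,
                      upper = 1, strict_upper = TRUE)
  check_scalar_number(dropout_prob, "dropout_prob", lower = 0, upper = 1)
  seed <- check_count(seed, "seed")
  structure(list(n_cells = n_cells, frame_interval = frame_interval,
                 total_time = total_time, speed_mean = speed_mean,
                 speed_sd = speed_sd,
                 turning_persistence = turning_persistence,
                 dropout_prob = dropout_prob, seed = seed),
            class = "track_sim_config")
}

#' Simulate persistent-random-walk cell tracks
#'
#' Each cell starts at the origin with a uniform random heading and takes
#' one step per frame; the turn angle between consecutive steps is
#' wrapped-Gaussian with `E[cos(turn)] = turning_persistence` (sd
#' `sqrt(-2 log p)`; uniform headings when `p = 0`). Step length is
#' `speed x frame_interval` with the cell's speed drawn once per track.
#' Tracks may terminate early with per-frame probability `dropout_prob`.
#' Deterministic given `config$seed`.
#'
#' @param config A [track_sim_config()].
#' @return Data frame with columns `track_id`, `frame`, `t_min`, `x_um`,
#'   `y_um`.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "track_sim_config"))
  n_frames <- as.integer(round(config$total_time / config$frame_interval)) + 1L
  p <- config$turning_persistence
  turn_sd <- if (p > 0) sqrt(-2 * log(p)) else NA_real_

  withr::with_seed(config$seed, {
    rows <- vector("list", config$n_cells)
    for (i in seq_len(config$n_cells)) {
      ## Early termination: number of observed frames (>= 2).
      n_obs <- n_frames
      if (config$dropout_prob > 0 && n_frames > 2L) {
        for (f in 3:n_frames) {
          if (stats::runif(1) < config$dropout_prob) { n_obs <- f - 1L; break }
        }
      }
      speed <- max(config$speed_mean +
                     if (config$speed_sd > 0)
                       stats::rnorm(1, 0, config$speed_sd) else 0, 0)
      step <- speed * config$frame_interval
      n_steps <- n_obs - 1L
      heading <- stats::runif(1, 0, 2 * pi)
      turns <- if (is.na(turn_sd)) {
        stats::runif(n_steps, 0, 2 * pi)
      } else {
        stats::rnorm(n_steps, 0, turn_sd)
      }
      headings <- if (is.na(turn_sd)) turns else heading + cumsum(turns)
      x <- c(0, cumsum(step * cos(headings)))
      y <- c(0, cumsum(step * sin(headings)))
      frames <- seq_len(n_obs)
      rows[[i]] <- data.frame(
        track_id = sprintf("cell%04d", i), frame = frames,
        t_min = (frames - 1L) * config$frame_interval,
        x_um = x, y_um = y, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a pair of gene sets with a planted overlap
#'
#' Draws two label sets from a universe such that exactly
#' `n_overlap` labels are shared — a deterministic fixture for the
#' hypergeometric overlap test.
#'
#' @param universe Character vector of labels.
#' @param n_a,n_b Sizes of the two sets.
#' @param n_overlap Planted overlap size, `<= min(n_a, n_b)`.
#' @param seed Integer RNG seed.
#' @return List with `set_a`, `set_b`.
#' @export
simulate_gene_sets <- function(universe, n_a, n_b, n_overlap, seed = 1L) {
  universe <- unique(as.character(universe))
  n_a <- check_count(n_a, "n_a", lower = 1L)
  n_b <- check_count(n_b, "n_b", lower = 1L)
  n_overlap <- check_count(n_overlap, "n_overlap")
  seed <- check_count(seed, "seed")
  if (n_overlap > min(n_a, n_b)) {
    stop_field("n_overlap", "must not exceed min(n_a, n_b)")
  }
  if (n_a + n_b - n_overlap > length(universe)) {
    stop_field("universe", "too small for the requested sets")
  }
  withr::with_seed(seed, {
    picked <- sample(universe, n_a + n_b - n_overlap)
    shared <- picked[seq_len(n_overlap)]
    a_only <- picked[n_overlap + seq_len(n_a - n_overlap)]
    b_only <- picked[n_a + seq_len(n_b - n_overlap)]
    list(set_a = c(shared, a_only), set_b = c(shared, b_only))
  })
}
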