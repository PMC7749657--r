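# Independent oracles, deliberately written on different code paths than the
# package: Heap's algorithm for permutations (the package uses prefix
# recursion) and stats::cor(method = "spearman") for the rank correlation.

# All permutations of the vector v, via Heap's algorithm (the working array
# is shared across recursion levels, as the algorithm requires).
heap_permutations <- function(v) {
  n <- length(v)
  rows <- vector("list", factorial(n))
  i <- 0L
  a <- v
  gen <- function(k) {
    if (k == 1L) {
      i <<- i + 1L
      rows[[i]] <<- a
      return(invisible())
    }
    for (j in seq_len(k - 1L)) {
      gen(k - 1L)
      idx <- if (k %% 2L == 0L) j else 1L
      tmp <- a[idx]; a[idx] <<- a[k]; a[k] <<- tmp
    }
    gen(k - 1L)
  }
  gen(n)
  do.call(rbind, rows)
}

# Exact one-sided (positive) permutation p-value of the Spearman correlation,
# by brute enumeration with cor(method = "spearman").
oracle_spearman_p_pos <- function(x, y) {
  rho <- stats::cor(x, y, method = "spearman")
  perms <- heap_permutations(y)
  rho_null <- apply(perms, 1, function(p) {
    stats::cor(x, p, method = "spearman")
  })
  mean(rho_null >= rho - 1e-8)
}

# Full null distribution of the Spearman rho at a given n (no ties).
oracle_spearman_null <- function(n) {
  perms <- heap_permutations(seq_len(n))
  apply(perms, 1, function(p) stats::cor(seq_len(n), p, method = "spearman"))
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) equally likely draws from a universe with K marked successes.
oracle_hypergeom_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= k)
}

# A small noiseless plate config shared by several tests (max = 100 so the
# untreated-normalized scale matches the true parameters).
toy_panel_params <- function() {
  list(L1 = c(min = 10, max = 100, ic50 = 50, hill = 1.5),
       L2 = c(min = 5,  max = 100, ic50 = 12, hill = 2.2),
       L3 = c(min = 20, max = 100, ic50 = 150, hill = 1.0),
       L4 = c(min = 0,  max = 100, ic50 = 30, hill = 0.8),
       L5 = c(min = 15, max = 100, ic50 = 75, hill = 3.0))
}

# Geometric dose ladder spanning [center/100, 100*center] over n points.
geometric_ladder <- function(center, n = 9) {
  exp(seq(log(center / 100), log(center * 100), length.out = n))
}

# Straight-line cell track along x at the given speed.
straight_track <- function(n_points = 10, dt = 20, speed = 0.25,
                           t_max = (n_points - 1) * dt) {
  t <- seq(0, by = dt, length.out = n_points)
  cell_track("straight", t, x = speed * t, y = rep(0, n_points),
             t_max = t_max)
}
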