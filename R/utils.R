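#' @keywords internal
"_PACKAGE"

## Internal validation helpers. Errors name the offending field so that config
## mistakes surface immediately (the simulators and the pipeline rely on this).

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (strict_lower) {
    if (x <= lower) stop_field(field, sprintf("must be > %g", lower))
  } else if (x < lower) {
    stop_field(field, sprintf("must be >= %g", lower))
  }
  if (strict_upper) {
    if (x >= upper) stop_field(field, sprintf("must be < %g", upper))
  } else if (x > upper) {
    stop_field(field, sprintf("must be <= %g", upper))
  }
  invisible(x)
}

check_count <- function(x, field, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    stop_field(field, "must be a single non-negative integer")
  }
  if (x < lower) stop_field(field, sprintf("must be >= %d", lower))
  invisible(as.integer(x))
}

check_doses <- function(doses, field = "dose_ladder") {
  if (!is.numeric(doses) || length(doses) < 1L || anyNA(doses)) {
    stop_field(field, "must be a numeric vector without missing values")
  }
  if (any(doses < 0)) stop_field(field, "doses must be non-negative")
  if (is.unsorted(doses, strictly = TRUE)) {
    stop_field(field, "doses must be strictly increasing")
  }
  invisible(doses)
}

#' All permutations of 1..n
#'
#' Row-wise enumeration of the n! permutations, used to build the exact
#' permutation null of the rank correlation at small n.
#'
#' @param n Number of elements (n! rows are produced; keep n small).
#' @return Integer matrix with n! rows and n columns.
#' @keywords internal
all_permutations <- function(n) {
  n <- check_count(n, "n", lower = 1L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  blocks <- lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(rep.int(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
  })
  out <- do.call(rbind, blocks)
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

## log(sum(exp(x))) without overflow/underflow; x may contain -Inf.
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Atomic text write: write to a sibling temp file, then rename into place.
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop(sprintf("failed to write '%s' atomically", path), call. = FALSE)
  }
  invisible(path)
}
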