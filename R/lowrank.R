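#' Full singular value decomposition of the primary matrix
#'
#' Deterministic dense SVD; the sign of each left singular vector is fixed by
#' forcing its largest-magnitude entry positive, so factors are reproducible
#' across runs and platforms.
#'
#' @param mat Numeric matrix (diseases x genes).
#' @return Object of class `lowrank_model`: list with `d` (singular values,
#'   nonincreasing), `u`, `v` (orthonormal factors), `row_ids`, `col_ids`.
#' @export
decompose <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L, ncol(mat) >= 1L)
  if (any(!is.finite(mat))) stop("matrix contains non-finite values")
  s <- svd(mat)
  for (j in seq_along(s$d)) {
    i <- which.max(abs(s$u[, j]))
    if (s$u[i, j] < 0) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  structure(list(d = s$d, u = s$u, v = s$v,
                 row_ids = rownames(mat), col_ids = colnames(mat)),
            class = "lowrank_model")
}

#' Select the approximation rank under an energy-retention rule
#'
#' Returns the smallest `r` whose leading singular values hold at least
#' `energy_target` of the total. `mode = "sum"` (default) measures energy as
#' the plain sum of singular values; `mode = "sum_of_squares"` uses the
#' variance-explained convention (squared singular values).
#'
#' @param d Nonincreasing nonnegative singular values.
#' @param energy_target Fraction in (0, 1\], default 0.95.
#' @param mode `"sum"` or `"sum_of_squares"`.
#' @return Integer rank `r >= 1`.
#' @export
select_rank <- function(d, energy_target = 0.95,
                        mode = c("sum", "sum_of_squares")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(d), length(d) >= 1L,
            energy_target > 0, energy_target <= 1)
  if (any(d < -1e-12)) stop("singular values must be nonnegative")
  if (is.unsorted(rev(d))) stop("singular values must be nonincreasing")
  e <- if (mode == "sum") d else d^2
  tot <- sum(e)
  if (tot <= 0) stop("all singular values are zero")
  # tolerance so target 1.0 is met at full length despite rounding
  which(cumsum(e) / tot >= energy_target - 1e-12)[1L]
}

#' Rank-r reconstruction of the decomposed matrix
#'
#' Zeroes all but the leading `r` singular values; by Eckart-Young this is
#' the best rank-r approximation in Frobenius norm.
#'
#' @param model A `lowrank_model` from [decompose()].
#' @param r Rank, `1 <= r <= length(model$d)`.
#' @return Dense matrix with the original dimnames.
#' @export
reconstruct <- function(model, r) {
  stopifnot(inherits(model, "lowrank_model"))
  if (r < 1L || r > length(model$d)) {
    stop("rank r = ", r, " out of range [1, ", length(model$d), "]")
  }
  idx <- seq_len(r)
  out <- model$u[, idx, drop = FALSE] %*%
    (model$d[idx] * t(model$v[, idx, drop = FALSE]))
  dimnames(out) <- list(model$row_ids, model$col_ids)
  out
}

#' Fit a low-rank model with the energy rank rule
#'
#' Convenience wrapper: [decompose()] then [select_rank()], recording the
#' selected rank and achieved energy fraction on the model.
#'
#' @inheritParams decompose
#' @inheritParams select_rank
#' @return `lowrank_model` with extra fields `rank_selected`,
#'   `energy_fraction`, `energy_target`, `energy_mode`.
#' @export
lowrank_fit <- function(mat, energy_target = 0.95,
                        mode = c("sum", "sum_of_squares")) {
  mode <- match.arg(mode)
  model <- decompose(mat)
  r <- select_rank(model$d, energy_target, mode)
  e <- if (mode == "sum") model$d else model$d^2
  model$rank_selected <- r
  model$energy_fraction <- sum(e[seq_len(r)]) / sum(e)
  model$energy_target <- energy_target
  model$energy_mode <- mode
  model
}

#' @export
print.lowrank_model <- function(x, ...) {
  cat("lowrank_model:", length(x$d), "singular values")
  if (!is.null(x$rank_selected)) {
    cat("; rank", x$rank_selected, sprintf("(%.1f%% %s energy)",
        100 * x$energy_fraction, x$energy_mode))
  }
  cat("\n")
  invisible(x)
}
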