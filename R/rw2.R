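#' Second-order random-walk quadratic form
#'
#' The RW2 smoothness prior penalises curvature: its log-density kernel is
#' proportional to minus half the sum of squared second differences of the
#' sequence. Linear sequences are annihilated (the kernel is zero on them).
#'
#' @param u Numeric vector of length at least 3 (values on the cohort grid).
#' @return `sum(diff(u, differences = 2)^2)`.
#' @export
#' @examples
#' rw2_quadratic_form(c(1, 2, 3, 4)) # 0 — linear sequences are free
#' rw2_quadratic_form(c(0, 1, 4, 9)) # 8
rw2_quadratic_form <- function(u) {
  if (length(u) < 3) stop("RW2 quadratic form needs length >= 3")
  sum(diff(u, differences = 2)^2)
}

#' RW2 structure matrix
#'
#' The matrix K = D'D, with D the second-difference operator, so that
#' `rw2_quadratic_form(u) == t(u) %*% K %*% u`. K has rank `length - 2`;
#' its null space is spanned by constant and linear sequences.
#'
#' @param k Grid length (>= 3).
#' @return A `k x k` matrix.
#' @export
rw2_structure_matrix <- function(k) {
  if (k < 3) stop("RW2 structure matrix needs k >= 3")
  D <- diff(diag(k), differences = 2)
  crossprod(D)
}

#' Project a grid vector onto the RW2 constraint space
#'
#' The non-linear component is identified alongside explicit intercept and
#' slope terms by the double linear constraint: sum zero and zero linear
#' moment (orthogonality to constant and linear sequences). This projects
#' onto that space; the projection is idempotent.
#'
#' @param u Numeric vector.
#' @return Vector of the same length with `sum(u) == 0` and
#'   `sum(t * u) == 0` (t centred) to machine precision.
#' @export
constrain_rw2 <- function(u) {
  k <- length(u)
  t_c <- seq_len(k) - (k + 1) / 2
  u <- u - mean(u)
  u - t_c * sum(t_c * u) / sum(t_c^2)
}

# Constraint matrix whose rows span the removed subspace (constant, linear).
rw2_constraint_matrix <- function(k) {
  rbind(rep(1, k), seq_len(k) - (k + 1) / 2)
}

#' Simulate a constrained RW2 vector
#'
#' Draws independent normal second-difference innovations, double-cumulates
#' them into a smooth path, and projects onto the identifiability
#' constraints. Used by the synthetic-truth generator.
#'
#' @param k Grid length.
#' @param innovation_sd Standard deviation of each second difference.
#' @return Constrained vector of length `k`; all zeros when
#'   `innovation_sd = 0`.
#' @export
rw2_simulate <- function(k, innovation_sd) {
  if (innovation_sd <= 0) return(numeric(k))
  eps <- stats::rnorm(k - 2, 0, innovation_sd)
  u <- c(0, 0, cumsum(cumsum(eps)))
  constrain_rw2(u)
}

# Linear interpolation of a grid vector at (possibly fractional) grid
# positions. `pos` is on the index scale: 1..k.
interp_grid <- function(u, pos) {
  k <- length(u)
  if (any(pos < 1 - 1e-9 | pos > k + 1e-9)) stop("position off grid")
  pos <- pmin(pmax(pos, 1), k)
  i0 <- pmin(floor(pos), k - 1)
  w <- pos - i0
  u[i0] * (1 - w) + u[i0 + 1] * w
}
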