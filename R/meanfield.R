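#' Density-dependent effective velocities
#'
#' In the mean-field factorization, the probability that a motor advances
#' exactly `i` sites combines its bare jump rates with the chance that a
#' longer intended jump was truncated by an occupied site:
#' `v4 = R4`, `v3 = R4*rho + R3`, `v2 = (R4 + R3)*rho + R2`,
#' `v1 = (R4 + R3 + R2)*rho + R1`.
#'
#' @param rates a [jump_rates()] object (or numeric `R1..R4`).
#' @param rho bulk density in `[0, 1]`.
#' @return Numeric vector `c(v1, v2, v3, v4)`.
#' @export
effective_velocities <- function(rates, rho) {
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  r <- unclass(rates)
  c(v1 = (r[[4]] + r[[3]] + r[[2]]) * rho + r[[1]],
    v2 = (r[[4]] + r[[3]]) * rho + r[[2]],
    v3 = r[[4]] * rho + r[[3]],
    v4 = r[[4]])
}

#' Mean-field bulk current
#'
#' Evaluates `J(rho) = rho * sum_i i * v_i(rho) * (1 - rho)^i`, the
#' mean-field current of the variable-step process on a ring, with the
#' effective velocities re-evaluated at `rho`.  Vectorized over `rho`.
#'
#' @inheritParams effective_velocities
#' @return Current (particles per bond per MCS).
#' @export
mf_current <- function(rates, rho) {
  vapply(rho, function(x) {
    v <- effective_velocities(rates, x)
    x * sum((1:4) * v * (1 - x)^(1:4))
  }, numeric(1))
}

#' Density maximizing the mean-field current
#'
#' Locates the argmax of [mf_current()] on (0, 1) by a coarse grid scan
#' followed by bracketed golden-section refinement; deterministic, no RNG.
#' This is the bulk density of the maximal-current (MC) phase.
#'
#' @inheritParams effective_velocities
#' @param tol absolute tolerance of the maximizer.
#' @return Density in (0, 1).
#' @examples
#' mf_rho_max(jump_rates(kinetics_params(Satt = 1, Sdet = 0)))  # TASEP: 0.5
#' @export
mf_rho_max <- function(rates, tol = 1e-6) {
  grid <- seq(1e-3, 1 - 1e-3, by = 1e-3)
  J <- mf_current(rates, grid)
  if (max(J) <= 0) stop("degenerate rates: mean-field current is identically 0")
  k <- which.max(J)
  lo <- grid[max(1L, k - 2L)]; hi <- grid[min(length(grid), k + 2L)]
  optimize(function(x) mf_current(rates, x), c(lo, hi),
           maximum = TRUE, tol = tol)$maximum
}

#' Boundary-rate thresholds of the maximal-current phase
#'
#' The MC phase occupies the region `alpha > alpha_star`,
#' `beta > beta_star` with `beta_star = 1 - rho_max` and
#' `alpha_star = rho_max * sum_i i * v_i(rho_max) * (1 - rho_max)^(i-1)`,
#' i.e. the injection rate whose entry-limited density reaches `rho_max`.
#' In the unit-step (TASEP) limit this reduces exactly to
#' `(r/2, 1/2)`.
#'
#' @inheritParams effective_velocities
#' @return List with `alpha_star`, `beta_star` and `rho_max`.
#' @export
mc_thresholds <- function(rates) {
  rmax <- mf_rho_max(rates)
  v <- effective_velocities(rates, rmax)
  alpha_star <- rmax * sum((1:4) * v * (1 - rmax)^(0:3))
  list(alpha_star = unname(alpha_star), beta_star = 1 - rmax, rho_max = rmax)
}

#' Bundle the mean-field description of a parameter set
#'
#' @param params a [kinetics_params()].
#' @param mode rate mode passed to [jump_rates()].
#' @return An object of class `meanfield_model` with elements `rates`,
#'   `rho_max`, `J_max`, `alpha_star`, `beta_star` and the current function
#'   `J(rho)`.
#' @export
meanfield_model <- function(params, mode = "binomial") {
  rates <- jump_rates(params, mode)
  th <- mc_thresholds(rates)
  structure(list(params = params, rates = rates,
                 rho_max = th$rho_max,
                 J_max = mf_current(rates, th$rho_max),
                 alpha_star = th$alpha_star, beta_star = th$beta_star,
                 J = function(rho) mf_current(rates, rho)),
            class = "meanfield_model")
}

#' @export
print.meanfield_model <- function(x, ...) {
  cat("Mean-field model:\n")
  print(x$rates)
  cat(sprintf("rho_max = %.4f  J_max = %.4f\n", x$rho_max, x$J_max))
  cat(sprintf("MC phase for alpha > %.4f and beta > %.4f\n",
              x$alpha_star, x$beta_star))
  invisible(x)
}

#' Stationary phase of the open one-dimensional TASEP
#'
#' Reference phase map of the unit-step totally asymmetric exclusion
#' process with hop rate `r`, injection `alpha` and extraction `beta`:
#' low-density (entry-limited, `rho = alpha/r`), high-density
#' (exit-limited, `rho = 1 - beta`), maximal-current
#' (`rho = 1/2`, `J = r/4` for `alpha > r/2`, `beta > 1/2`), and the
#' first-order coexistence line `beta = alpha/r`.
#'
#' @param alpha,beta boundary rates in `[0, 1]`.
#' @param r bulk hop rate.
#' @param tol half-width of the band around the coexistence line that is
#'   labelled `"coexistence"`.
#' @return List with `phase` (`"LD"`, `"HD"`, `"MC"` or `"coexistence"`),
#'   `rho` and `J`.
#' @export
tasep_phase <- function(alpha, beta, r = 1, tol = 1e-9) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1, r > 0)
  if (alpha > r / 2 && beta > 1 / 2)
    return(list(phase = "MC", rho = 0.5, J = r / 4))
  if (abs(beta - alpha / r) <= tol && alpha < r / 2)
    return(list(phase = "coexistence", rho = NA_real_,
                J = alpha * (1 - alpha / r)))
  if (alpha < beta * r)
    list(phase = "LD", rho = alpha / r, J = alpha * (1 - alpha / r))
  else
    list(phase = "HD", rho = 1 - beta, J = r * beta * (1 - beta))
}
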