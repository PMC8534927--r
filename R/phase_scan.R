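# Phase classification from simulation: the phases are defined by the
# (in)dependence of the bulk density on the boundary rates, so the
# classifier probes each node with perturbed-alpha and perturbed-beta runs
# rather than matching thresholds alone.

#' Default scan geometry
#'
#' Scaled-down geometry used for phase-diagram scans: `Lx = 300`,
#' `Ly` as requested, warmup `100 * Lx` MCS and sampling `200 * Lx` MCS.
#'
#' @param kinetics a [kinetics_params()].
#' @param Lx,Ly lattice size.
#' @param seed engine seed.
#' @param ... passed to [run_config()].
#' @return A `run_config` template (boundary rates are placeholders that
#'   the scan overrides).
#' @export
scan_config <- function(kinetics, Lx = 300, Ly = 4, seed = 1L, ...) {
  run_config(lattice_config(Lx, Ly), kinetics, boundary_rates(0.5, 0.5),
             warmup = 100L * Lx, sample = 200L * Lx, seed = seed, ...)
}

with_boundary <- function(config, alpha, beta, seed_offset = 0L) {
  config$boundary <- boundary_rates(min(alpha, 1), min(beta, 1))
  config$seed <- config$seed + as.integer(seed_offset)
  config
}

run_bulk <- function(config) {
  run <- simulate_run(config)
  prof <- measure_density(run)
  cur <- measure_current(run)
  b <- run$block_bulk
  half <- seq_len(length(b) %/% 2)
  se_half <- function(x) sd(x) / sqrt(length(x))
  stationary <- abs(mean(b[half]) - mean(b[-half])) <=
    2 * sqrt(se_half(b[half])^2 + se_half(b[-half])^2)
  list(bulk = prof$bulk, se = prof$bulk_se, profile = prof,
       J = cur$J, J_se = cur$J_se, stationary = stationary)
}

#' Classify the stationary phase at one boundary-rate point
#'
#' Runs the simulator at `(alpha, beta)` plus probe runs at perturbed
#' boundary rates and labels the point:
#' \describe{
#'   \item{LD}{bulk density tracks the alpha perturbation and is
#'     insensitive to beta.}
#'   \item{HD}{bulk density tracks beta, is insensitive to alpha, and
#'     matches `1 - beta`.}
#'   \item{MC}{insensitive to both probes and matching the mean-field
#'     current maximizer [mf_rho_max()].}
#'   \item{coexistence}{domain-wall profile (low entrance-side and high
#'     exit-side plateau) or sensitivity to both rates.}
#' }
#' Ambiguous evidence yields `"unclassified"`, never a forced label.
#'
#' @param alpha,beta boundary rates.
#' @param config a `run_config` template (see [scan_config()]).
#' @param delta probe perturbation of the boundary rates.
#' @param rho_tol density-match tolerance (plus 3 standard errors).
#' @return An object of class `phase_point`: `alpha`, `beta`, `bulk`,
#'   `bulk_se`, `J`, `J_se`, `label`, and the `evidence` list.
#' @export
classify_phase <- function(alpha, beta, config, delta = 0.05,
                           rho_tol = 0.02) {
  base <- run_bulk(with_boundary(config, alpha, beta))
  da <- if (alpha + delta <= 1) delta else -delta
  db <- if (beta + delta <= 1) delta else -delta
  pa <- run_bulk(with_boundary(config, alpha + da, beta, 1L))
  pb <- run_bulk(with_boundary(config, alpha, beta + db, 2L))

  sens <- function(probe) {
    abs(probe$bulk - base$bulk) > rho_tol / 2 + 2 * (probe$se + base$se)
  }
  alpha_sens <- sens(pa)
  beta_sens <- sens(pb)

  rho <- base$profile$rho
  n <- length(rho)
  left <- mean(rho[seq.int(floor(0.10 * n) + 1, floor(0.30 * n))])
  right <- mean(rho[seq.int(floor(0.70 * n) + 1, floor(0.90 * n))])
  domain_wall <- (right - left) > 0.15

  rho_mc <- mf_rho_max(jump_rates(config$kinetics))
  near_mc <- abs(base$bulk - rho_mc) <= rho_tol + 3 * base$se
  near_hd <- abs(base$bulk - (1 - beta)) <= rho_tol + 3 * base$se

  label <-
    if (!alpha_sens && !beta_sens && near_mc && !domain_wall) "MC"
    else if (domain_wall) "coexistence"
    else if (alpha_sens && !beta_sens) "LD"
    else if (beta_sens && !alpha_sens && near_hd) "HD"
    else if (alpha_sens && beta_sens) "coexistence"
    else "unclassified"

  structure(list(alpha = alpha, beta = beta,
                 bulk = base$bulk, bulk_se = base$se,
                 J = base$J, J_se = base$J_se, label = label,
                 evidence = list(alpha_sensitive = alpha_sens,
                                 beta_sensitive = beta_sens,
                                 domain_wall = domain_wall,
                                 near_mc = near_mc, near_hd = near_hd,
                                 rho_mc = rho_mc,
                                 probe_alpha = pa$bulk, probe_beta = pb$bulk,
                                 stationary = base$stationary)),
            class = "phase_point")
}

#' @export
print.phase_point <- function(x, ...) {
  cat(sprintf("(alpha = %.3g, beta = %.3g): %s, bulk = %.4f +/- %.4f, J = %.4f\n",
              x$alpha, x$beta, x$label, x$bulk, x$bulk_se, x$J))
  invisible(x)
}

#' Locate the first-order LD/HD transition along an alpha sweep
#'
#' Sweeps `alpha` at fixed `beta`, finds the largest bulk-density jump
#' between adjacent sweep points, and refines the bracketing interval by
#' bisection.  Across the line the density is discontinuous while the
#' current changes continuously (the first-order signature).
#'
#' @param config a `run_config` template.
#' @param beta fixed outflux rate.
#' @param alphas increasing injection-rate sweep bracketing the transition.
#' @param refine bisection iterations on the bracketing interval.
#' @param min_jump smallest adjacent-point density jump accepted as a
#'   bracket.
#' @return List: `alpha_c`, `uncertainty` (half the final bracket),
#'   `density_jump` (HD minus LD branch at the bracket), `current_jump`
#'   (absolute), `current_se`, and the sweep `table`.
#' @export
locate_transition <- function(config, beta, alphas, refine = 3,
                              min_jump = 0.1) {
  stopifnot(length(alphas) >= 3, !is.unsorted(alphas))
  eval_pt <- function(a)
    run_bulk(with_boundary(config, a, beta,
                           seed_offset = round(1000 * a)))
  pts <- lapply(alphas, eval_pt)
  bulk <- vapply(pts, `[[`, numeric(1), "bulk")
  jumps <- diff(bulk)
  k <- which.max(jumps)
  if (jumps[k] < min_jump)
    stop("no LD/HD transition bracketed: largest density step ",
         signif(jumps[k], 3), " < ", min_jump,
         " (sweep may lie entirely in one phase)")
  lo <- alphas[k]; hi <- alphas[k + 1]
  lo_pt <- pts[[k]]; hi_pt <- pts[[k + 1]]
  for (i in seq_len(refine)) {
    mid <- (lo + hi) / 2
    mp <- eval_pt(mid)
    if (abs(mp$bulk - lo_pt$bulk) < abs(mp$bulk - hi_pt$bulk)) {
      lo <- mid; lo_pt <- mp
    } else {
      hi <- mid; hi_pt <- mp
    }
  }
  list(alpha_c = (lo + hi) / 2, uncertainty = (hi - lo) / 2,
       density_jump = hi_pt$bulk - lo_pt$bulk,
       current_jump = abs(hi_pt$J - lo_pt$J),
       current_se = sqrt(hi_pt$J_se^2 + lo_pt$J_se^2),
       J_lo = lo_pt$J, J_hi = hi_pt$J,
       table = data.frame(alpha = alphas, bulk = bulk,
                          J = vapply(pts, `[[`, numeric(1), "J")))
}

#' Scan a boundary-rate grid and classify every node
#'
#' Batch driver over an `(alpha, beta)` grid with a shared-seed policy
#' (each node's runs derive their seeds from the template seed and the
#' node's rates).  Node failures are recorded and the scan continues.
#'
#' @param alphas,betas grid values.
#' @param config a `run_config` template.
#' @param ... passed to [classify_phase()].
#' @return Data frame with one row per node: `alpha`, `beta`, `bulk`,
#'   `bulk_se`, `J`, `label`.
#' @export
scan_grid <- function(alphas, betas, config, ...) {
  grid <- expand.grid(alpha = alphas, beta = betas)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    a <- grid$alpha[i]; b <- grid$beta[i]
    node_cfg <- config
    node_cfg$seed <- config$seed + 101L * i
    pt <- tryCatch(classify_phase(a, b, node_cfg, ...),
                   error = function(e) NULL)
    if (is.null(pt))
      data.frame(alpha = a, beta = b, bulk = NA_real_, bulk_se = NA_real_,
                 J = NA_real_, label = "failed")
    else
      data.frame(alpha = a, beta = b, bulk = pt$bulk, bulk_se = pt$bulk_se,
                 J = pt$J, label = pt$label)
  })
  do.call(rbind, rows)
}

#' Onset of alpha-independent bulk density (MC recovery)
#'
#' Sweeps the injection rate at fixed `beta` and reports the smallest grid
#' alpha beyond which the bulk density stops tracking alpha: adjacent
#' sweep points are compared, and a step is "tracking" when the density
#' difference exceeds `rho_tol / 2` plus two joint standard errors.  Used
#' to detect the reappearance of the maximal-current phase when the
#' transverse hop probability is raised.
#'
#' @param config a `run_config` template.
#' @param beta fixed outflux rate.
#' @param alphas increasing sweep grid.
#' @param rho_tol density tolerance.
#' @return List: `onset` (NA when the density still tracks alpha at the
#'   end of the sweep) and the sweep `table`.
#' @export
mc_onset <- function(config, beta, alphas, rho_tol = 0.02) {
  stopifnot(length(alphas) >= 3, !is.unsorted(alphas))
  pts <- lapply(seq_along(alphas), function(i)
    run_bulk(with_boundary(config, alphas[i], beta, seed_offset = 7L * i)))
  bulk <- vapply(pts, `[[`, numeric(1), "bulk")
  se <- vapply(pts, `[[`, numeric(1), "se")
  nstep <- length(alphas) - 1L
  tracking <- vapply(seq_len(nstep), function(i)
    (bulk[i + 1] - bulk[i]) > rho_tol / 2 + 2 * (se[i] + se[i + 1]),
    logical(1))
  flat_from <- NA_integer_
  for (i in seq_len(nstep)) {
    if (!any(tracking[i:nstep])) { flat_from <- i; break }
  }
  list(onset = if (is.na(flat_from)) NA_real_ else alphas[flat_from],
       table = data.frame(alpha = alphas, bulk = bulk, se = se,
                          tracking = c(tracking, NA)))
}
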