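#' Lattice geometry of the open cylinder
#'
#' `Lx` columns along the transport direction (open at both ends) and `Ly`
#' lanes with periodic transverse boundaries.  The quasi-two-dimensional
#' regime of interest has `Ly/Lx << 1` (not enforced).
#'
#' @param Lx number of columns per lane (>= 8).
#' @param Ly number of lanes (>= 1).
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(Lx, Ly = 1L) {
  Lx <- as.integer(Lx); Ly <- as.integer(Ly)
  if (is.na(Lx) || Lx < 8L) stop("Lx must be an integer >= 8")
  if (is.na(Ly) || Ly < 1L) stop("Ly must be an integer >= 1")
  structure(list(Lx = Lx, Ly = Ly), class = "lattice_config")
}

#' Open-boundary injection and extraction rates
#'
#' Particles enter at the first column of each lane with probability
#' `alpha` per lane per MCS (only if the entrance site is empty), and leave
#' with probability `beta` at each exit opportunity (a move attempt that
#' reaches or passes the last column).
#'
#' @param alpha,beta probabilities in `[0, 1]`.
#' @return An object of class `boundary_rates`.
#' @export
boundary_rates <- function(alpha, beta) {
  if (any(c(alpha, beta) < 0) || any(c(alpha, beta) > 1))
    stop("alpha and beta must lie in [0, 1]")
  structure(list(alpha = alpha, beta = beta), class = "boundary_rates")
}

#' Complete run configuration
#'
#' Bundles geometry, kinetics, boundary rates and run control into a fully
#' serializable configuration; a run is reproducible from `(config, code
#' version)` alone.
#'
#' @param lattice a [lattice_config()].
#' @param kinetics a [kinetics_params()].
#' @param boundary a [boundary_rates()].
#' @param warmup,sample Monte Carlo steps discarded / measured.
#' @param seed integer seed of the engine's private RNG stream.
#' @param record_events record one row per entry/move/exit event (needed
#'   for dwell times, tagged trajectories, MSD).
#' @param max_events event-log capacity; recording stops (flagged) beyond it.
#' @param entry_state `"empty"` (entrants carry no ATP, the default) or
#'   `"stationary"` (binding sites drawn from their stationary law).
#' @param periodic close the lattice into a longitudinal ring (no
#'   injection/extraction; used for mean-field cross-checks at fixed N).
#' @param init optional `Ly x Lx` 0/1 matrix of initial occupancy.
#' @param init_primary,init_s internal state given to initial particles.
#' @param nblocks number of equal sampling blocks used for standard errors.
#' @param check run full occupancy/registry consistency checks every sweep.
#' @return An object of class `run_config`.
#' @export
run_config <- function(lattice, kinetics, boundary,
                       warmup = 1000L, sample = 5000L, seed = 1L,
                       record_events = FALSE, max_events = 5e6,
                       entry_state = c("empty", "stationary"),
                       periodic = FALSE, init = NULL,
                       init_primary = FALSE, init_s = 0L,
                       nblocks = 10L, check = FALSE) {
  stopifnot(inherits(lattice, "lattice_config"),
            inherits(kinetics, "kinetics_params"),
            inherits(boundary, "boundary_rates"))
  entry_state <- match.arg(entry_state)
  if (lattice$Ly == 1L && kinetics$Py > 0)
    stop("Py must be 0 when Ly = 1 (no transverse ring to hop on)")
  if (warmup < 0 || sample < 1) stop("need warmup >= 0 and sample >= 1")
  if (!is.null(init)) {
    init <- as.matrix(init)
    if (nrow(init) != lattice$Ly || ncol(init) != lattice$Lx)
      stop("init must be a Ly x Lx matrix")
  }
  structure(list(lattice = lattice, kinetics = kinetics, boundary = boundary,
                 warmup = as.integer(warmup), sample = as.integer(sample),
                 seed = as.integer(seed), record_events = record_events,
                 max_events = max_events, entry_state = entry_state,
                 periodic = periodic, init = init,
                 init_primary = init_primary, init_s = as.integer(init_s),
                 nblocks = as.integer(nblocks), check = check),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: %d x %d lattice, alpha = %g, beta = %g%s\n",
              x$lattice$Lx, x$lattice$Ly, x$boundary$alpha, x$boundary$beta,
              if (x$periodic) " (periodic ring)" else ""))
  print(x$kinetics)
  cat(sprintf("warmup %d + sample %d MCS, seed %d\n",
              x$warmup, x$sample, x$seed))
  invisible(x)
}

#' Landing site of a multi-step jump under the sliding rule
#'
#' A motor intending `n` forward steps slides to the last empty site before
#' the first obstacle: it lands at `position + min(n, g)`, where `g` is the
#' number of contiguous empty sites immediately ahead in the lane, capped
#' at the lane end.  Particles never overtake within a lane.
#'
#' @param lane_occupancy logical (or 0/1) vector; the lane, `TRUE` =
#'   occupied.
#' @param position column index (1-based) of the mover.
#' @param n intended number of steps, 1..4.
#' @return The landing column index (equal to `position` when blocked).
#' @examples
#' occ <- rep(FALSE, 10); occ[3] <- TRUE; occ[7] <- TRUE
#' slide_target(occ, 3, 4)  # obstacle at 7 truncates the jump to column 6
#' @export
slide_target <- function(lane_occupancy, position, n) {
  occ <- as.logical(lane_occupancy)
  position <- as.integer(position); n <- as.integer(n)
  stopifnot(n >= 1, n <= 4, position >= 1, position <= length(occ))
  Lx <- length(occ)
  g <- 0L
  while (g < n && position + g + 1L <= Lx && !occ[position + g + 1L])
    g <- g + 1L
  position + g
}

#' Run the kinetic Monte Carlo simulation
#'
#' Advances the system by `warmup + sample` Monte Carlo steps under
#' random-sequential updating: one MCS consists of `N + Ly` elementary
#' draws with replacement over the current agents (the `N` resident
#' particles plus one entrance slot per lane), so every agent is updated
#' once per MCS on average and the chain is the discrete skeleton of the
#' continuous-time process.  Drawing an entrance slot attempts an
#' injection (probability `alpha`, entrance site must be empty); drawing a
#' particle applies one attachment/detachment trial per binding site and
#' then, if the primary site holds ATP, one move attempt of intended
#' length `4 - s` in a direction drawn with probabilities
#' `(Px, Py, Py)`.  A realized hop (displacement >= 1, including full
#' transverse wraps) hydrolyses the primary ATP; blocked attempts do not.
#' Extraction trials are folded into move attempts that reach or pass the
#' last column.  Observables are accumulated over the sampling window only.
#'
#' @param config a [run_config()].
#' @return An object of class `dynlane_run`: the configuration plus
#'   \describe{
#'     \item{density}{`Ly x Lx` time-averaged occupancy.}
#'     \item{bond_current}{per-bond longitudinal current (per lane per
#'       MCS); index `i` is the bond between columns `i` and `i+1`, index
#'       `Lx` the exit (or wrap) bond.}
#'     \item{jump_long, jump_trans}{realized-displacement counts, lengths
#'       1..4.}
#'     \item{block_bulk, block_J, block_trans}{per-block mid-bulk density,
#'       spatially averaged longitudinal current, and net transverse
#'       current, for standard errors.}
#'     \item{events}{data frame of (t, id, lane, col, dx, dy, type) when
#'       `record_events = TRUE`; type is `"enter"`, `"move"` or `"exit"`.}
#'     \item{n_injected, n_extracted, final}{bookkeeping over the whole
#'       run and the surviving-particle registry.}
#'   }
#' @examples
#' cfg <- run_config(lattice_config(50, 2), kinetics_params(),
#'                   boundary_rates(0.3, 0.7), warmup = 200, sample = 500)
#' run <- simulate_run(cfg)
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lat <- config$lattice; kin <- config$kinetics; bnd <- config$boundary
  init <- config$init
  if (is.null(init)) init <- matrix(0L, 0L, 0L)
  res <- .sim_core(lat$Lx, lat$Ly, bnd$alpha, bnd$beta,
                   kin$Patt, kin$Pdet, kin$Satt, kin$Sdet, kin$Px, kin$Py,
                   config$warmup, config$sample, config$seed,
                   init, config$init_primary, config$init_s,
                   config$entry_state == "stationary",
                   config$periodic,
                   config$record_events, as.integer(config$max_events),
                   config$nblocks, config$check)
  events <- NULL
  if (!is.null(res$events)) {
    e <- res$events
    if (isTRUE(e$truncated))
      warning("event log truncated at max_events; late events are missing")
    events <- data.frame(t = e$t, id = e$id, lane = e$lane, col = e$col,
                         dx = e$dx, dy = e$dy,
                         type = c("enter", "move", "exit")[e$type + 1L])
  }
  norm <- config$sample * lat$Ly
  structure(list(
    config = config,
    density = res$density,
    bond_current = res$bond_raw / norm,
    bond_raw = res$bond_raw,
    jump_long = setNames(res$jump_long, 1:4),
    jump_trans = setNames(res$jump_trans, 1:4),
    up_cross = res$up_cross, down_cross = res$down_cross,
    block_bulk = res$block_bulk, block_J = res$block_J,
    block_trans = res$block_trans,
    n_injected = res$n_injected, n_extracted = res$n_extracted,
    final = as.data.frame(res$final),
    events = events), class = "dynlane_run")
}

#' @export
print.dynlane_run <- function(x, ...) {
  lat <- x$config$lattice
  cat(sprintf("dynlane run: %d x %d, alpha = %g, beta = %g\n",
              lat$Lx, lat$Ly, x$config$boundary$alpha, x$config$boundary$beta))
  cat(sprintf("  %d injected, %d extracted, %d on lattice\n",
              x$n_injected, x$n_extracted, nrow(x$final)))
  cat(sprintf("  mid-bulk density %.4f, mean current %.4f\n",
              mean(x$block_bulk), mean(x$block_J)))
  invisible(x)
}
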