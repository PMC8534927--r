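#' Stationary density profile of a run
#'
#' Time-averaged occupancy per column (averaged over lanes), with a bulk
#' estimate taken over the middle 50% of columns and a block standard
#' error.
#'
#' @param run a [simulate_run()] result.
#' @return An object of class `density_profile`: `x`, `rho` (per column),
#'   `rho_lane` (`Ly x Lx`), `bulk`, `bulk_se`.
#' @export
measure_density <- function(run) {
  stopifnot(inherits(run, "dynlane_run"))
  Lx <- run$config$lattice$Lx
  rho <- colMeans(run$density)
  blocks <- run$block_bulk
  structure(list(x = seq_len(Lx), rho = rho, rho_lane = run$density,
                 bulk = mean(blocks),
                 bulk_se = sd(blocks) / sqrt(length(blocks)),
                 window = c(run$config$warmup + 1L,
                            run$config$warmup + run$config$sample)),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Density profile over %d columns; bulk = %.4f +/- %.4f\n",
              length(x$x), x$bulk, x$bulk_se))
  invisible(x)
}

#' Stationary bond currents of a run
#'
#' Longitudinal current per bond (particles crossing per lane per MCS; a
#' realized displacement of length `d` crosses `d` bonds) and the net
#' transverse current, each with block standard errors.  `J` is the
#' spatial average over all bonds including the exit bond.
#'
#' @param run a [simulate_run()] result.
#' @return An object of class `current_record`.
#' @export
measure_current <- function(run) {
  stopifnot(inherits(run, "dynlane_run"))
  Lx <- run$config$lattice$Lx
  structure(list(bond = run$bond_current,
                 J = mean(run$block_J),
                 J_se = sd(run$block_J) / sqrt(length(run$block_J)),
                 transverse = mean(run$block_trans),
                 transverse_se = sd(run$block_trans) /
                   sqrt(length(run$block_trans))),
            class = "current_record")
}

#' @export
print.current_record <- function(x, ...) {
  cat(sprintf("J = %.5f +/- %.5f per bond per lane per MCS\n", x$J, x$J_se))
  cat(sprintf("net transverse current = %.2g +/- %.2g\n",
              x$transverse, x$transverse_se))
  invisible(x)
}

#' Histogram of realized jump lengths
#'
#' Counts of realized (post-sliding) displacements 1..4 over the sampling
#' window, separately for longitudinal and transverse moves.
#'
#' @param run a [simulate_run()] result.
#' @return An object of class `jump_histogram`: matrix of counts with rows
#'   `longitudinal`/`transverse`, plus the proportions.
#' @export
jump_histogram <- function(run) {
  stopifnot(inherits(run, "dynlane_run"))
  counts <- rbind(longitudinal = run$jump_long, transverse = run$jump_trans)
  colnames(counts) <- 1:4
  prop <- counts / pmax(rowSums(counts), 1)
  structure(list(counts = counts, prop = prop), class = "jump_histogram")
}

#' @export
print.jump_histogram <- function(x, ...) {
  cat("Realized jump-length counts:\n"); print(x$counts); invisible(x)
}

#' Tag particles by entry epoch
#'
#' Particle `A` is the first entrant; `B` is the first particle entering
#' at or after `c_B * Lx` MCS, `C` the first at or after `c_C * Lx^2` MCS.
#' The three classes probe increasingly crowded environments.
#'
#' @param run a [simulate_run()] result with `record_events = TRUE`.
#' @param c_B,c_C entry-time scale factors.
#' @return Data frame with columns `class`, `id`, `t_en` (classes missing
#'   from too-short runs are dropped with a warning).
#' @export
tag_particles <- function(run, c_B = 1, c_C = 1) {
  stopifnot(inherits(run, "dynlane_run"))
  if (is.null(run$events)) stop("run was not recorded with record_events = TRUE")
  en <- run$events[run$events$type == "enter", ]
  if (nrow(en) == 0) {
    warning("no particles entered; no tags assigned")
    return(data.frame(class = character(), id = integer(), t_en = integer()))
  }
  en <- en[order(en$t, en$id), ]
  Lx <- run$config$lattice$Lx
  pick <- function(tmin) {
    i <- which(en$t >= tmin)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  sel <- c(A = 1L, B = pick(c_B * Lx), C = pick(c_C * Lx^2))
  if (anyNA(sel))
    warning("run too short for tag class(es): ",
            paste(names(sel)[is.na(sel)], collapse = ", "))
  keep <- !is.na(sel)
  data.frame(class = names(sel)[keep], id = en$id[sel[keep]],
             t_en = en$t[sel[keep]])
}

#' Reconstruct a particle trajectory from the event log
#'
#' Positions are piecewise constant between realized jumps.  The
#' transverse coordinate is unwrapped (cumulative signed ring
#' displacement), so transverse MSDs are free of periodic-boundary
#' artifacts.
#'
#' @param run a [simulate_run()] result with `record_events = TRUE`.
#' @param id particle id.
#' @return Data frame `t` (MCS since entry), `x`, `y` (unwrapped), plus
#'   attributes `t_en` and `exited`.
#' @export
trajectory <- function(run, id) {
  stopifnot(inherits(run, "dynlane_run"))
  if (is.null(run$events)) stop("run was not recorded with record_events = TRUE")
  ev <- run$events[run$events$id == id, ]
  if (nrow(ev) == 0) stop("unknown particle id ", id)
  ev <- ev[order(ev$t), ]
  if (ev$type[1] != "enter") stop("event log lacks the entry of particle ", id)
  t_en <- ev$t[1]
  x <- ev$col[1] + cumsum(c(0, ev$dx[-1]))
  y <- ev$lane[1] + cumsum(c(0, ev$dy[-1]))
  out <- data.frame(t = ev$t - t_en, x = x, y = y)
  attr(out, "t_en") <- t_en
  attr(out, "exited") <- any(ev$type == "exit")
  out
}

#' Ensemble mean-square displacement
#'
#' Averages the squared displacement since entry over an ensemble of
#' trajectories (independent realizations), on the common time range all
#' trajectories cover.  With `detrend = TRUE` (the default) the squared
#' ensemble-mean displacement is subtracted, giving the displacement
#' variance -- the quantity whose growth exponent distinguishes driven
#' (KPZ-like) from diffusive tagged-particle dynamics.  With
#' `detrend = FALSE` the raw second moment is returned, which for a free
#' drifting motor is asymptotically ballistic.
#'
#' @param trajs list of [trajectory()] data frames.
#' @param axis `"x"` (longitudinal) or `"y"` (transverse, unwrapped).
#' @param detrend subtract the squared mean displacement.
#' @param tmax last lag; defaults to the largest lag covered by every
#'   trajectory.
#' @return An object of class `msd_curve`: data frame `t`, `msd`, and the
#'   ensemble size `n` as an attribute.
#' @export
msd_ensemble <- function(trajs, axis = c("x", "y"), detrend = TRUE,
                         tmax = NULL) {
  axis <- match.arg(axis)
  stopifnot(length(trajs) >= 1)
  ends <- vapply(trajs, function(d) max(d$t), numeric(1))
  if (is.null(tmax)) tmax <- min(ends)
  if (tmax < 1) stop("trajectories too short for an MSD")
  tt <- seq_len(tmax)
  disp <- vapply(trajs, function(d) {
    pos <- d[[axis]]
    pos[findInterval(tt, d$t)] - pos[1]
  }, numeric(length(tt)))
  disp <- matrix(disp, nrow = length(tt))
  m2 <- rowMeans(disp^2)
  msd <- if (detrend) m2 - rowMeans(disp)^2 else m2
  out <- data.frame(t = tt, msd = msd)
  attr(out, "n") <- length(trajs)
  attr(out, "axis") <- axis
  attr(out, "detrend") <- detrend
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit a growth law to an MSD curve
#'
#' Fits `MSD = A * t^xi` (`model = "power"`) or the log-corrected form
#' `MSD = A * t^xi / ln(t)` (`model = "log"`) by least squares on
#' log-log axes over a fit window spanning at least 1.5 decades; the
#' exponent is not reported on narrower windows.
#'
#' @param msd an [msd_ensemble()] curve.
#' @param window `c(tmin, tmax)`; default `c(tmax/10^1.5, tmax)`.
#' @param model `"log"` (default) or `"power"`.
#' @param min_realizations fits are refused below this ensemble size.
#' @return An object of class `msd_fit`: `xi`, `se`, `A`, `model`,
#'   `window`.
#' @export
fit_msd <- function(msd, window = NULL, model = c("log", "power"),
                    min_realizations = 100) {
  model <- match.arg(model)
  n <- attr(msd, "n")
  if (!is.null(n) && n < min_realizations)
    stop("fit refused: only ", n, " realizations (need >= ",
         min_realizations, "); the curve itself is still usable")
  if (is.null(window)) window <- c(max(msd$t) / 10^1.5, max(msd$t))
  if (log10(window[2] / window[1]) < 1.5 - 1e-9)
    stop("fit window must span at least 1.5 decades")
  d <- msd[msd$t >= window[1] & msd$t <= window[2] & msd$msd > 0, ]
  d <- d[d$t > 1, ]  # ln(t) correction undefined at t = 1
  y <- if (model == "log") log(d$msd * log(d$t)) else log(d$msd)
  fit <- lm(y ~ log(d$t))
  structure(list(xi = unname(coef(fit)[2]),
                 se = unname(sqrt(diag(vcov(fit)))[2]),
                 A = exp(unname(coef(fit)[1])),
                 model = model, window = window, n = n),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  form <- if (x$model == "log") "A t^xi / ln t" else "A t^xi"
  cat(sprintf("MSD fit %s: xi = %.3f +/- %.3f over t in [%.3g, %.3g]\n",
              form, x$xi, x$se, x$window[1], x$window[2]))
  invisible(x)
}

#' Dwell (waiting) times between consecutive realized jumps
#'
#' The dwell time is the time a particle waits between two consecutive
#' realized jumps, in any direction (exit jumps included).  Event times
#' carry their position within the sweep, and waiting times are reported
#' in whole MCS (`ceiling` of the elapsed time), so they are always
#' >= 1 MCS and an exponential waiting process of rate `lambda` maps
#' exactly onto a geometric law with `p = 1 - exp(-lambda)`.
#'
#' @param run a [simulate_run()] result with `record_events = TRUE`.
#' @param ids optional particle ids to restrict to (e.g. a tag class).
#' @return Integer vector of waiting times (>= 1 MCS each).
#' @export
dwell_times <- function(run, ids = NULL) {
  stopifnot(inherits(run, "dynlane_run"))
  if (is.null(run$events)) stop("run was not recorded with record_events = TRUE")
  ev <- run$events[run$events$type %in% c("move", "exit"), ]
  if (!is.null(ids)) ev <- ev[ev$id %in% ids, ]
  if (nrow(ev) == 0) return(integer(0))
  ev <- ev[order(ev$id, ev$t), ]
  dt <- diff(ev$t)
  same <- diff(ev$id) == 0L
  as.integer(ceiling(dt[same]))
}

#' Fit exponential models to a dwell-time distribution
#'
#' Dwell times live on 1, 2, 3, ... MCS, so fits use the discrete
#' (geometric) likelihood, `P(W = k) = p (1-p)^(k-1)`; the reported decay
#' rates are the continuous-time equivalents `lambda = -log(1 - p)`.  The
#' `"double"` model is the two-stage (difference-of-exponentials) form
#' `P(W = k) = p1 p2 (q2^k - q1^k) / (q2 - q1)` with `q = 1 - p` -- the
#' convolution of two geometric stages (e.g. waiting for ATP and waiting
#' for space), which decays slowly at short times and crosses over to the
#' slower rate's pure exponential at long times, the shape characteristic
#' of congested traffic.  It nests the single model as `p1 -> 1`.
#' `"auto"` selects between single and double by BIC.
#'
#' @param w integer waiting times (>= 1).
#' @param model `"auto"`, `"single"` or `"double"`.
#' @param min_n below this sample size the fit is refused and only the
#'   histogram is returned.
#' @return An object of class `dwell_fit` with the selected `model`,
#'   stage parameter(s) `p` (fast stage first for the double model), decay
#'   rate(s) `lambda`, `logLik` and `bic` for both candidates, and the
#'   histogram `table`.
#' @export
fit_dwell <- function(w, model = c("auto", "single", "double"), min_n = 500) {
  model <- match.arg(model)
  w <- as.integer(w)
  stopifnot(all(w >= 1))
  hist <- table(w)
  if (length(w) < min_n) {
    warning("only ", length(w), " intervals (< ", min_n,
            "); returning the histogram without a fit")
    return(structure(list(model = NA_character_, table = hist, n = length(w)),
                     class = "dwell_fit"))
  }
  loglik_geom <- function(p) sum(log(p) + (w - 1) * log1p(-p))
  p_single <- 1 / mean(w)
  ll1 <- loglik_geom(p_single)
  bic1 <- -2 * ll1 + log(length(w))

  # two-stage model: maximum likelihood over (p1, p2) on the logit scale,
  # deterministic starts (fast stage near 1 / slow stage at the mean, and a
  # symmetric split)
  nll2 <- function(par) {
    p <- stats::plogis(par)
    if (abs(p[1] - p[2]) < 1e-8) p[1] <- min(p[1] + 1e-6, 1 - 1e-9)
    q1 <- 1 - p[1]; q2 <- 1 - p[2]
    lp <- log(p[1]) + log(p[2]) - log(abs(q2 - q1)) +
      log(abs(q2^w - q1^w))
    if (!all(is.finite(lp))) return(1e10)
    -sum(lp)
  }
  starts <- list(stats::qlogis(c(0.8, min(p_single * 1.2, 0.95))),
                 stats::qlogis(pmin(pmax(c(2 * p_single, p_single / 2),
                                         1e-4), 1 - 1e-4)))
  fits <- lapply(starts, function(s)
    stats::optim(s, nll2, method = "BFGS", control = list(maxit = 500)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  p2 <- sort(stats::plogis(best$par), decreasing = TRUE)  # fast, slow
  ll2 <- -best$value
  bic2 <- -2 * ll2 + 2 * log(length(w))

  selected <- switch(model,
                     single = "single", double = "double",
                     auto = if (bic2 < bic1) "double" else "single")
  out <- list(model = selected,
              p = if (selected == "single") p_single else p2,
              lambda = if (selected == "single") -log1p(-p_single)
                       else -log1p(-p2),
              logLik = c(single = ll1, double = ll2),
              bic = c(single = bic1, double = bic2),
              table = hist, n = length(w))
  structure(out, class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  if (is.na(x$model)) {
    cat("Dwell histogram of", x$n, "intervals (no fit)\n")
    return(invisible(x))
  }
  cat(sprintf("Dwell-time fit (%s exponential, n = %d):\n", x$model, x$n))
  cat("  lambda =", paste(signif(x$lambda, 4), collapse = ", "), "\n")
  cat(sprintf("  BIC single %.1f vs double %.1f\n",
              x$bic["single"], x$bic["double"]))
  invisible(x)
}

#' Fit the characteristic density-profile shapes
#'
#' In the maximal-current phase the stationary profile follows a tangent
#' shape, `rho(x) = rho_max * (1 - q * tan(q * (x - x0)))` with small `q`;
#' on the first-order coexistence line the domain wall gives a hyperbolic
#' tangent, `rho(x) = c0 + a * tanh((x - x0) / w)`.  Least-squares fits
#' over the bulk, with a configurable boundary-layer exclusion.
#'
#' @param profile a [measure_density()] profile (or data frame `x`, `rho`).
#' @param form `"tangent"` or `"tanh"`.
#' @param exclude fraction of columns dropped at each end.
#' @return An object of class `profile_fit`: `par`, `residual_sd`, `form`.
#' @export
fit_profile <- function(profile, form = c("tangent", "tanh"), exclude = 0.1) {
  form <- match.arg(form)
  x <- profile$x; rho <- profile$rho
  n <- length(x)
  keep <- seq.int(max(1L, floor(n * exclude)), ceiling(n * (1 - exclude)))
  d <- data.frame(x = x[keep], rho = rho[keep])
  span <- diff(range(d$x))
  fit <- if (form == "tangent") {
    # x0 is profiled over a deterministic grid: with all three parameters
    # free, flat profiles make the rmax and x0 gradient directions
    # collinear (singular at q -> 0), while the inner (rmax, q) problem is
    # always well posed
    inner <- function(x0) {
      tryCatch(minpack.lm::nlsLM(
        rho ~ rmax * (1 - q * tan(q * (x - x0))), data = cbind(d, x0 = x0),
        start = list(rmax = mean(d$rho), q = 0.5 / span),
        lower = c(rmax = 1e-6, q = 1e-6),
        upper = c(rmax = 1, q = 0.99 * pi / span),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    }
    x0_grid <- mean(d$x) + span * seq(-0.3, 0.3, by = 0.15)
    cand <- lapply(x0_grid, inner)
    ok <- !vapply(cand, is.null, logical(1))
    if (!any(ok))
      stop("tangent profile fit did not converge from any start; ",
           "profile may be incompatible with the tangent form")
    rss <- vapply(cand[ok], function(f) sum(resid(f)^2), numeric(1))
    best_i <- which(ok)[which.min(rss)]
    best <- cand[[best_i]]
    # polish with x0 free where the geometry allows it
    polish <- tryCatch(minpack.lm::nlsLM(
      rho ~ rmax * (1 - q * tan(q * (x - x0))), data = d,
      start = c(as.list(coef(best)), list(x0 = x0_grid[best_i])),
      lower = c(rmax = 1e-6, q = 1e-6, x0 = min(d$x) - span),
      upper = c(rmax = 1, q = 0.99 * pi / span, x0 = max(d$x) + span),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(polish) && sum(resid(polish)^2) <= min(rss)) polish
    else structure(best, x0_fixed = x0_grid[best_i])
  } else {
    minpack.lm::nlsLM(
      rho ~ c0 + a * tanh((x - x0) / w0), data = d,
      start = list(c0 = mean(d$rho), a = diff(range(d$rho)) / 2,
                   x0 = mean(d$x), w0 = span / 8),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  par <- coef(fit)
  if (!is.null(attr(fit, "x0_fixed")))
    par <- c(par, x0 = attr(fit, "x0_fixed"))
  structure(list(par = par, residual_sd = sd(resid(fit)),
                 form = form, fit = fit), class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("%s profile fit: ", x$form))
  cat(paste(names(x$par), "=", signif(x$par, 4), collapse = ", "), "\n")
  cat(sprintf("residual sd = %.4g\n", x$residual_sd))
  invisible(x)
}

#' Dominant spatial period of entrance-side density oscillations
#'
#' The low-density phase shows damped density oscillations near the
#' entrance, an artifact of the multi-site jumps, with a period of four
#' columns.  The period is estimated as the lag of the highest spatial
#' autocorrelation peak of `rho(x) - rho_bulk` over the entrance region.
#'
#' @param profile a [measure_density()] profile.
#' @param cols columns to analyse (default the first 50).
#' @param max_lag largest lag considered.
#' @return Integer period (lag of the dominant autocorrelation peak).
#' @export
oscillation_period <- function(profile, cols = 1:50, max_lag = 10) {
  y <- profile$rho[cols] - profile$bulk
  a <- acf(y, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  lags <- 2:max_lag
  unname(lags[which.max(a[lags])])
}

#' Synthetic observables with known parameters
#'
#' Generators used by the parameter-recovery oracle suites:
#' `synth_tangent_profile()` draws a tangent-shaped density profile with
#' additive Gaussian noise, and `synth_geometric_dwell()` draws geometric
#' waiting times.  Both use R's RNG stream.  The default `q` makes
#' `q * (x - x0)` span most of the tangent branch across the lattice, as
#' in stationary maximal-current profiles whose boundary bending is
#' visible; far smaller `q` values leave the shape indistinguishable from
#' a flat profile at realistic noise.
#'
#' @param Lx number of columns.
#' @param rho_max,q,x0 tangent-profile parameters.
#' @param noise additive noise standard deviation.
#' @return `synth_tangent_profile`: a `density_profile`-like list;
#'   `synth_geometric_dwell`: an integer vector.
#' @export
synth_tangent_profile <- function(Lx = 300, rho_max = 0.45, q = 3 / Lx,
                                  x0 = NULL, noise = 0.01) {
  if (is.null(x0)) x0 <- Lx / 2
  x <- seq_len(Lx)
  rho <- rho_max * (1 - q * tan(q * (x - x0))) + stats::rnorm(Lx, 0, noise)
  structure(list(x = x, rho = rho, bulk = mean(rho[(Lx %/% 4):(3 * Lx %/% 4)]),
                 bulk_se = noise / sqrt(Lx / 2)),
            class = "density_profile")
}

#' @rdname synth_tangent_profile
#' @param n number of waiting times.
#' @param p geometric success parameter (jump probability per MCS).
#' @export
synth_geometric_dwell <- function(n, p) {
  stats::rgeom(n, p) + 1L
}
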