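#' ATP-binding kinetics of a single motor
#'
#' A motor particle carries four ATP binding sites: one primary
#' (hydrolysis) site that enables movement, and three secondary sites that
#' carry load.  Each bound secondary ATP shortens the intended jump by one
#' site, so a motor with `s` loaded secondary sites attempts a hop of
#' `4 - s` lattice sites, and a motor with an empty primary site does not
#' move at all.
#'
#' `kinetics_params()` validates and bundles the six per-sweep
#' probabilities: `Patt`/`Pdet` (attachment/detachment at the primary
#' site), `Satt`/`Sdet` (per secondary site), and the direction
#' probabilities `Px` (forward) and `Py` (up, and separately down).
#' The direction probabilities must satisfy `Px + 2*Py = 1`.
#'
#' @param Patt,Pdet primary-site ATP attachment/detachment probability per
#'   Monte Carlo step (MCS).
#' @param Satt,Sdet per-secondary-site attachment/detachment probability
#'   per MCS.  The study conditions use `Sdet = 1 - Satt`.
#' @param Px,Py probability of choosing the forward direction, and of
#'   choosing up (down has the same probability `Py`).
#' @return An object of class `kinetics_params`.
#' @examples
#' high_load <- kinetics_params(Satt = 0.8)
#' low_load  <- kinetics_params(Satt = 0.2)
#' @export
kinetics_params <- function(Patt = 0.8, Pdet = 0.2, Satt = 0.8,
                            Sdet = 1 - Satt, Px = 0.95, Py = 0.025) {
  p <- list(Patt = Patt, Pdet = Pdet, Satt = Satt, Sdet = Sdet,
            Px = Px, Py = Py)
  probs <- unlist(p)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all kinetic parameters must be probabilities in [0, 1]")
  if (abs(Px + 2 * Py - 1) > 1e-9)
    stop("direction probabilities must satisfy Px + 2*Py = 1 (got ",
         format(Px + 2 * Py), ")")
  structure(p, class = "kinetics_params")
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat("Motor kinetics: Patt =", x$Patt, " Pdet =", x$Pdet,
      " Satt =", x$Satt, " Sdet =", x$Sdet, "\n")
  cat("Directions:     Px =", x$Px, " Py =", x$Py, "\n")
  invisible(x)
}

#' Internal state of a single motor
#'
#' @param primary logical; is the primary (hydrolysis) site occupied?
#' @param s integer 0-3; number of secondary sites holding ATP.
#' @return An object of class `motor_state`.
#' @export
motor_state <- function(primary = FALSE, s = 0L) {
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 0L || s > 3L)
    stop("s must be an integer in 0..3")
  structure(list(primary = isTRUE(primary), s = s), class = "motor_state")
}

#' One sweep of attachment/detachment trials on a motor's binding sites
#'
#' Applies exactly one trial per site: an empty primary site gains ATP with
#' probability `Patt`, an occupied one loses it with probability `Pdet`;
#' each of the three secondary sites independently gains ATP with
#' probability `Satt` when empty and loses it with probability `Sdet` when
#' occupied.  Attachment and detachment are mutually exclusive per site and
#' sweep.  Uses R's RNG stream.
#'
#' @param state a [motor_state()].
#' @param params a [kinetics_params()].
#' @return The updated `motor_state`.
#' @export
update_internal_state <- function(state, params) {
  stopifnot(inherits(state, "motor_state"), inherits(params, "kinetics_params"))
  primary <- if (state$primary) runif(1) >= params$Pdet else runif(1) < params$Patt
  stay <- if (state$s > 0L) sum(runif(state$s) >= params$Sdet) else 0L
  gain <- if (state$s < 3L) sum(runif(3L - state$s) < params$Satt) else 0L
  motor_state(primary = primary, s = as.integer(stay + gain))
}

#' Intended jump length of a motor
#'
#' A motor with a filled primary site attempts to hop `4 - s` sites, where
#' `s` is its secondary-site load; with an empty primary site it cannot
#' move.
#'
#' @param state a [motor_state()].
#' @return Integer in 0..4.
#' @export
intended_steps <- function(state) {
  stopifnot(inherits(state, "motor_state"))
  if (!state$primary) return(0L)
  4L - state$s
}

#' Stationary distribution of the secondary-site load
#'
#' The three secondary sites evolve as independent two-state chains, so the
#' stationary law of the load count `s` is Binomial(3, p) with
#' `p = Satt / (Satt + Sdet)`.
#'
#' @param params a [kinetics_params()].
#' @return Probability vector over `s = 0, 1, 2, 3`.
#' @export
secondary_stationary_dist <- function(params) {
  stopifnot(inherits(params, "kinetics_params"))
  if (params$Satt + params$Sdet <= 0)
    stop("degenerate secondary kinetics: Satt + Sdet must be positive")
  p <- params$Satt / (params$Satt + params$Sdet)
  setNames(dbinom(0:3, 3, p), paste0("s", 0:3))
}

#' Closed-form per-sweep jump rates of an unobstructed motor
#'
#' Returns `R1..R4`, the per-MCS probabilities that a free motor performs a
#' jump of length 1..4.  The default `"binomial"` mode is the product-form
#' rate: the stationary occupancy of the primary site,
#' `Patt / (Patt + Pdet)`, times the binomial probability of the secondary
#' load `s = 4 - i` from [secondary_stationary_dist()].  The `"series"`
#' mode evaluates an alternative set of series expressions for `R1`, `R2`
#' and `R4` that carry `(1 - Pdet)`-type prefactors; it is retained as a
#' cross-check and falls back to the binomial form for `R3`, for which no
#' self-consistent series expression exists.  The binomial mode is the one
#' validated against direct simulation of a free motor and is used
#' throughout the mean-field analysis.
#'
#' @param params a [kinetics_params()].
#' @param mode `"binomial"` (default, normative) or `"series"`.
#' @return An object of class `jump_rates`: numeric vector `R1..R4` with a
#'   `mode` attribute.
#' @examples
#' jump_rates(kinetics_params(Satt = 0.8))
#' @export
jump_rates <- function(params, mode = c("binomial", "series")) {
  stopifnot(inherits(params, "kinetics_params"))
  mode <- match.arg(mode)
  pocc <- if (params$Patt + params$Pdet > 0)
    params$Patt / (params$Patt + params$Pdet) else 0
  sdist <- secondary_stationary_dist(params)
  binom <- pocc * rev(unname(sdist))   # R_i pairs with s = 4 - i
  r <- binom
  if (mode == "series") {
    Sa <- params$Satt; Sd <- params$Sdet
    Pa <- params$Patt; Pd <- params$Pdet
    r[4] <- Pa * (1 - Pd) * sum((Sa * Sd)^(0:3) * (1 - Sa)^(3 - 0:3))
    r[2] <- Pa * (1 - Pd / 4) * Sa^2 * (1 - Sd)^2 * ((Sa * Sd) + (1 - Sa))
    r[1] <- Pa * (1 - Pd) * Sa^3 * (1 - Sd)^3
    # r[3] has no closed series form; binomial value retained
  }
  structure(setNames(r, paste0("R", 1:4)), class = "jump_rates", mode = mode)
}

#' @export
print.jump_rates <- function(x, ...) {
  cat("Unobstructed jump rates (", attr(x, "mode"), " mode):\n", sep = "")
  print(round(setNames(as.numeric(x), names(x)), 6))
  invisible(x)
}
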