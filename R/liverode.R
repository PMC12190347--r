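# Mechanistic model of liver regeneration after partial hepatectomy.
#
# Hepatocytes move between quiescent (Q), primed (P) and replicating (R)
# states. Resection removes cells, raising the metabolic load per hepatocyte
# m = M/N (N = Q+P+R, whole-body demand M constant). The load drives TNF and
# growth-factor production; TNF degrades extracellular matrix (via MMPs) and
# induces IL-6, which activates STAT3; STAT3 transcribes SOCS3 (negative
# feedback on its own activation) and immediate-early genes, which prime
# quiescent cells. Growth factor, freed as the ECM that sequesters it is
# degraded, pushes primed cells into replication. As mass returns, the load
# normalizes, ECM reforms, growth factor is taken back up, and replicating
# cells return to quiescence.
#
# State variables are normalized so the pre-resection steady state has every
# component equal to 1 (cell number N = Q = 1; molecular levels at basal 1;
# ECM 1). Time is in hours.

STATE_ORDER <- c("Q", "P", "R", "TNF", "IL6", "STAT3", "SOCS3", "IE", "GF", "ECM")

#' Default rate constants of the liver-regeneration model
#'
#' All rates are per hour; levels dimensionless. Defaults are calibration
#' artifacts chosen so that (i) the pre-resection state is a stable fixed
#' point with every component 1, (ii) a 60% resection recovers at least 95%
#' of liver volume within 12 months, and (iii) peak replication falls between
#' 1 and 10 days -- the proliferative window of regeneration.
#'
#' @param ... named overrides of individual constants.
#' @return An `ode_params` named list: cytokine cascade production/decay
#'   (`kappa_T`, `lambda_T`, `kappa_I`, `lambda_I`, `kappa_S`, `lambda_S`,
#'   `gamma_SOCS`, `kappa_C`, `lambda_C`, `kappa_E`, `lambda_E`), growth
#'   factor (`kappa_G`, `lambda_G`, `k_up`), matrix turnover (`k_syn`,
#'   `k_deg`), cell transitions (`alpha0` priming via IE excess over
#'   `IE_basal`, `beta0` replication entry via GF, `theta_R` R->Q return,
#'   `theta_P` ECM-driven P->Q reversion, `k_div` division, `delta_P`,
#'   `delta_R` apoptosis), hypertrophy weights `h_P`, `h_R`, and metabolic
#'   demand `M`.
#' @export
ode_params <- function(...) {
  p <- list(
    kappa_T = 0.5, lambda_T = 0.5,
    kappa_I = 0.4, lambda_I = 0.4,
    kappa_S = 0.6, lambda_S = 0.3, gamma_SOCS = 1,
    kappa_C = 0.2, lambda_C = 0.2,
    kappa_E = 0.4, lambda_E = 0.4,
    kappa_G = 0.5, lambda_G = 0.1, k_up = 0.4,
    k_syn = 0.05, k_deg = 0.05,
    alpha0 = 0.02, beta0 = 0.02,
    theta_R = 0.06, theta_P = 0.02,
    k_div = 0.025, delta_P = 0.002, delta_R = 0.005,
    h_P = 1.5, h_R = 1.5, M = 1, IE_basal = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (any(unlist(p) < 0)) stop("all parameters must be non-negative")
  structure(p, class = "ode_params")
}

#' Time derivatives of the liver-regeneration state
#'
#' @param state named numeric vector in the order of [state_vector()].
#' @param params an [ode_params()].
#' @return Named vector of derivatives (per hour).
#' @export
liver_rhs <- function(state, params) {
  if (any(!is.finite(state))) stop("non-finite state")
  s <- as.list(state); p <- params
  N <- s$Q + s$P + s$R
  m <- p$M / N
  priming <- p$alpha0 * max(s$IE - p$IE_basal, 0) * s$Q
  c(Q = -priming + p$theta_R * s$R + p$theta_P * s$ECM * s$P,
    P = priming - p$beta0 * s$GF * s$P - p$theta_P * s$ECM * s$P - p$delta_P * s$P,
    R = p$beta0 * s$GF * s$P + p$k_div * s$R - p$theta_R * s$R - p$delta_R * s$R,
    TNF = p$kappa_T * m - p$lambda_T * s$TNF,
    IL6 = p$kappa_I * s$TNF - p$lambda_I * s$IL6,
    STAT3 = p$kappa_S * s$IL6 / (1 + p$gamma_SOCS * s$SOCS3) - p$lambda_S * s$STAT3,
    SOCS3 = p$kappa_C * s$STAT3 - p$lambda_C * s$SOCS3,
    IE = p$kappa_E * s$STAT3 - p$lambda_E * s$IE,
    GF = p$kappa_G * m - p$lambda_G * s$GF - p$k_up * s$ECM * s$GF,
    ECM = p$k_syn - p$k_deg * s$TNF * s$ECM)
}

#' Quiescent steady state of the model
#'
#' The fixed point on the P = R = 0 branch, with total cell number normalized
#' to `Q = 1`. The molecular cascade solves in closed form given the load
#' m = M: TNF and IL-6 are production/decay balances, STAT3 solves a
#' quadratic through the SOCS3 feedback, IE follows STAT3, ECM balances
#' synthesis against TNF-driven degradation, and GF balances production
#' against decay plus ECM uptake. The state only qualifies as quiescent when
#' basal IE does not exceed the priming threshold `IE_basal`; otherwise no
#' quiescent fixed point exists and an error is raised.
#'
#' @param params an [ode_params()].
#' @param residual_tol maximum allowed derivative norm at the returned state.
#' @return Named state vector with residual below `residual_tol`.
#' @export
quiescent_steady_state <- function(params, residual_tol = 1e-8) {
  p <- params
  m <- p$M / 1
  if (p$lambda_T <= 0 || p$lambda_I <= 0 || p$lambda_S <= 0 ||
      p$lambda_C <= 0 || p$lambda_E <= 0)
    stop("no finite quiescent fixed point: a decay rate is zero")
  TNF <- p$kappa_T * m / p$lambda_T
  IL6 <- p$kappa_I * TNF / p$lambda_I
  # lambda_S*gamma*kappa_C/lambda_C * S^2 + lambda_S * S - kappa_S*IL6 = 0
  a <- p$lambda_S * p$gamma_SOCS * p$kappa_C / p$lambda_C
  b <- p$lambda_S; cc <- -p$kappa_S * IL6
  STAT3 <- if (a > 0) (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a) else -cc / b
  SOCS3 <- p$kappa_C * STAT3 / p$lambda_C
  IE <- p$kappa_E * STAT3 / p$lambda_E
  if (TNF <= 0 || p$k_deg <= 0)
    stop("no finite quiescent fixed point: ECM balance undefined (k_deg*TNF = 0)")
  ECM <- p$k_syn / (p$k_deg * TNF)
  GF <- p$kappa_G * m / (p$lambda_G + p$k_up * ECM)
  st <- c(Q = 1, P = 0, R = 0, TNF = TNF, IL6 = IL6, STAT3 = STAT3,
          SOCS3 = SOCS3, IE = IE, GF = GF, ECM = ECM)
  if (IE > p$IE_basal + 1e-10)
    stop(sprintf("basal IE (%.4f) exceeds the priming threshold IE_basal (%.4f): quiescence is not a fixed point",
                 IE, p$IE_basal))
  res <- max(abs(liver_rhs(st, p)))
  if (res > residual_tol)
    stop(sprintf("steady-state residual %.3e exceeds tolerance %.1e", res, residual_tol))
  st
}

#' Apply a partial hepatectomy to a quiescent state
#'
#' Removes fraction `f` of the liver: `Q -> (1 - f) Q`, `P = R = 0`. The
#' molecular levels are untouched at the instant of resection; the metabolic
#' load jumps implicitly through the drop in cell number.
#'
#' @param state a quiescent steady state (see [quiescent_steady_state()]).
#' @param f resected fraction in `[0, 1)`.
#' @return The post-resection state.
#' @export
apply_resection <- function(state, f) {
  if (!is.numeric(f) || length(f) != 1 || f < 0 || f >= 1)
    stop("resected fraction f must lie in [0, 1)")
  state["Q"] <- (1 - f) * state["Q"]
  state["P"] <- 0; state["R"] <- 0
  state
}

#' Simulate the regeneration model over a time grid
#'
#' Adaptive, stiff-capable integration (lsoda) from `state0` at the first
#' requested hour. Tiny negative undershoots (integrator tolerance artifacts)
#' are clipped to 0; undershoot beyond `clip_tol` triggers a warning.
#'
#' @param params an [ode_params()].
#' @param state0 initial named state vector.
#' @param grid a [time_grid()] (its hours are used) or a numeric vector of
#'   hours, non-decreasing.
#' @param clip_tol undershoot beyond this magnitude triggers a warning
#'   (default 1e-9); all negatives are clipped to 0 either way.
#' @return A `liver_trajectory`: `times` (hours), `states` (time x component
#'   matrix), `volume` = Q + h_P P + h_R R.
#' @export
simulate_liver <- function(params, state0, grid, clip_tol = 1e-9) {
  hours <- if (inherits(grid, "time_grid")) grid$hours else as.numeric(grid)
  if (length(hours) < 1 || any(diff(hours) < 0)) stop("grid hours must be non-decreasing")
  if (any(state0 < 0)) stop("initial state must be non-negative")
  state0 <- state0[STATE_ORDER]
  if (length(hours) == 1 || max(hours) == min(hours)) {
    states <- matrix(rep(state0, length(hours)), nrow = length(hours),
                     byrow = TRUE, dimnames = list(NULL, STATE_ORDER))
  } else {
    dedup <- !duplicated(hours)
    f_ode <- function(t, y, parms) list(unname(liver_rhs(y, parms)))
    sol <- deSolve::lsoda(y = state0, times = hours[dedup], func = f_ode,
                          parms = params, rtol = 1e-8, atol = 1e-10)
    if (nrow(sol) < sum(dedup))
      stop(sprintf("integrator failed after t = %.3f h", sol[nrow(sol), 1]))
    states <- sol[match(hours, hours[dedup]), -1, drop = FALSE]
    colnames(states) <- STATE_ORDER
  }
  if (min(states) < -clip_tol)
    warning(sprintf("state undershoot %.3e clipped to 0", min(states)), call. = FALSE)
  states[states < 0] <- 0
  vol <- states[, "Q"] + params$h_P * states[, "P"] + params$h_R * states[, "R"]
  structure(list(times = hours, states = states, volume = vol,
                 params = params),
            class = "liver_trajectory")
}

#' @export
print.liver_trajectory <- function(x, ...) {
  cat(sprintf("<liver_trajectory> %d time points, %.2f h to %.2f h; final volume %.3f\n",
              length(x$times), min(x$times), max(x$times), tail(x$volume, 1)))
  invisible(x)
}

#' Simulate one patient over the study grid
#'
#' Pre-resection grid points carry the quiescent steady state; the resection
#' (fraction `f`) happens at hour 0 and post-resection points come from
#' integrating the resected state forward.
#'
#' @param params an [ode_params()].
#' @param f resected fraction.
#' @param grid a [time_grid()].
#' @return A `liver_trajectory` over all grid points.
#' @export
simulate_patient <- function(params, f, grid) {
  ss <- quiescent_steady_state(params)
  post <- post_op_idx(grid)
  s0 <- apply_resection(ss, f)
  sim <- simulate_liver(params, s0, c(0, grid$hours[post]))
  states <- matrix(rep(ss, length(grid$hours)), nrow = length(grid$hours),
                   byrow = TRUE, dimnames = list(grid$labels, STATE_ORDER))
  states[post, ] <- sim$states[-1, , drop = FALSE]
  vol <- states[, "Q"] + params$h_P * states[, "P"] + params$h_R * states[, "R"]
  structure(list(times = grid$hours, states = states, volume = vol,
                 params = params, f = f),
            class = "liver_trajectory")
}

#' Flatten a liver state to the fixed-order vector (and back)
#'
#' The component order `Q, P, R, TNF, IL6, STAT3, SOCS3, IE, GF, ECM` is the
#' interface contract with the neural maps.
#'
#' @param state named state vector (any order, all 10 components present).
#' @return Unnamed numeric vector of length 10.
#' @export
state_vector <- function(state) {
  if (length(state) != length(STATE_ORDER) ||
      !all(STATE_ORDER %in% names(state)))
    stop("state must contain exactly the components: ",
         paste(STATE_ORDER, collapse = ", "))
  unname(state[STATE_ORDER])
}

#' @rdname state_vector
#' @param x numeric vector of length 10 in the fixed order.
#' @export
vector_to_state <- function(x) {
  if (length(x) != length(STATE_ORDER))
    stop(sprintf("state vector must have length %d", length(STATE_ORDER)))
  stats::setNames(as.numeric(x), STATE_ORDER)
}
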