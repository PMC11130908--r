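## Model core: mass-action fluxes f1..f10, the six ODE right-hand sides,
## the (lower-triangular) system matrix, eigenvalue stability, closed-form
## steady state, and numerical time integration.
##
## State order everywhere: (mdC, hmdC, fdC, cadC, hmdU, U).
## Fluxes:
##   f1  = kDNMT1 * C * DNMT1          methylation influx
##   f2  = sum_{i in s1} k1TETi * mdC  * TETi
##   f3  = sum_{i in s2} k2TETi * hmdC * TETi
##   f4  = sum_{i in s3} k3TETi * fdC  * TETi
##   f5  = k4 * fdC                    5-fdC removal by BER
##   f6  = k5 * cadC                   5-cadC removal by BER
##   f7  = kAID_hmdC * hmdC * AID      deamination of 5-hmdC
##   f8  = kSMUG * hmdU * SMUG1        5-hmdU removal
##   f9  = kTDG * U * TDG              uracil removal
##   f10 = kAID_C * C * AID            deamination of the cytidine pool

## Per-reaction oxidation rate: sum over active TETs of k * enzyme level.
oxidation_rates <- function(enzymes, params, structure) {
  act <- structure_activity(structure)
  pref <- c("k1", "k2", "k3")
  vapply(1:3, function(r) {
    tets <- TET_NAMES[act[r, ]]
    sum(params[paste0(pref[r], tets)] * enzymes[tets])
  }, numeric(1))
}

## Total removal rate of each species (the negated Jacobian diagonal).
removal_rates <- function(enzymes, params, structure) {
  S <- oxidation_rates(enzymes, params, structure)
  c(mdC  = S[1],
    hmdC = S[2] + params[["kAID_hmdC"]] * enzymes[["AID"]],
    fdC  = S[3] + params[["k4"]],
    cadC = params[["k5"]],
    hmdU = params[["kSMUG"]] * enzymes[["SMUG1"]],
    U    = params[["kTDG"]] * enzymes[["TDG"]])
}

validate_model_inputs <- function(enzymes, params, C) {
  if (!is.numeric(C) || length(C) != 1 || !is.finite(C) || C <= 0)
    stop("cytidine pool C must be a single positive number", call. = FALSE)
  list(enzymes = as_enzyme_profile(enzymes), params = as_rate_parameters(params))
}

#' Evaluate the ten model fluxes
#'
#' Computes the mass-action fluxes f1..f10 at a given modification state,
#' enzyme profile and parameter set.  Oxidation fluxes f2, f3, f4 sum only
#' over the TETs active in the corresponding reaction of `structure`;
#' coefficients of masked TETs contribute nothing regardless of their
#' value.
#'
#' @param state A [modification_state()] (or named numeric with the six
#'   state variables).
#' @param enzymes An [enzyme_profile()].
#' @param params A [rate_parameters()] vector.
#' @param structure A [model_structure()].
#' @param C The unmodified-deoxycytidine pool, treated as an exogenous
#'   positive constant (default 1; the fitting convention absorbs it).
#' @return Named numeric vector `f1..f10`, all non-negative for valid
#'   inputs.
#' @examples
#' compute_fluxes(modification_state(mdC = 2),
#'                enzyme_profile(1, 1, 1, 1, 1, 1, 1),
#'                rate_parameters(k1TET1 = 1, k1TET2 = 1, k1TET3 = 1),
#'                full_structure())
#' @export
compute_fluxes <- function(state, enzymes, params, structure, C = 1) {
  v <- validate_model_inputs(enzymes, params, C)
  enzymes <- v$enzymes; params <- v$params
  state <- as_modification_state(state)
  S <- oxidation_rates(enzymes, params, structure)
  f <- c(f1  = params[["kDNMT1"]] * C * enzymes[["DNMT1"]],
         f2  = S[1] * state[["mdC"]],
         f3  = S[2] * state[["hmdC"]],
         f4  = S[3] * state[["fdC"]],
         f5  = params[["k4"]] * state[["fdC"]],
         f6  = params[["k5"]] * state[["cadC"]],
         f7  = params[["kAID_hmdC"]] * state[["hmdC"]] * enzymes[["AID"]],
         f8  = params[["kSMUG"]] * state[["hmdU"]] * enzymes[["SMUG1"]],
         f9  = params[["kTDG"]] * state[["U"]] * enzymes[["TDG"]],
         f10 = params[["kAID_C"]] * C * enzymes[["AID"]])
  f
}

#' Time derivatives of the six state variables
#'
#' Right-hand sides of the six ODEs, each the balance of production and
#' removal fluxes:
#' `(f1 - f2, f2 - f3 - f7, f3 - f4 - f5, f4 - f6, f7 - f8, f10 - f9)`.
#' The uracil equation follows the production-minus-removal convention
#' (AID produces U from the cytidine pool, TDG removes it), consistent
#' with the other five equations; at steady state (f9 = f10) the sign
#' convention is immaterial.
#'
#' @inheritParams compute_fluxes
#' @return Named numeric vector of the six derivatives, state order.
#' @export
time_derivatives <- function(state, enzymes, params, structure, C = 1) {
  f <- compute_fluxes(state, enzymes, params, structure, C)
  d <- c(f[["f1"]] - f[["f2"]],
         f[["f2"]] - f[["f3"]] - f[["f7"]],
         f[["f3"]] - f[["f4"]] - f[["f5"]],
         f[["f4"]] - f[["f6"]],
         f[["f7"]] - f[["f8"]],
         f[["f10"]] - f[["f9"]])
  names(d) <- STATE_NAMES
  d
}

#' System matrix (Jacobian) of the linear model
#'
#' The Jacobian of [time_derivatives()] with respect to the state.  The
#' model is linear in the state, so this matrix fully determines the
#' dynamics up to the constant inflows f1 and f10.  In the canonical state
#' order it is lower triangular, with diagonal entries equal to minus the
#' total removal rate of each species; its eigenvalues are therefore the
#' diagonal entries, all real.
#'
#' @inheritParams compute_fluxes
#' @return A 6 x 6 matrix with state names on both dimensions.
#' @export
system_matrix <- function(enzymes, params, structure) {
  v <- validate_model_inputs(enzymes, params, 1)
  enzymes <- v$enzymes; params <- v$params
  S <- oxidation_rates(enzymes, params, structure)
  aA <- params[["kAID_hmdC"]] * enzymes[["AID"]]
  J <- matrix(0, 6, 6, dimnames = list(STATE_NAMES, STATE_NAMES))
  J["mdC",  "mdC"]  <- -S[1]
  J["hmdC", "mdC"]  <-  S[1]
  J["hmdC", "hmdC"] <- -(S[2] + aA)
  J["fdC",  "hmdC"] <-  S[2]
  J["fdC",  "fdC"]  <- -(S[3] + params[["k4"]])
  J["cadC", "fdC"]  <-  S[3]
  J["cadC", "cadC"] <- -params[["k5"]]
  J["hmdU", "hmdC"] <-  aA
  J["hmdU", "hmdU"] <- -params[["kSMUG"]] * enzymes[["SMUG1"]]
  J["U",    "U"]    <- -params[["kTDG"]] * enzymes[["TDG"]]
  J
}

#' Eigenvalue stability report for the system matrix
#'
#' Computes the six eigenvalues of [system_matrix()] and reports whether
#' the steady state is asymptotically stable (all real parts negative) and
#' whether the dynamics are aperiodic (all eigenvalues real).  For strictly
#' positive parameters and enzyme levels, with every removal channel
#' present, both flags are true; a species with zero total removal rate
#' yields a zero eigenvalue and `stable = FALSE` (reported, not raised).
#'
#' @inheritParams compute_fluxes
#' @return A list of class `"stability_report"` with elements
#'   `eigenvalues` (real parts, named by species for the triangular
#'   ordering), `stable`, `aperiodic`.
#' @export
check_stability <- function(enzymes, params, structure) {
  J <- system_matrix(enzymes, params, structure)
  ev <- eigen(J, only.values = TRUE)$values
  tol <- 1e-12 * max(1, max(abs(ev)))
  out <- list(eigenvalues = ev,
              stable = all(Re(ev) < 0),
              aperiodic = all(abs(Im(ev)) <= tol))
  class(out) <- "stability_report"
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Eigenvalues:", paste(format(x$eigenvalues, digits = 4), collapse = ", "),
      "\nStable:", x$stable, " Aperiodic:", x$aperiodic, "\n")
  invisible(x)
}

#' Closed-form steady state
#'
#' Solves the six steady-state flux balances
#' `f1 = f2, f2 = f3 + f7, f3 = f4 + f5, f4 = f6, f7 = f8, f9 = f10`
#' by cascading them down the (triangular) pathway: the methylation influx
#' f1 fixes mdC*, which fixes the flux into hmdC*, and so on through the
#' oxidation and deamination branches.  The steady state exists and is
#' unique iff every species has a strictly positive total removal rate.
#'
#' @inheritParams compute_fluxes
#' @param partial If `TRUE`, species whose steady level is undefined
#'   (zero total removal rate, or dependent on such a species) are
#'   returned as `NA` instead of raising an error.
#' @return A [modification_state()]; with `partial = TRUE` possibly
#'   containing `NA`s.
#' @export
steady_state <- function(enzymes, params, structure, C = 1, partial = FALSE) {
  v <- validate_model_inputs(enzymes, params, C)
  enzymes <- v$enzymes; params <- v$params
  r <- removal_rates(enzymes, params, structure)
  if (!partial && any(r <= 0)) {
    bad <- names(r)[r <= 0][1]
    stop(errorCondition(
      sprintf("no finite steady state: %s has zero total removal rate", bad),
      class = c("tetflux_no_steady_state", "error", "condition")))
  }
  S <- oxidation_rates(enzymes, params, structure)
  safe_div <- function(num, den) if (is.na(num) || den <= 0) NA_real_ else num / den
  F1 <- params[["kDNMT1"]] * C * enzymes[["DNMT1"]]
  mdC  <- safe_div(F1, r[["mdC"]])
  hmdC <- safe_div(F1, r[["hmdC"]])
  f3   <- if (is.na(hmdC)) NA_real_ else S[2] * hmdC
  fdC  <- safe_div(f3, r[["fdC"]])
  f4   <- if (is.na(fdC)) NA_real_ else S[3] * fdC
  cadC <- safe_div(f4, r[["cadC"]])
  f7   <- if (is.na(hmdC)) NA_real_ else
    params[["kAID_hmdC"]] * hmdC * enzymes[["AID"]]
  hmdU <- safe_div(f7, r[["hmdU"]])
  U    <- safe_div(params[["kAID_C"]] * C * enzymes[["AID"]], r[["U"]])
  x <- c(mdC = mdC, hmdC = hmdC, fdC = fdC, cadC = cadC, hmdU = hmdU, U = U)
  class(x) <- "modification_state"
  x
}

#' Integrate the model in time
#'
#' Numerical solution of the six linear ODEs from an arbitrary
#' non-negative initial state, using a stiff-capable integrator
#' (`deSolve::ode`, method `"lsoda"`, rtol 1e-8, atol 1e-12).  For
#' positive parameters the trajectory converges, without oscillation, to
#' the [steady_state()].
#'
#' @param initial Initial [modification_state()].
#' @inheritParams compute_fluxes
#' @param horizon Positive end time of the integration.
#' @param n_points Number of output time points (>= 2), evenly spaced
#'   from 0 to `horizon`.
#' @param rtol,atol Integrator tolerances.
#' @return A data frame with a `time` column followed by the six state
#'   columns.
#' @export
simulate_model <- function(initial, enzymes, params, structure, C = 1,
                           horizon, n_points = 101,
                           rtol = 1e-8, atol = 1e-12) {
  if (!is.numeric(horizon) || horizon <= 0) stop("horizon must be > 0")
  if (n_points < 2) stop("n_points must be >= 2")
  v <- validate_model_inputs(enzymes, params, C)
  enzymes <- v$enzymes; params <- v$params
  y0 <- as_modification_state(initial)
  times <- seq(0, horizon, length.out = n_points)
  rhs <- function(t, y, p) {
    names(y) <- STATE_NAMES
    class(y) <- "modification_state"
    list(unname(time_derivatives(y, enzymes, params, structure, C)))
  }
  sol <- deSolve::ode(y = unname(unclass(y0)), times = times, func = rhs,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(sol, "istate")[1], ")")
  out <- as.data.frame(sol)
  names(out) <- c("time", STATE_NAMES)
  out
}
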