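#' Create a species state
#'
#' A named concentration vector (nM) over the nine tracked species, in the
#' fixed ordering E, S, ES, EP, P, I, PI, EPI, PIE: free enzyme TF:VIIa
#' (E), factor X (S), the Michaelis complex TF:VIIa:X (ES), the
#' product complex TF:VIIa:Xa (EP), free factor Xa (P), free TFPI (I),
#' the solution-phase Xa:TFPI complex (PI), the transient quaternary
#' complex TF:VIIa:Xa:TFPI (EPI), and its tight conformation (PIE).
#'
#' @param E,S,ES,EP,P,I,PI,EPI,PIE concentrations in nM, all >= 0.
#' @return Named numeric vector of length nine.
#' @export
#' @examples
#' species_state(E = 0.128, S = 170, I = 2.4)
species_state <- function(E = 0, S = 0, ES = 0, EP = 0, P = 0,
                          I = 0, PI = 0, EPI = 0, PIE = 0) {
  x <- c(E = E, S = S, ES = ES, EP = EP, P = P,
         I = I, PI = PI, EPI = EPI, PIE = PIE)
  validate_state(x)
  x
}

validate_state <- function(x, allow_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 9L || !identical(names(x), SPECIES))
    stop("a species state must be a named numeric vector over ",
         paste(SPECIES, collapse = ", "), call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-finite species concentration", call. = FALSE)
  if (!allow_negative && any(x < 0))
    stop("negative species concentration: ",
         paste(names(x)[x < 0], collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Mass-action derivatives of the closed (static) system
#'
#' Evaluates the instantaneous rate of change (nM/s) of each of the nine
#' species in a well-mixed closed solution under the elementary-reaction
#' scheme: reversible binding of X and Xa to TF:VIIa (reactions 1, 3),
#' catalysis (2), solution-phase Xa:TFPI formation (4), TFPI capture of
#' Xa held in TF:VIIa:Xa (6), the conformational change to the tight
#' quaternary complex (7), and Xa:TFPI binding to TF:VIIa (8).  The terms
#' of the removed double-binding reaction 5 are retained in the algebra
#' and vanish at the default zero rates.
#'
#' @param state species state (see \code{\link{species_state}}); transient
#'   solver iterates may be slightly negative, so negativity is not
#'   rejected here.
#' @param rates a \code{\link{rate_set}}.
#' @return Named numeric vector of the nine derivatives, nM/s.
#' @export
static_rhs <- function(state, rates) {
  validate_state(state, allow_negative = TRUE)
  validate_rate_set(rates)
  mass_action_rhs(state, unclass(rates))
}

# plain-R reference implementation of the mass-action algebra; the
# compiled derivatives used by the integrator must agree with this exactly
mass_action_rhs <- function(y, k) {
  r1  <- k[["k_plus_1"]]  * y[["E"]]  * y[["S"]]
  rm1 <- k[["k_minus_1"]] * y[["ES"]]
  r2  <- k[["k_plus_2"]]  * y[["ES"]]
  r3  <- k[["k_plus_3"]]  * y[["E"]]  * y[["P"]]
  rm3 <- k[["k_minus_3"]] * y[["EP"]]
  r4  <- k[["k_plus_4"]]  * y[["P"]]  * y[["I"]]
  rm4 <- k[["k_minus_4"]] * y[["PI"]]
  r5  <- k[["k_plus_5"]]  * y[["E"]]  * y[["PI"]]
  rm5 <- k[["k_minus_5"]] * y[["PIE"]]
  r6  <- k[["k_plus_6"]]  * y[["EP"]] * y[["I"]]
  rm6 <- k[["k_minus_6"]] * y[["EPI"]]
  r7  <- k[["k_plus_7"]]  * y[["EPI"]]
  rm7 <- k[["k_minus_7"]] * y[["PIE"]]
  r8  <- k[["k_plus_8"]]  * y[["E"]]  * y[["PI"]]
  rm8 <- k[["k_minus_8"]] * y[["EPI"]]
  c(E   = -r1 + rm1 - r3 + rm3 - r5 + rm5 - r8 + rm8,
    S   = -r1 + rm1,
    ES  =  r1 - rm1 - r2,
    EP  =  r2 + r3 - rm3 - r6 + rm6,
    P   = -r3 + rm3 - r4 + rm4,
    I   = -r4 + rm4 - r6 + rm6,
    PI  =  r4 - rm4 - r5 + rm5 - r8 + rm8,
    EPI =  r6 - rm6 - r7 + rm7 + r8 - rm8,
    PIE =  r5 - rm5 + r7 - rm7)
}

# default solver tolerances: tight enough that moiety conservation holds
# to 1e-8 nM despite the stiffness (k_plus_7 ~ 361 s^-1 next to
# k_minus_4 ~ 1e-4 s^-1)
ODE_RTOL <- 1e-8
ODE_ATOL <- 1e-12

# undershoot below this (nM) is treated as solver misconfiguration
NEG_TOL <- -1e-9

solve_ode <- function(y0, times, func, parms, rtol = ODE_RTOL,
                      atol = ODE_ATOL) {
  out <- deSolve::lsoda(
    y = y0, times = times, func = func, parms = parms,
    dllname = "tfpiflow",
    initfunc = sub("derivs", "init", func),
    rtol = rtol, atol = atol, maxsteps = 50000L
  )
  if (nrow(out) < length(times))
    stop("ODE integration failed near t = ",
         signif(out[nrow(out), 1L], 6), " s", call. = FALSE)
  mat <- out[, -1L, drop = FALSE]
  if (min(mat) < NEG_TOL)
    stop("integration produced a concentration below ", NEG_TOL,
         " nM (min ", signif(min(mat), 4),
         "); solver settings are suspect", call. = FALSE)
  mat
}

#' Simulate the static system
#'
#' Integrates the closed well-mixed system with a stiff solver (lsoda,
#' relative tolerance 1e-8, absolute tolerance 1e-12 nM) and returns the
#' trajectory at the requested times.
#'
#' @param initial initial \code{\link{species_state}}, nonnegative.
#' @param rates a \code{\link{rate_set}}.
#' @param times output times in seconds, sorted ascending, first >= 0.
#'   A leading 0 is prepended internally if absent so the integration
#'   always starts from the initial condition.
#' @return A \code{tfpi_trajectory}: data frame with column \code{time_s}
#'   followed by one column per species (nM).
#' @export
#' @examples
#' tr <- simulate_static(species_state(E = 0.128, S = 170, I = 2.4),
#'                       table1_rates(), times = seq(0, 720, by = 60))
#' tail(tr, 2)
simulate_static <- function(initial, rates, times) {
  validate_state(initial)
  validate_rate_set(rates)
  check_times(times)
  simulate_with(initial, times, "tfpi_derivs_static", unclass(rates))
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)))
    stop("times must be finite numeric", call. = FALSE)
  if (times[1L] < 0 || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing with first entry >= 0",
         call. = FALSE)
}

simulate_with <- function(initial, times, func, parms) {
  solve_times <- if (times[1L] > 0) c(0, times) else times
  mat <- solve_ode(unname(initial), solve_times, func, parms)
  if (times[1L] > 0) mat <- mat[-1L, , drop = FALSE]
  colnames(mat) <- SPECIES
  out <- data.frame(time_s = times, mat, check.names = FALSE)
  class(out) <- c("tfpi_trajectory", "data.frame")
  out
}

#' Conserved moiety totals of a state
#'
#' The closed reaction scheme conserves three totals: the enzyme moiety
#' (all species containing TF:VIIa), the factor X moiety (X plus every
#' species containing X or Xa) and the TFPI moiety.
#'
#' @param state a \code{\link{species_state}} or a \code{tfpi_trajectory};
#'   for a trajectory the totals are evaluated row-wise.
#' @return Named vector \code{c(enzyme, factor_x, tfpi)} in nM, or a data
#'   frame with those columns plus \code{time_s} for a trajectory.
#' @export
conserved_totals <- function(state) {
  if (inherits(state, "tfpi_trajectory")) {
    m <- as.matrix(state[SPECIES])
    return(data.frame(
      time_s = state$time_s,
      enzyme   = rowSums(m[, c("E", "ES", "EP", "EPI", "PIE"), drop = FALSE]),
      factor_x = rowSums(m[, c("S", "ES", "EP", "P", "PI", "EPI", "PIE"),
                           drop = FALSE]),
      tfpi     = rowSums(m[, c("I", "PI", "EPI", "PIE"), drop = FALSE])
    ))
  }
  validate_state(state, allow_negative = TRUE)
  c(enzyme   = sum(state[c("E", "ES", "EP", "EPI", "PIE")]),
    factor_x = sum(state[c("S", "ES", "EP", "P", "PI", "EPI", "PIE")]),
    tfpi     = sum(state[c("I", "PI", "EPI", "PIE")]))
}

#' Write / read a trajectory CSV
#'
#' Trajectories are persisted with header
#' \code{time_s,E,S,ES,EP,P,I,PI,EPI,PIE}, one row per time point, all
#' concentrations in nM, 12 significant digits.
#'
#' @param traj a \code{tfpi_trajectory}.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "tfpi_trajectory"))
  out <- traj
  for (cl in names(out)) out[[cl]] <- signif(out[[cl]], 12)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- read.csv(path, check.names = FALSE)
  expected <- c("time_s", SPECIES)
  if (!identical(names(out), expected))
    stop("trajectory file must have header ",
         paste(expected, collapse = ","), call. = FALSE)
  class(out) <- c("tfpi_trajectory", "data.frame")
  out
}
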