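#' Flow configuration for the reaction-zone model
#'
#' The flow model treats the injury site as a well-mixed reaction zone
#' exchanging material with upstream plasma at a single mass-transfer rate
#' \code{k_flow}.  Factor X and TFPI are carried in at their upstream
#' concentrations and free X, Xa, TFPI and the Xa:TFPI complex are washed
#' out; the enzyme species stay anchored at the injury site.
#'
#' @param k_flow mass-transfer rate, s^-1, >= 0.
#' @param S_up upstream factor X concentration, nM (default 170, plasma
#'   level used throughout the experiments).
#' @param I_up upstream TFPI concentration, nM (default 2.4).
#' @return An object of class \code{flow_config}.
#' @export
flow_config <- function(k_flow, S_up = 170, I_up = 2.4) {
  if (!is.numeric(k_flow) || length(k_flow) != 1L || !is.finite(k_flow) ||
      k_flow < 0)
    stop("k_flow must be a single finite nonnegative number", call. = FALSE)
  if (S_up < 0 || I_up < 0)
    stop("upstream concentrations must be nonnegative", call. = FALSE)
  structure(list(k_flow = k_flow, S_up = S_up, I_up = I_up),
            class = "flow_config")
}

#' Vessel geometry for deriving the mass-transfer rate
#'
#' @param V midstream velocity, micrometers/s.
#' @param L injury length, micrometers (default 10).
#' @param D molecular diffusivity, micrometers^2/s (default 50, the
#'   reported value for proteins of 40-60 kDa).
#' @param R vessel radius, micrometers.
#' @return An object of class \code{vessel_geometry}.
#' @export
vessel_geometry <- function(V, L = 10, D = 50, R) {
  g <- list(V = V, L = L, D = D, R = R)
  bad <- names(g)[!vapply(g, function(z)
    is.numeric(z) && length(z) == 1L && is.finite(z) && z > 0, logical(1))]
  if (length(bad))
    stop("vessel geometry fields must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(g, class = "vessel_geometry")
}

#' Mass-transfer rate from vessel geometry
#'
#' Computes k_flow = (3/4) * (V^2 * D / (R*L)^2)^(1/3), the combined
#' flow-and-diffusion transfer coefficient of the reaction zone.  Applied
#' to reported velocities and radii from arteries to veins with D = 50
#' um^2/s and L = 10 um this yields the physiological range of roughly
#' 1e-3 to 1e3 s^-1.
#'
#' @param geom a \code{\link{vessel_geometry}}.
#' @return Mass-transfer rate in s^-1.
#' @export
#' @examples
#' kflow_from_vessel(vessel_geometry(V = 1000, R = 1000))
kflow_from_vessel <- function(geom) {
  if (!inherits(geom, "vessel_geometry"))
    stop("geom must be a vessel_geometry", call. = FALSE)
  0.75 * (geom$V^2 * geom$D / (geom$R * geom$L)^2)^(1 / 3)
}

# which reactions each inhibition pathway removes from the full scheme
VARIANT_NULLIFIED <- list(
  NI  = c(4L, 5L, 6L, 7L, 8L),  # product inhibition only (reactions 1-3)
  DB  = c(4L, 5L),              # direct binding via 6 -> 7
  IB  = c(5L, 6L),              # indirect binding via 4 -> 8 -> 7
  DIB = 5L                      # both pathways active
)

#' Inhibition-pathway variant
#'
#' The four pathway variants of the flow analysis: \code{NI} (no TFPI:
#' reactions 1-3 only, inhibition by the product Xa alone), \code{DB}
#' (direct binding of TFPI to enzyme-bound Xa), \code{IB} (indirect
#' binding via the solution-phase Xa:TFPI complex) and \code{DIB} (both
#' pathways).  Reaction 5 is nullified in all variants.
#'
#' @param label one of "NI", "DB", "IB", "DIB".
#' @return An object of class \code{pathway_variant} with fields
#'   \code{label} and \code{nullified_reactions}.
#' @export
pathway_variant <- function(label) {
  if (!is.character(label) || length(label) != 1L ||
      !label %in% names(VARIANT_NULLIFIED))
    stop("unknown pathway variant; use one of ",
         paste(names(VARIANT_NULLIFIED), collapse = ", "), call. = FALSE)
  structure(list(label = label,
                 nullified_reactions = VARIANT_NULLIFIED[[label]]),
            class = "pathway_variant")
}

#' Restrict a rate set to an inhibition pathway
#'
#' Returns a copy of \code{rates} with the forward and reverse constants
#' of every reaction absent from the chosen pathway set to zero.
#'
#' @param rates a \code{\link{rate_set}}.
#' @param variant a \code{\link{pathway_variant}} or its label.
#' @return A \code{rate_set}.
#' @export
#' @examples
#' apply_pathway_variant(table1_rates(), "NI")
apply_pathway_variant <- function(rates, variant) {
  if (is.character(variant)) variant <- pathway_variant(variant)
  if (!inherits(variant, "pathway_variant"))
    stop("variant must be a pathway_variant or label", call. = FALSE)
  nullify_reactions(rates, variant$nullified_reactions)
}

#' Mass-action derivatives of the flow system
#'
#' The static derivatives plus flow exchange: \code{k_flow*(S_up - S)} on
#' factor X, \code{-k_flow*P} on Xa, \code{k_flow*(I_up - I)} on TFPI and
#' \code{-k_flow*PI} on Xa:TFPI.  The enzyme species carry no flow terms,
#' so the enzyme moiety remains conserved under flow.
#'
#' @param state species state, nM.
#' @param rates a \code{\link{rate_set}}.
#' @param flow a \code{\link{flow_config}}.
#' @return Named numeric vector of derivatives, nM/s.
#' @export
flow_rhs <- function(state, rates, flow) {
  stopifnot(inherits(flow, "flow_config"))
  d <- static_rhs(state, rates)
  d[["S"]]  <- d[["S"]] + flow$k_flow * (flow$S_up - state[["S"]])
  d[["P"]]  <- d[["P"]] - flow$k_flow * state[["P"]]
  d[["I"]]  <- d[["I"]] + flow$k_flow * (flow$I_up - state[["I"]])
  d[["PI"]] <- d[["PI"]] - flow$k_flow * state[["PI"]]
  d
}

#' Simulate the flow system
#'
#' @inheritParams simulate_static
#' @param flow a \code{\link{flow_config}}.
#' @return A \code{tfpi_trajectory}.
#' @export
simulate_flow <- function(initial, rates, flow, times) {
  validate_state(initial)
  validate_rate_set(rates)
  stopifnot(inherits(flow, "flow_config"))
  check_times(times)
  parms <- c(unclass(rates), k_flow = flow$k_flow,
             S_up = flow$S_up, I_up = flow$I_up)
  simulate_with(initial, times, "tfpi_derivs_flow", parms)
}

#' Functional-enzyme metric
#'
#' The concentration of enzyme still able to activate factor X: free
#' TF:VIIa plus the Michaelis complex, E + E:S.  A value equal to the
#' initial enzyme amount means no inhibition; zero means complete
#' inhibition.
#'
#' @param state a \code{\link{species_state}} or \code{tfpi_trajectory}.
#' @return E + ES in nM (a vector for a trajectory).
#' @export
e_functional <- function(state) {
  if (inherits(state, "tfpi_trajectory")) return(state$E + state$ES)
  validate_state(state, allow_negative = TRUE)
  state[["E"]] + state[["ES"]]
}

#' Steady state of the flow system
#'
#' Finds the steady state reached from the standard start (all enzyme
#' free, every other species zero).  The stiff system is integrated over
#' geometrically growing horizons until the residual is small, then
#' polished by a damped Newton iteration on the algebraic system in which
#' the (conserved, hence degenerate) free-enzyme balance is replaced by
#' the enzyme-moiety constraint.  Convergence requires every component of
#' the flow right-hand side to be below \code{tol} in absolute value.
#'
#' @param rates a \code{\link{rate_set}}.
#' @param flow a \code{\link{flow_config}} with \code{k_flow > 0}.
#' @param enzyme_total initial (and conserved) enzyme amount, nM, > 0.
#' @param tol residual tolerance, nM/s.
#' @return The steady \code{\link{species_state}}.
#' @export
#' @examples
#' ni <- apply_pathway_variant(table1_rates(), "NI")
#' ss <- steady_state(ni, flow_config(k_flow = 1), enzyme_total = 1)
#' e_functional(ss)  # ~0.92 nM of enzyme survives at medium flow
steady_state <- function(rates, flow, enzyme_total, tol = 1e-10) {
  validate_rate_set(rates)
  stopifnot(inherits(flow, "flow_config"))
  if (flow$k_flow <= 0)
    stop("steady_state requires k_flow > 0", call. = FALSE)
  if (enzyme_total <= 0)
    stop("enzyme_total must be > 0", call. = FALSE)

  state <- species_state(E = enzyme_total)
  resid <- function(x) flow_rhs(stats::setNames(x, SPECIES), rates, flow)

  # Newton residual with the (degenerate) free-enzyme balance replaced
  # by the enzyme-moiety constraint
  enzyme_idx <- match(c("E", "ES", "EP", "EPI", "PIE"), SPECIES)
  Ffun <- function(x) {
    f <- unname(resid(x))
    f[1L] <- sum(x[enzyme_idx]) - enzyme_total
    f
  }
  newton <- function(x) {
    for (iter in 1:50) {
      Fx <- Ffun(x)
      if (max(abs(resid(x))) < tol && abs(Fx[1L]) < tol) return(x)
      J <- num_jacobian(Ffun, x)
      step <- tryCatch(qr.solve(J, -Fx), error = function(e) NULL)
      if (is.null(step)) return(x)
      lambda <- 1
      repeat {
        xn <- x + lambda * step
        if (min(xn) >= NEG_TOL &&
            sum(abs(Ffun(xn))) <= sum(abs(Fx)) * (1 - 1e-4 * lambda) + tol) {
          x <- pmax(xn, 0)
          break
        }
        lambda <- lambda / 2
        if (lambda < 1e-10) return(pmax(x, 0))
      }
    }
    x
  }

  # alternate relaxation by stiff integration (horizons growing past the
  # slowest scales, 1/k_flow and 1/k_minus_4) with Newton polishing
  parms <- c(unclass(rates), k_flow = flow$k_flow,
             S_up = flow$S_up, I_up = flow$I_up)
  horizon <- max(100, 10 / flow$k_flow)
  x <- unname(state)
  for (round in 1:14) {
    mat <- solve_ode(x, c(0, horizon), "tfpi_derivs_flow", parms)
    x <- pmax(mat[2L, ], 0)
    if (max(abs(resid(x))) < 10) {
      x <- newton(x)
      if (max(abs(resid(x))) < tol) break
    }
    horizon <- horizon * 10
  }
  out <- stats::setNames(x, SPECIES)
  if (max(abs(resid(out))) >= tol)
    stop("steady_state failed to converge: residual ",
         signif(max(abs(resid(out))), 4), " nM/s at k_flow = ",
         flow$k_flow, call. = FALSE)
  out
}

num_jacobian <- function(f, x, eps = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (f(xp) - f0) / h
  }
  J
}

#' Steady-state functional enzyme across flow rates
#'
#' Computes the steady-state E + E:S of a pathway variant at each point
#' of a grid of mass-transfer rates, as in the steady-state inhibition
#' analysis from low (1e-3 s^-1) to high (1e3 s^-1) flow.
#'
#' @param rates a \code{\link{rate_set}} (full scheme; the variant is
#'   applied internally).
#' @param variant a \code{\link{pathway_variant}} or label.
#' @param kflow_grid positive mass-transfer rates, s^-1; defaults to 25
#'   log-spaced points over 1e-3..1e3.
#' @param flow a \code{\link{flow_config}} providing the upstream
#'   concentrations (its \code{k_flow} is ignored).
#' @param enzyme_total enzyme amount, nM.
#' @return Data frame with columns \code{variant}, \code{k_flow_per_s},
#'   \code{E_functional_nM}.
#' @export
flow_sweep <- function(rates, variant, kflow_grid = default_kflow_grid(),
                       flow = flow_config(k_flow = 1),
                       enzyme_total = 1) {
  if (is.character(variant)) variant <- pathway_variant(variant)
  if (any(kflow_grid <= 0))
    stop("kflow_grid must be strictly positive", call. = FALSE)
  vrates <- apply_pathway_variant(rates, variant)
  ef <- vapply(kflow_grid, function(kf) {
    ss <- tryCatch(
      steady_state(vrates, flow_config(kf, flow$S_up, flow$I_up),
                   enzyme_total),
      error = function(e)
        stop("flow_sweep failed at k_flow = ", kf, ": ",
             conditionMessage(e), call. = FALSE))
    e_functional(ss)
  }, numeric(1))
  data.frame(variant = variant$label, k_flow_per_s = kflow_grid,
             E_functional_nM = ef)
}

#' @rdname flow_sweep
#' @export
default_kflow_grid <- function() 10^seq(-3, 3, length.out = 25L)

#' Product-inhibition sweep
#'
#' Repeats the no-TFPI (NI) flow sweep with the Xa unbinding rate
#' k_minus_3 divided by each scaling factor phi while k_plus_3 stays at
#' its median, i.e. with the product dissociation constant K_D_3 scaled
#' to K_D_3/phi.  Used to ask how tightly Xa would have to bind TF:VIIa
#' for product inhibition alone to rival the direct TFPI pathway.
#'
#' @param rates a \code{\link{rate_set}}.
#' @param phi_values positive dimensionless scale factors (default
#'   1, 10, 100, 1000, giving K_D_3 = 520, 52, 5.2, 0.52 nM at the
#'   median rates).
#' @inheritParams flow_sweep
#' @return Data frame with columns \code{variant}, \code{phi},
#'   \code{k_flow_per_s}, \code{E_functional_nM}.
#' @export
product_inhibition_sweep <- function(rates,
                                     phi_values = c(1, 10, 100, 1000),
                                     kflow_grid = default_kflow_grid(),
                                     flow = flow_config(k_flow = 1),
                                     enzyme_total = 1) {
  if (any(phi_values <= 0))
    stop("phi_values must be strictly positive", call. = FALSE)
  out <- lapply(phi_values, function(phi) {
    r <- unclass(rates)
    r[["k_minus_3"]] <- r[["k_minus_3"]] / phi
    sw <- flow_sweep(structure(r, class = "rate_set"), "NI", kflow_grid,
                     flow, enzyme_total)
    cbind(variant = sw$variant, phi = phi, sw[, -1L, drop = FALSE])
  })
  do.call(rbind, out)
}
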