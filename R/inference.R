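# fixed constants of the constrained parameterization
K_M_FIXED  <- 238      # Michaelis constant for X activation by TF:VIIa, nM
K_D3_FIXED <- 520      # Xa / TF:VIIa dissociation constant, nM
K_D4_FIXED <- 2.63e-2  # Xa / TFPI dissociation constant, nM

FREE_PARAMS_FULL <- c("k_plus_1", "k_plus_2", "k_plus_3", "k_plus_4",
                      "k_plus_6", "k_minus_6", "k_plus_7", "k_minus_7",
                      "k_plus_8", "k_minus_8", "sigma")

#' Bounds of the free parameter vector
#'
#' The sampler works on the free vector theta = (k_plus_1, k_plus_2,
#' k_plus_3, k_plus_4, k_plus_6, k_minus_6, k_plus_7, k_minus_7,
#' k_plus_8, k_minus_8, sigma); the remaining rates are derived:
#' k_minus_1 = K_M*k_plus_1 - k_plus_2 (Michaelis relationship with
#' K_M = 238 nM fixed), k_minus_3 = 520*k_plus_3 and k_minus_4 =
#' 2.63e-2*k_plus_4 (fixed dissociation constants).  Bimolecular forward
#' rates are capped at the diffusion limit 1 nM^-1 s^-1; reverse rates
#' and the conformational rate k_plus_7 at 500 s^-1; the reverse
#' conformational rate k_minus_7 at 1e-2 s^-1 (the tight complex is
#' long-lived); k_plus_2 at K_M so that k_minus_1 can stay nonnegative;
#' the proportional-error scale sigma at 1.  All lower bounds are open
#' at 0.
#'
#' @param model "full" or "no_reaction_7" (the alternative scheme, which
#'   drops k_plus_7 and k_minus_7 from the free vector and fixes them
#'   at 0).
#' @return Data frame with columns \code{lower} and \code{upper}, row
#'   names the free parameter names.
#' @export
param_bounds <- function(model = c("full", "no_reaction_7")) {
  model <- match.arg(model)
  b <- data.frame(
    lower = rep(0, 11L),
    upper = c(1, K_M_FIXED, 1, 1, 1, 500, 500, 1e-2, 1, 500, 1),
    row.names = FREE_PARAMS_FULL
  )
  if (model == "no_reaction_7")
    b <- b[setdiff(FREE_PARAMS_FULL, c("k_plus_7", "k_minus_7")), ]
  b
}

#' Expand a free parameter vector into a full rate set
#'
#' @param theta named free vector (see \code{\link{param_bounds}}; the
#'   \code{sigma} entry is ignored here).
#' @param model "full" or "no_reaction_7".
#' @return A \code{\link{rate_set}} with the derived reverse rates filled
#'   in and reaction 5 nullified.
#' @export
theta_to_rates <- function(theta, model = c("full", "no_reaction_7")) {
  model <- match.arg(model)
  th <- as.list(theta)
  k7  <- if (model == "full") th$k_plus_7  else 0
  km7 <- if (model == "full") th$k_minus_7 else 0
  rate_set(
    k_plus_1 = th$k_plus_1,
    k_minus_1 = K_M_FIXED * th$k_plus_1 - th$k_plus_2,
    k_plus_2 = th$k_plus_2,
    k_plus_3 = th$k_plus_3, k_minus_3 = K_D3_FIXED * th$k_plus_3,
    k_plus_4 = th$k_plus_4, k_minus_4 = K_D4_FIXED * th$k_plus_4,
    k_plus_6 = th$k_plus_6, k_minus_6 = th$k_minus_6,
    k_plus_7 = k7, k_minus_7 = km7,
    k_plus_8 = th$k_plus_8, k_minus_8 = th$k_minus_8
  )
}

# TRUE iff theta lies inside the open/closed bounded box and satisfies
# the derived-rate constraint k_minus_1 >= 0 (i.e. k_plus_1 >= k_plus_2/K_M)
theta_in_bounds <- function(theta, bounds) {
  all(theta > bounds$lower) && all(theta <= bounds$upper) &&
    K_M_FIXED * theta[["k_plus_1"]] - theta[["k_plus_2"]] >= 0
}

#' Proportional-error log-likelihood
#'
#' The measurements are modelled as independent normal deviates around
#' the model prediction with standard deviation proportional to it:
#' A(t_i) ~ N(mu(t_i|theta), sigma*mu(t_i|theta)).  The total
#' log-likelihood is the sum over all measurements of both experiments.
#' Predictions are obtained by simulating each condition's protocol
#' (including the two-hour pre-incubation for Experiment Two) once per
#' evaluation.
#'
#' @param theta named free parameter vector including \code{sigma}.
#' @param data a \code{tfpi_dataset} (see \code{\link{as_dataset}}) or a
#'   pre-split series list from the internal splitter (used by the
#'   samplers to avoid re-splitting at every iteration).
#' @param model "full" or "no_reaction_7".
#' @param mapping observable mapping, see \code{\link{predict_observable}}.
#' @return Log-likelihood; \code{-Inf} if theta violates its bounds or a
#'   predicted mean is nonpositive at a measurement time.
#' @export
log_likelihood <- function(theta, data, model = "full", mapping = "P") {
  series <- if (inherits(data, "tfpi_dataset")) dataset_series(data) else data
  bounds <- param_bounds(model)
  theta <- theta[rownames(bounds)]
  if (any(is.na(theta)) || !theta_in_bounds(theta, bounds)) return(-Inf)
  rates <- theta_to_rates(theta, model)
  sigma <- theta[["sigma"]]
  ll <- 0
  for (s in series) {
    mu <- tryCatch(
      predict_condition(s$condition, rates, s$times, mapping),
      error = function(e) NULL)
    if (is.null(mu) || any(!is.finite(mu)) || any(mu <= 0)) return(-Inf)
    ll <- ll + sum(dnorm(s$values, mean = mu, sd = sigma * mu, log = TRUE))
  }
  ll
}

#' Latin-hypercube pre-exploration of the parameter box
#'
#' Draws a Latin-hypercube sample over the bounded box, discards draws
#' violating the nonnegativity constraint on the derived k_minus_1,
#' evaluates the log-likelihood of the rest, and condenses the top
#' \code{top_k} draws into a starting point (their component-wise mean)
#' and a diagonal proposal covariance (their component-wise variances,
#' scaled by 2.38^2/d).
#'
#' @param data dataset or pre-split series list.
#' @param n_samples number of LHS draws.
#' @param top_k number of best draws kept (default 500).
#' @param seed RNG seed.
#' @param model,mapping passed to \code{\link{log_likelihood}}.
#' @return List with \code{theta0}, \code{proposal_cov} (diagonal
#'   matrix), \code{top} (matrix of retained draws) and \code{log_lik}.
#' @export
lhs_preexplore <- function(data, n_samples = 1e4, top_k = 500, seed = 1,
                           model = "full", mapping = "P") {
  if (n_samples < top_k)
    stop("n_samples must be at least top_k", call. = FALSE)
  series <- if (inherits(data, "tfpi_dataset")) dataset_series(data) else data
  bounds <- param_bounds(model)
  d <- nrow(bounds)
  set.seed(seed)
  u <- lhs::randomLHS(n_samples, d)
  draws <- sweep(sweep(u, 2L, bounds$upper - bounds$lower, `*`),
                 2L, bounds$lower, `+`)
  colnames(draws) <- rownames(bounds)
  ll <- apply(draws, 1L, function(row)
    log_likelihood(row, series, model, mapping))
  ok <- is.finite(ll)
  if (!any(ok))
    stop("LHS pre-exploration found no finite-likelihood draw",
         call. = FALSE)
  keep <- order(ll, decreasing = TRUE)[seq_len(min(top_k, sum(ok)))]
  top <- draws[keep, , drop = FALSE]
  spread <- apply(top, 2L, var)
  spread[spread <= 0] <- 1e-12
  # top-k draws scatter far wider than the posterior, so the optimal-RW
  # factor is shrunk an extra 10x to keep the seed chain moving
  list(theta0 = colMeans(top),
       proposal_cov = diag(spread * 0.1 * 2.38^2 / d, d),
       top = top, log_lik = ll[keep])
}

new_chain <- function(samples, log_post, accepted, phase, seed) {
  structure(list(samples = samples, log_post = log_post,
                 accepted = accepted, phase = phase, seed = seed),
            class = "tfpi_chain")
}

#' @export
print.tfpi_chain <- function(x, ...) {
  cat("<tfpi_chain> phase", paste(unique(x$phase), collapse = "+"),
      ":", nrow(x$samples), "samples,",
      ncol(x$samples), "parameters, acceptance",
      signif(mean(x$accepted), 3), "\n")
  invisible(x)
}

#' Random-walk Metropolis sampler
#'
#' Fixed multivariate-normal proposals; out-of-support proposals (for
#' which \code{log_post} returns \code{-Inf}) are rejected, never
#' clipped.
#'
#' @param log_post function of the parameter vector returning the
#'   unnormalized log posterior.
#' @param theta0 named starting vector with finite log posterior.
#' @param proposal_cov proposal covariance matrix (or a vector of
#'   diagonal variances).
#' @param n_iter number of iterations.
#' @param seed RNG seed.
#' @return A \code{tfpi_chain}.
#' @export
metropolis <- function(log_post, theta0, proposal_cov, n_iter, seed = 1) {
  if (is.vector(proposal_cov)) proposal_cov <- diag(proposal_cov,
                                                    length(theta0))
  lp0 <- log_post(theta0)
  if (!is.finite(lp0))
    stop("log posterior not finite at theta0", call. = FALSE)
  d <- length(theta0)
  R <- chol(proposal_cov + diag(1e-300, d))
  set.seed(seed)
  samples <- matrix(NA_real_, n_iter, d,
                    dimnames = list(NULL, names(theta0)))
  lps <- numeric(n_iter)
  acc <- logical(n_iter)
  cur <- theta0; lp <- lp0
  for (i in seq_len(n_iter)) {
    prop <- cur + drop(rnorm(d) %*% R)
    lpp <- log_post(prop)
    if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
      cur <- prop; lp <- lpp; acc[i] <- TRUE
    }
    samples[i, ] <- cur
    lps[i] <- lp
  }
  new_chain(samples, lps, acc, rep("MA", n_iter), seed)
}

#' Adaptive Metropolis sampler
#'
#' Continues a fixed-proposal chain with an adaptive mixture kernel
#' built for the long climbs and curved ridges of ODE-kinetics
#' posteriors.  Full-vector proposals (probability \code{p_full}) are
#' multivariate normal with covariance equal to the (exponentially
#' forgetting) empirical covariance of the chain scaled by 2.38^2/d, a
#' small diagonal regularizer, and a global scale factor adapted
#' towards the standard 23.4% acceptance target; a rejected full-vector
#' proposal is given a delayed-rejection second stage at one fifth of
#' the scale, and an occasional proposal is inflated to help traverse
#' ridges.  These are interleaved with random-scan single-coordinate
#' proposals whose per-coordinate scales adapt towards 44% acceptance,
#' which lets weakly identified coordinates travel their full range
#' while sharply identified ones take commensurately small steps, and
#' optionally with joint multiplicative moves that rescale a named
#' group of coordinates by a common lognormal factor (with the standard
#' Hastings correction), used to traverse ratio-identified sloppy
#' directions of kinetic models.  Starts from the seed chain's final
#' state with moments initialized from its history.
#'
#' The first \code{anneal_frac} of the run is an annealed burn-in: the
#' log posterior is tempered by a factor ramping linearly from
#' \code{beta0} to 1, after which the exact posterior is sampled.  The
#' tempered stretch belongs to the burn-in and must be discarded before
#' summarizing.
#'
#' @param log_post unnormalized log-posterior function.
#' @param ma_chain the seed \code{tfpi_chain}.
#' @param n_iter number of adaptive iterations.
#' @param seed RNG seed.
#' @param epsilon diagonal regularizer added to the empirical covariance.
#' @param p_full probability of a full-vector move; single-coordinate
#'   moves take the remaining mass less the group-scaling share.
#' @param window effective memory (iterations) of the forgetting moment
#'   estimates.
#' @param dr_scale scale ratio of the delayed-rejection second stage.
#' @param big_p,big_scale probability and scale multiplier of inflated
#'   full-vector proposals.
#' @param coord_scales optional initial standard deviations of the
#'   coordinate moves; defaults to the seed chain's per-coordinate
#'   standard deviations (floored at 1e-6).
#' @param pair_groups list of character vectors naming coordinate
#'   groups for the joint multiplicative moves (10% of iterations when
#'   nonempty).
#' @param anneal_frac fraction of the run spent in the annealed
#'   burn-in.
#' @param beta0 initial inverse temperature of the annealed stretch.
#' @return A \code{tfpi_chain} of the adaptive iterations.
#' @export
adaptive_metropolis <- function(log_post, ma_chain, n_iter, seed = 2,
                                epsilon = 1e-10, p_full = 0.55,
                                window = 2000, dr_scale = 0.2,
                                big_p = 0.15, big_scale = 3,
                                coord_scales = NULL,
                                pair_groups = list(),
                                anneal_frac = 0.25, beta0 = 0.05) {
  stopifnot(inherits(ma_chain, "tfpi_chain"), nrow(ma_chain$samples) > 1)
  hist0 <- ma_chain$samples
  d <- ncol(hist0)
  s_d <- 2.38^2 / d
  m <- colMeans(hist0)
  C <- cov(hist0)
  cur <- hist0[nrow(hist0), ]
  lp <- log_post(cur)
  if (!is.finite(lp))
    stop("log posterior not finite at the seed chain's final state",
         call. = FALSE)
  if (is.null(coord_scales))
    coord_scales <- pmax(apply(hist0, 2L, sd), 1e-6)
  logsc <- log(coord_scales)
  n_coord <- rep(0L, d)
  groups <- lapply(pair_groups, function(g) {
    jj <- match(g, colnames(hist0))
    if (any(is.na(jj)))
      stop("pair_groups names not found in the parameter vector",
           call. = FALSE)
    jj
  })
  p_pair <- if (length(groups)) 0.1 else 0
  p_coord <- 1 - p_full - p_pair
  grp_log <- rep(log(0.3), length(groups))
  n_grp <- rep(0L, length(groups))
  set.seed(seed)
  samples <- matrix(NA_real_, n_iter, d,
                    dimnames = list(NULL, colnames(hist0)))
  lps <- numeric(n_iter)
  acc <- logical(n_iter)
  loglam <- 0
  ldmvn <- function(x, mu, R) {  # log N(x; mu, RR') up to a constant
    z <- backsolve(R, x - mu, transpose = TRUE)
    -0.5 * sum(z * z) - sum(log(diag(R)))
  }
  n_anneal <- floor(anneal_frac * n_iter)
  for (i in seq_len(n_iter)) {
    beta <- if (i <= n_anneal)
      beta0 + (1 - beta0) * (i - 1) / n_anneal else 1
    alpha <- 1 / min(i + 10, window)
    u <- runif(1)
    if (u < p_full) {
      mult <- if (runif(1) < big_p) big_scale else 1
      P <- exp(loglam) * s_d * mult^2 * (C + diag(epsilon, d))
      R <- tryCatch(chol(P), error = function(e) chol(P + diag(1e-12, d)))
      y1 <- cur + drop(rnorm(d) %*% R)
      lp1 <- log_post(y1)
      a1 <- if (is.finite(lp1)) min(1, exp(beta * (lp1 - lp))) else 0
      if (runif(1) < a1) {
        cur <- y1; lp <- lp1; acc[i] <- TRUE
      } else {
        # delayed rejection: retry at a fraction of the scale, with the
        # two-stage acceptance ratio preserving detailed balance
        R2 <- R * dr_scale
        y2 <- cur + drop(rnorm(d) %*% R2)
        lp2 <- log_post(y2)
        if (is.finite(lp2)) {
          a1_rev <- min(1, exp(beta * (lp1 - lp2)))
          num <- beta * lp2 + ldmvn(y1, y2, R) +
            log(max(1 - a1_rev, 1e-300))
          den <- beta * lp + ldmvn(y1, cur, R) +
            log(max(1 - a1, 1e-300))
          if (log(runif(1)) < num - den) {
            cur <- y2; lp <- lp2; acc[i] <- TRUE
          }
        }
      }
      if (mult == 1) loglam <- loglam + i^-0.6 * (a1 - 0.234)
    } else if (u < p_full + p_coord) {
      j <- sample.int(d, 1L)
      prop <- cur
      prop[j] <- prop[j] + rnorm(1, sd = exp(logsc[j]))
      lpp <- log_post(prop)
      a <- if (is.finite(lpp)) min(1, exp(beta * (lpp - lp))) else 0
      if (runif(1) < a) {
        cur <- prop; lp <- lpp; acc[i] <- TRUE
      }
      n_coord[j] <- n_coord[j] + 1L
      logsc[j] <- logsc[j] + n_coord[j]^-0.6 * (a - 0.44)
    } else {
      # joint multiplicative rescaling of a coordinate group; the
      # lognormal kernel needs a Hastings factor of fac per coordinate
      g <- if (length(groups) == 1L) 1L else sample.int(length(groups), 1L)
      jj <- groups[[g]]
      fac <- exp(rnorm(1, sd = exp(grp_log[g])))
      prop <- cur
      prop[jj] <- prop[jj] * fac
      lpp <- log_post(prop)
      a <- min(if (is.finite(lpp))
        exp(beta * (lpp - lp)) * fac^length(jj) else 0, 1)
      if (runif(1) < a) {
        cur <- prop; lp <- lpp; acc[i] <- TRUE
      }
      n_grp[g] <- n_grp[g] + 1L
      grp_log[g] <- grp_log[g] + n_grp[g]^-0.6 * (a - 0.44)
    }
    samples[i, ] <- cur
    lps[i] <- lp
    # forgetting update of the proposal moments
    m_old <- m
    m <- (1 - alpha) * m + alpha * cur
    C <- (1 - alpha) * C + alpha * tcrossprod(cur - m, cur - m_old)
  }
  new_chain(samples, lps, acc, rep("AM", n_iter), seed)
}

#' Burn-in and thinning of the combined chain
#'
#' Concatenates the fixed-proposal and adaptive chains, drops the first
#' \code{burn} iterations, and keeps every \code{stride}-th remaining
#' sample.  At the full-scale design (1e5 + 6e6 iterations, burn 1e5,
#' stride 100) this leaves 6e4 estimates.  The lag-1 autocorrelation of
#' each retained parameter is reported and a warning is issued when any
#' exceeds 0.05.
#'
#' @param chain_ma,chain_am \code{tfpi_chain}s (either may be NULL).
#' @param burn iterations to drop from the front of the combined chain.
#' @param stride thinning stride.
#' @return A \code{tfpi_chain} with an extra \code{lag1} field.
#' @export
thin_chain <- function(chain_ma, chain_am, burn = 1e5, stride = 100) {
  chains <- Filter(Negate(is.null), list(chain_ma, chain_am))
  stopifnot(length(chains) > 0)
  samples <- do.call(rbind, lapply(chains, `[[`, "samples"))
  lps <- unlist(lapply(chains, `[[`, "log_post"))
  acc <- unlist(lapply(chains, `[[`, "accepted"))
  phase <- unlist(lapply(chains, `[[`, "phase"))
  n <- nrow(samples)
  if (burn >= n)
    stop("burn-in exceeds the combined chain length", call. = FALSE)
  idx <- seq.int(burn + stride, n, by = stride)
  if (stride == 1L) idx <- seq.int(burn + 1L, n)
  if (!length(idx))
    stop("thinning left no samples", call. = FALSE)
  out <- new_chain(samples[idx, , drop = FALSE], lps[idx], acc[idx],
                   phase[idx], chains[[1L]]$seed)
  out$lag1 <- apply(out$samples, 2L, function(x) {
    if (sd(x) == 0) return(0)
    stats::cor(x[-length(x)], x[-1L])
  })
  if (any(abs(out$lag1) > 0.05))
    warning("lag-1 autocorrelation above 5% for: ",
            paste(names(out$lag1)[abs(out$lag1) > 0.05], collapse = ", "),
            call. = FALSE)
  out
}

#' Posterior summary of a chain
#'
#' Per-parameter medians and equal-tailed 95% credible intervals, for
#' the free parameters and for the derived constants (k_minus_1,
#' k_minus_3, k_minus_4, K_D_1, K_D_6, K_D_8 and the conformational
#' ratio reported in both directions, K_R_7 = k_plus_7/k_minus_7 and its
#' reciprocal).  Derived quantities are computed per sample and then
#' summarized, so monotone transforms commute with the median.
#'
#' @param chain a \code{tfpi_chain}.
#' @param model "full" or "no_reaction_7".
#' @return Data frame with columns \code{parameter}, \code{median},
#'   \code{lower_95}, \code{upper_95}; class \code{posterior_summary}.
#' @export
summarize_chain <- function(chain, model = "full") {
  stopifnot(inherits(chain, "tfpi_chain"), nrow(chain$samples) > 0)
  s <- as.data.frame(chain$samples)
  derived <- list(
    k_minus_1 = K_M_FIXED * s$k_plus_1 - s$k_plus_2,
    k_minus_3 = K_D3_FIXED * s$k_plus_3,
    k_minus_4 = K_D4_FIXED * s$k_plus_4,
    K_D_1 = (K_M_FIXED * s$k_plus_1 - s$k_plus_2) / s$k_plus_1,
    K_D_6 = s$k_minus_6 / s$k_plus_6,
    K_D_8 = s$k_minus_8 / s$k_plus_8
  )
  if (model == "full" && !is.null(s$k_plus_7)) {
    derived$K_R_7 <- s$k_plus_7 / s$k_minus_7
    derived$K_R_7_reciprocal <- s$k_minus_7 / s$k_plus_7
  }
  all_q <- c(as.list(s), derived)
  out <- do.call(rbind, lapply(names(all_q), function(nm) {
    q <- quantile(all_q[[nm]], c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(parameter = nm, median = q[1L],
               lower_95 = q[2L], upper_95 = q[3L])
  }))
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Posterior predictive bands for a condition
#'
#' Pointwise quantiles of the predicted observable over posterior
#' samples, at the requested credible levels (default the 70, 90 and 99
#' percent bands around the pointwise median).
#'
#' @param chain a \code{tfpi_chain} (usually thinned).
#' @param condition an \code{\link{experiment_condition}}.
#' @param times measurement times, s.
#' @param levels credible levels in (0, 1).
#' @param model,mapping as in \code{\link{log_likelihood}}.
#' @param max_draws cap on the number of posterior draws used (evenly
#'   spaced through the chain).
#' @return Data frame with \code{time_s}, \code{median} and
#'   \code{lower_XX}/\code{upper_XX} columns per level.
#' @export
prediction_bands <- function(chain, condition, times,
                             levels = c(0.70, 0.90, 0.99),
                             model = "full", mapping = "P",
                             max_draws = 500L) {
  stopifnot(inherits(chain, "tfpi_chain"))
  n <- nrow(chain$samples)
  idx <- if (n > max_draws)
    unique(round(seq(1, n, length.out = max_draws))) else seq_len(n)
  curves <- vapply(idx, function(i) {
    theta <- chain$samples[i, ]
    predict_condition(condition, theta_to_rates(theta, model), times,
                      mapping)
  }, numeric(length(times)))
  curves <- matrix(curves, nrow = length(times))
  out <- data.frame(time_s = times,
                    median = apply(curves, 1L, median))
  for (lv in sort(levels)) {
    a <- (1 - lv) / 2
    tag <- sprintf("%02d", round(lv * 100))
    out[[paste0("lower_", tag)]] <- apply(curves, 1L, quantile, probs = a)
    out[[paste0("upper_", tag)]] <- apply(curves, 1L, quantile,
                                          probs = 1 - a)
  }
  out
}

#' Default estimation settings
#'
#' Desk-scale counts (about 100x below the full-scale design of 1e6 LHS
#' draws, 1e5 fixed-proposal iterations, 6e6 adaptive iterations and
#' stride 100); the full design is reachable by overriding the counts.
#' The desk-scale \code{top_k} keeps roughly the full design's retained
#' fraction (500 out of 1e6 draws); the desk-scale burn-in discards the
#' fixed-proposal phase plus the first half of the adaptive phase (the
#' discard-half convention, which at these counts comfortably covers
#' the annealed stretch and the tail of the climb towards the posterior
#' mode); and \code{n_chains} independent chains are run from separate
#' pre-explorations and pooled, so that between-chain spread is
#' reflected in the posterior summaries.
#'
#' @param n_lhs,top_k,n_ma,n_am,burn,stride,seed per-chain estimation
#'   counts and base seed.
#' @param n_chains number of independent chains pooled for summaries.
#' @param model "full" or "no_reaction_7".
#' @param mapping observable mapping.
#' @return Named list of settings.
#' @export
fit_config <- function(n_lhs = 1e4, top_k = 3, n_ma = 1e3, n_am = 2e4,
                       burn = n_ma + n_am %/% 2, stride = 10, seed = 1,
                       n_chains = 3, model = "full", mapping = "P") {
  stopifnot(n_lhs >= top_k, n_ma > 0, n_am > 0, stride >= 1,
            n_chains >= 1)
  list(n_lhs = n_lhs, top_k = top_k, n_ma = n_ma, n_am = n_am,
       burn = burn, stride = stride, seed = seed,
       n_chains = as.integer(n_chains),
       model = match.arg(model, c("full", "no_reaction_7")),
       mapping = mapping)
}

#' Four-step estimation of the kinetic rate constants
#'
#' Runs the full pipeline on a measurement dataset: (i) Latin-hypercube
#' pre-exploration of the bounded box under the uniform prior, (ii)
#' random-walk Metropolis seeded from the best pre-exploration draws,
#' (iii) adaptive Metropolis continuing the chain with covariance
#' adaptation, and (iv) burn-in removal plus thinning.  The alternative
#' scheme without the conformational change is fit by setting
#' \code{model = "no_reaction_7"}, which removes k_plus_7/k_minus_7 from
#' the free vector and nullifies reaction 7.
#'
#' @param data a \code{tfpi_dataset}.
#' @param config settings from \code{\link{fit_config}}.
#' @return List with elements \code{chains} (one element per chain,
#'   each holding \code{lhs}, \code{chain_ma}, \code{chain_am} and the
#'   per-chain \code{thinned} chain), \code{thinned} (the pooled
#'   thinned chain used for inference), \code{summary} (a
#'   \code{posterior_summary} of the pooled chain) and \code{config}.
#' @export
fit_kinetics <- function(data, config = fit_config()) {
  series <- dataset_series(data)
  log_post <- function(theta)
    log_likelihood(theta, series, config$model, config$mapping)
  bounds <- param_bounds(config$model)
  run_one <- function(base_seed) {
    pre <- lhs_preexplore(series, config$n_lhs, config$top_k,
                          seed = base_seed, model = config$model,
                          mapping = config$mapping)
    ma <- metropolis(log_post, pre$theta0, pre$proposal_cov,
                     config$n_ma, seed = base_seed + 1L)
    am <- adaptive_metropolis(
      log_post, ma, config$n_am, seed = base_seed + 2L,
      coord_scales = 0.05 * (bounds$upper - bounds$lower),
      pair_groups = list(c("k_plus_3", "k_plus_6")))
    list(lhs = pre, chain_ma = ma, chain_am = am,
         thinned = thin_chain(ma, am, burn = config$burn,
                              stride = config$stride))
  }
  chains <- lapply(seq_len(config$n_chains), function(k)
    run_one(config$seed + 3L * (k - 1L)))
  pooled <- chains[[1L]]$thinned
  if (config$n_chains > 1L) {
    pooled$samples <- do.call(rbind,
                              lapply(chains, function(ch) ch$thinned$samples))
    pooled$log_post <- unlist(lapply(chains, function(ch) ch$thinned$log_post))
    pooled$accepted <- unlist(lapply(chains, function(ch) ch$thinned$accepted))
    pooled$phase <- unlist(lapply(chains, function(ch) ch$thinned$phase))
  }
  list(chains = chains, thinned = pooled,
       summary = summarize_chain(pooled, config$model),
       config = config)
}

#' Persist a chain or summary as CSV
#'
#' Chains are written one row per retained sample with the free
#' parameters, the log posterior and the phase label; summaries in the
#' layout of the rate-constant table (parameter, median, 95% interval).
#'
#' @param chain a \code{tfpi_chain}.
#' @param path output file.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "tfpi_chain"))
  out <- as.data.frame(signif(chain$samples, 12))
  out$log_posterior <- signif(chain$log_post, 12)
  out$phase <- chain$phase
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chain
#' @param summary a \code{posterior_summary}.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "posterior_summary"))
  out <- as.data.frame(summary)
  for (cl in c("median", "lower_95", "upper_95"))
    out[[cl]] <- signif(out[[cl]], 12)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
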