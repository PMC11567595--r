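#' Synthetic-data design
#'
#' Describes a protocol-faithful simulated study: a true parameter
#' vector, the Experiment One enzyme titration levels, the Experiment
#' Two pre-incubation Xa levels, a shared measurement-time grid and a
#' proportional-noise scale.
#'
#' @param theta_true named free parameter vector (including
#'   \code{sigma}, which is ignored in favour of \code{sigma_true} when
#'   generating noise; keeping both makes the design self-describing for
#'   recovery tests).
#' @param exp1_enzyme_nM Experiment One TF:VIIa levels, nM.
#' @param exp2_Xa_nM Experiment Two pre-incubation Xa levels, nM.
#' @param times measurement times, s, strictly positive.
#' @param sigma_true proportional noise scale, > 0.
#' @param seed RNG seed used by \code{\link{generate_dataset}}.
#' @param model "full" or "no_reaction_7".
#' @return An object of class \code{synthetic_design}.
#' @export
synthetic_design <- function(theta_true, exp1_enzyme_nM, exp2_Xa_nM,
                             times, sigma_true, seed = 20240101L,
                             model = "full") {
  if (any(exp1_enzyme_nM < 0) || any(exp2_Xa_nM < 0))
    stop("concentration lists must be nonnegative", call. = FALSE)
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing and positive", call. = FALSE)
  if (sigma_true <= 0)
    stop("sigma_true must be positive", call. = FALSE)
  structure(list(theta_true = theta_true,
                 exp1_enzyme_nM = exp1_enzyme_nM,
                 exp2_Xa_nM = exp2_Xa_nM,
                 times = times, sigma_true = sigma_true,
                 seed = as.integer(seed), model = model),
            class = "synthetic_design")
}

#' Reference synthetic design
#'
#' The default study conditions: true rates at the fitted medians of the
#' full scheme (with the reverse rates re-derived through the fixed
#' K_M, K_D_3 and K_D_4 so that the truth lies in the estimable
#' parameterization), the six doubling enzyme levels 0.032-1.024 nM for
#' Experiment One, pre-incubation Xa levels 0, 0.1, 0.5 and 1 nM for
#' Experiment Two, twelve equally spaced measurement times over 720 s,
#' and proportional noise sigma_true = 0.05.
#'
#' @return A \code{\link{synthetic_design}}.
#' @export
#' @examples
#' d <- make_reference_design()
#' d$theta_true[["k_plus_2"]]
make_reference_design <- function() {
  theta <- c(k_plus_1 = 0.51, k_plus_2 = 16.23, k_plus_3 = 0.16,
             k_plus_4 = 3.67e-3, k_plus_6 = 0.56, k_minus_6 = 25.16,
             k_plus_7 = 360.92, k_minus_7 = 7.36e-3,
             k_plus_8 = 0.95, k_minus_8 = 16.03, sigma = 0.05)
  synthetic_design(
    theta_true = theta,
    exp1_enzyme_nM = c(0.032, 0.064, 0.128, 0.256, 0.512, 1.024),
    exp2_Xa_nM = c(0, 0.1, 0.5, 1.0),
    times = seq(60, 720, by = 60),
    sigma_true = 0.05,
    seed = 20240101L
  )
}

#' Generate a synthetic measurement dataset
#'
#' Simulates every condition of the design (including the two-hour
#' pre-incubation of the Experiment Two conditions), evaluates the
#' noise-free observable at the measurement times, and adds independent
#' normal noise with standard deviation sigma_true times the noise-free
#' signal.  Negative draws are redrawn so the support of the data
#' matches the nonnegativity of concentrations while keeping the normal
#' shape near the bulk; the number of redraws is recorded in the
#' \code{redraws} attribute.  Points with a zero noise-free signal are
#' emitted noise-free and counted in the \code{flagged_zero} attribute.
#'
#' @param design a \code{\link{synthetic_design}}.
#' @param noise_free if TRUE, return the noise-free predictions
#'   (equivalent to the limit sigma_true -> 0).
#' @return A \code{tfpi_dataset} with attributes \code{theta_true},
#'   \code{sigma_true}, \code{seed}, \code{redraws}, \code{flagged_zero}.
#' @export
generate_dataset <- function(design, noise_free = FALSE) {
  stopifnot(inherits(design, "synthetic_design"))
  rates <- theta_to_rates(design$theta_true, design$model)
  conds <- c(
    lapply(design$exp1_enzyme_nM, function(e)
      experiment_condition(1L, enzyme_nM = e)),
    lapply(design$exp2_Xa_nM, function(xa)
      experiment_condition(2L, enzyme_nM = 0.128,
                           preincubated_Xa_nM = xa))
  )
  set.seed(design$seed)
  redraws <- 0L
  flagged <- 0L
  rows <- lapply(conds, function(cond) {
    mu <- predict_condition(cond, rates, design$times)
    y <- numeric(length(mu))
    for (i in seq_along(mu)) {
      if (noise_free) { y[i] <- mu[i]; next }
      if (mu[i] <= 0) { y[i] <- mu[i]; flagged <<- flagged + 1L; next }
      repeat {
        draw <- rnorm(1L, mean = mu[i], sd = design$sigma_true * mu[i])
        if (draw >= 0) break
        redraws <<- redraws + 1L
      }
      y[i] <- draw
    }
    data.frame(experiment_id = cond$experiment_id,
               enzyme_nM = cond$enzyme_nM, X_nM = cond$X_nM,
               TFPI_nM = cond$TFPI_total_nM,
               preincubated_Xa_nM = cond$preincubated_Xa_nM,
               time_s = design$times, Xa_nM = y)
  })
  out <- as_dataset(do.call(rbind, rows))
  attr(out, "theta_true") <- design$theta_true
  attr(out, "sigma_true") <- design$sigma_true
  attr(out, "seed") <- design$seed
  attr(out, "redraws") <- redraws
  attr(out, "flagged_zero") <- flagged
  out
}

#' Write a synthetic dataset with its manifest
#'
#' Emits the dataset CSV plus a JSON sidecar manifest recording the true
#' parameters, noise scale and seed, so recovery studies can be rerun
#' from the files alone.
#'
#' @param data a dataset from \code{\link{generate_dataset}}.
#' @param path CSV output path; the manifest is written alongside with
#'   extension \code{.manifest.json}.
#' @export
write_synthetic <- function(data, path) {
  write_dataset(data, path)
  manifest <- list(theta_true = as.list(attr(data, "theta_true")),
                   sigma_true = attr(data, "sigma_true"),
                   seed = attr(data, "seed"),
                   redraws = attr(data, "redraws"),
                   flagged_zero = attr(data, "flagged_zero"))
  jsonlite::write_json(manifest, sub("\\.csv$", ".manifest.json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
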