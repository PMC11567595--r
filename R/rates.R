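#' @useDynLib tfpiflow
#' @importFrom stats dnorm median quantile rnorm runif sd setNames cov acf
#' @importFrom utils read.csv write.csv
NULL

# canonical species ordering used in every vector, file and summary
SPECIES <- c("E", "S", "ES", "EP", "P", "I", "PI", "EPI", "PIE")

# rate-constant names in the order expected by the compiled derivatives
RATE_NAMES <- c(
  "k_plus_1", "k_minus_1", "k_plus_2",
  "k_plus_3", "k_minus_3",
  "k_plus_4", "k_minus_4",
  "k_plus_5", "k_minus_5",
  "k_plus_6", "k_minus_6",
  "k_plus_7", "k_minus_7",
  "k_plus_8", "k_minus_8"
)

#' Create a full set of kinetic rate constants
#'
#' Constructs the parameter home of the nine-species scheme: forward and
#' reverse rate constants for reactions 1 through 8.  Bimolecular forward
#' rates carry units of nM^-1 s^-1; unimolecular rates (all reverse rates
#' plus the catalytic rate \code{k_plus_2} and the conformational-change
#' rate \code{k_plus_7}) carry s^-1.  Reaction 5 (simultaneous double
#' binding of Xa:TFPI to TF:VIIa) is excluded from the working scheme, so
#' its rates default to zero; callers may override explicitly to recover
#' the full original scheme.
#'
#' @param k_plus_1,k_minus_1 binding/unbinding of X to TF:VIIa.
#' @param k_plus_2 catalytic conversion of TF:VIIa:X to TF:VIIa:Xa, s^-1.
#' @param k_plus_3,k_minus_3 binding/unbinding of Xa to TF:VIIa.
#' @param k_plus_4,k_minus_4 solution-phase binding of Xa and TFPI.
#' @param k_plus_5,k_minus_5 direct quaternary-complex formation
#'   (nullified by default).
#' @param k_plus_6,k_minus_6 TFPI binding to TF:VIIa:Xa.
#' @param k_plus_7,k_minus_7 conformational change to the tight complex, s^-1.
#' @param k_plus_8,k_minus_8 Xa:TFPI binding to TF:VIIa.
#' @return An object of class \code{rate_set}: a named numeric vector of
#'   the 15 rate constants.
#' @export
#' @examples
#' r <- table1_rates()
#' derived_constants(r)["K_M"]
rate_set <- function(k_plus_1, k_minus_1, k_plus_2,
                     k_plus_3, k_minus_3,
                     k_plus_4, k_minus_4,
                     k_plus_5 = 0, k_minus_5 = 0,
                     k_plus_6, k_minus_6,
                     k_plus_7, k_minus_7,
                     k_plus_8, k_minus_8) {
  x <- c(k_plus_1 = k_plus_1, k_minus_1 = k_minus_1, k_plus_2 = k_plus_2,
         k_plus_3 = k_plus_3, k_minus_3 = k_minus_3,
         k_plus_4 = k_plus_4, k_minus_4 = k_minus_4,
         k_plus_5 = k_plus_5, k_minus_5 = k_minus_5,
         k_plus_6 = k_plus_6, k_minus_6 = k_minus_6,
         k_plus_7 = k_plus_7, k_minus_7 = k_minus_7,
         k_plus_8 = k_plus_8, k_minus_8 = k_minus_8)
  validate_rate_set(x)
  structure(x, class = "rate_set")
}

validate_rate_set <- function(x) {
  if (!is.numeric(x) || length(x) != 15L || !identical(names(x), RATE_NAMES))
    stop("a rate_set must hold the 15 named rate constants ",
         paste(RATE_NAMES, collapse = ", "), call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-finite rate constant: ",
         paste(names(x)[!is.finite(x)], collapse = ", "), call. = FALSE)
  if (any(x < 0))
    stop("negative rate constant: ",
         paste(names(x)[x < 0], collapse = ", "), call. = FALSE)
  invisible(x)
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set> (nM^-1 s^-1 for bimolecular forward rates, s^-1 otherwise)\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Posterior-median rate constants of the full scheme
#'
#' The fitted medians for the working scheme (reactions 1-4 and 6-8 active,
#' reaction 5 nullified), suitable as a reference parameterization for
#' simulation and for the flow analyses.
#'
#' @return A \code{rate_set}.
#' @export
table1_rates <- function() {
  rate_set(
    k_plus_1 = 0.51,    k_minus_1 = 104.30, k_plus_2 = 16.23,
    k_plus_3 = 0.16,    k_minus_3 = 81.18,
    k_plus_4 = 3.67e-3, k_minus_4 = 9.64e-5,
    k_plus_6 = 0.56,    k_minus_6 = 25.16,
    k_plus_7 = 360.92,  k_minus_7 = 7.36e-3,
    k_plus_8 = 0.95,    k_minus_8 = 16.03
  )
}

#' Posterior-median rate constants of the alternative scheme
#'
#' The re-estimated medians for the alternative model in which the
#' conformational change to the tight quaternary complex (reaction 7) is
#' removed along with reaction 5; the fit compensates by making reactions
#' 6 and 8 nearly irreversible.
#'
#' @return A \code{rate_set} with reactions 5 and 7 nullified.
#' @export
table2_rates <- function() {
  rate_set(
    k_plus_1 = 0.51,    k_minus_1 = 103.93, k_plus_2 = 17.33,
    k_plus_3 = 7.42e-2, k_minus_3 = 38.59,
    k_plus_4 = 3.40e-3, k_minus_4 = 8.94e-5,
    k_plus_6 = 0.24,    k_minus_6 = 2.21e-4,
    k_plus_7 = 0,       k_minus_7 = 0,
    k_plus_8 = 0.94,    k_minus_8 = 8.19e-4
  )
}

#' Derived equilibrium and Michaelis constants
#'
#' Computes the Michaelis constant K_M = (k_minus_1 + k_plus_2)/k_plus_1 and
#' the dissociation constants K_D_n = k_minus_n/k_plus_n for the reversible
#' binding reactions, plus the dimensionless ratio K_R_7 = k_plus_7/k_minus_7
#' measuring the strength of the tight complex.  Entries whose forward (or,
#' for K_R_7, either) rate is zero are returned as NA.
#'
#' @param rates a \code{rate_set}.
#' @return Named numeric vector with elements K_M, K_D_1, K_D_3, K_D_4,
#'   K_D_5, K_D_6, K_D_8 (nM) and K_R_7 (dimensionless).
#' @export
derived_constants <- function(rates) {
  validate_rate_set(rates)
  r <- unclass(rates)
  kd <- function(n) {
    kp <- r[[paste0("k_plus_", n)]]
    if (kp > 0) r[[paste0("k_minus_", n)]] / kp else NA_real_
  }
  c(K_M   = if (r[["k_plus_1"]] > 0)
              (r[["k_minus_1"]] + r[["k_plus_2"]]) / r[["k_plus_1"]]
            else NA_real_,
    K_D_1 = kd(1), K_D_3 = kd(3), K_D_4 = kd(4), K_D_5 = kd(5),
    K_D_6 = kd(6), K_D_8 = kd(8),
    K_R_7 = if (r[["k_plus_7"]] > 0 && r[["k_minus_7"]] > 0)
              r[["k_plus_7"]] / r[["k_minus_7"]]
            else NA_real_)
}

#' Nullify the rates of selected reactions
#'
#' Returns a copy of \code{rates} in which the forward and reverse
#' constants of each listed reaction are set to zero.  This is the
#' primitive used to build the inhibition-pathway variants and the
#' alternative (no tight complex) model.
#'
#' @param rates a \code{rate_set}.
#' @param reactions integer vector with elements in 1:8.
#' @return A \code{rate_set}.
#' @export
nullify_reactions <- function(rates, reactions) {
  validate_rate_set(rates)
  if (length(reactions) && (!is.numeric(reactions) ||
      any(!(reactions %in% 1:8))))
    stop("reactions must be integers in 1..8", call. = FALSE)
  out <- unclass(rates)
  for (n in reactions) {
    out[[paste0("k_plus_", n)]] <- 0
    # reaction 2 is irreversible; it has no reverse constant
    km <- paste0("k_minus_", n)
    if (km %in% names(out)) out[[km]] <- 0
  }
  structure(out, class = "rate_set")
}

#' Read / write a rate configuration file
#'
#' Rate sets are persisted as a flat key-value JSON object with keys
#' \code{k_plus_1} ... \code{k_minus_8}.  Unknown keys are an error so
#' that typos in hand-edited configurations fail loudly.
#'
#' @param path file path.
#' @return \code{read_rates} returns a \code{rate_set};
#'   \code{write_rates} returns \code{path} invisibly.
#' @export
read_rates <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(x), RATE_NAMES)
  if (length(bad))
    stop("unknown rate key in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(RATE_NAMES, names(x))
  if (length(missing))
    stop("missing rate key in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  vals <- vapply(RATE_NAMES, function(k) as.numeric(x[[k]]), numeric(1))
  validate_rate_set(vals)
  structure(vals, class = "rate_set")
}

#' @rdname read_rates
#' @param rates a \code{rate_set} to serialize.
#' @export
write_rates <- function(rates, path) {
  validate_rate_set(rates)
  jsonlite::write_json(as.list(unclass(rates)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
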