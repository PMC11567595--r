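# shared fixtures for the suite

# rates with only reaction 1 active (single bimolecular binding step)
binding_only_rates <- function(k_plus_1 = 0.51) {
  rate_set(k_plus_1 = k_plus_1, k_minus_1 = 0, k_plus_2 = 0,
           k_plus_3 = 0, k_minus_3 = 0, k_plus_4 = 0, k_minus_4 = 0,
           k_plus_6 = 0, k_minus_6 = 0, k_plus_7 = 0, k_minus_7 = 0,
           k_plus_8 = 0, k_minus_8 = 0)
}

# random nonnegative state / rate set under a fixed seed, for
# property-style loops
random_state <- function() {
  species_state(E = runif(1, 0, 2), S = runif(1, 0, 200),
                ES = runif(1, 0, 1), EP = runif(1, 0, 1),
                P = runif(1, 0, 50), I = runif(1, 0, 5),
                PI = runif(1, 0, 3), EPI = runif(1, 0, 1),
                PIE = runif(1, 0, 1))
}

random_rates <- function() {
  rate_set(k_plus_1 = runif(1), k_minus_1 = runif(1, 0, 200),
           k_plus_2 = runif(1, 0, 20),
           k_plus_3 = runif(1), k_minus_3 = runif(1, 0, 100),
           k_plus_4 = runif(1, 0, 0.01), k_minus_4 = runif(1, 0, 1e-3),
           k_plus_5 = runif(1, 0, 0.5), k_minus_5 = runif(1, 0, 1),
           k_plus_6 = runif(1), k_minus_6 = runif(1, 0, 50),
           k_plus_7 = runif(1, 0, 400), k_minus_7 = runif(1, 0, 0.01),
           k_plus_8 = runif(1), k_minus_8 = runif(1, 0, 50))
}

# closed-form fixed point of the five-species No-TFPI (reactions 1-3)
# flow subsystem: ES from the reaction-1 balance, P = k2*ES/k_flow,
# S = S_up - P, EP from the reaction-3 balance, enzyme conservation
# closing the system.  Independent of the integrate+Newton solver.
ni_steady_state_oracle <- function(rates, kflow, enzyme_total = 1,
                                   S_up = 170) {
  k <- unclass(rates)
  k1 <- k[["k_plus_1"]]; km1 <- k[["k_minus_1"]]; k2 <- k[["k_plus_2"]]
  k3 <- k[["k_plus_3"]]; km3 <- k[["k_minus_3"]]
  efun <- function(E) {
    g <- function(S) {
      ES <- k1 * E * S / (km1 + k2)
      S_up - k2 * ES / kflow - S
    }
    S <- uniroot(g, c(0, S_up), tol = 1e-14)$root
    ES <- k1 * E * S / (km1 + k2)
    P <- k2 * ES / kflow
    EP <- (k2 * ES + k3 * E * P) / km3
    list(E = E, S = S, ES = ES, EP = EP, P = P,
         gap = E + ES + EP - enzyme_total)
  }
  E <- uniroot(function(E) efun(E)$gap, c(1e-12, enzyme_total),
               tol = 1e-15)$root
  out <- efun(E)
  species_state(E = out$E, S = out$S, ES = out$ES, EP = out$EP,
                P = out$P)
}
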