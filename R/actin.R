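## actin_laws: closed-form force and rate laws of actin polymerization at
## endocytic sites. Only the analytic laws are implemented; the full
## Brownian-dynamics network simulation is out of scope.
##
## Unit conventions: forces pN, lengths nm, concentrations uM, rates 1/s,
## thermal energy pN*nm. Every returned quantity carries a "unit" attribute
## so downstream code can assert dimensional consistency.

with_unit <- function(x, unit) structure(x, unit = unit)

#' Unit of a quantity returned by the actin-law functions
#' @param x a value returned by one of the actin-law functions.
#' @return the unit string, or NA if none attached.
#' @export
unit_of <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) NA_character_ else u
}

#' Brownian-ratchet parameters
#'
#' @param kon polymerization rate constant, per uM per s. (Printed rate
#'   tables often list kon in 1/s; a rate is only obtained after
#'   multiplying by the monomer concentration, so per-uM-per-s is the
#'   dimensionally consistent reading.)
#' @param koff depolymerization rate, 1/s.
#' @param A1 free G-actin concentration, uM.
#' @param delta extension added per monomer, nm (default 2.8).
#' @param kBT thermal energy, pN nm (default 4.114, 25 degrees C).
#' @return a `ratchet_params` list; element `A1_crit` is the critical
#'   G-actin concentration `koff/kon` (uM).
#' @export
ratchet_params <- function(kon = 400, koff = 1.4, A1 = 40, delta = 2.8,
                           kBT = 4.114) {
  for (nm in c("kon", "koff", "A1", "delta", "kBT")) {
    check_number(get(nm), nm, 0, strict = TRUE)
  }
  structure(list(kon = kon, koff = koff, A1 = A1, delta = delta, kBT = kBT,
                 A1_crit = koff / kon),
            class = "ratchet_params")
}

#' Brownian-ratchet polymerization rate under load
#'
#' A filament growing against an opposing force `f` adds monomers at rate
#' `k+ = kon * A1 * exp(-f * delta / kBT)`; the depolymerization rate
#' `k- = koff` is force-independent.
#'
#' @param p a [ratchet_params()].
#' @param force opposing force, pN (>= 0; vectorized).
#' @return list with `k_plus` and `k_minus` (1/s, unit-tagged).
#' @export
polymerization_rate <- function(p, force = 0) {
  if (!inherits(p, "ratchet_params")) stopf("'p' must be ratchet_params")
  if (any(force < 0)) stopf("'force' must be >= 0 (opposing load)")
  kp <- p$kon * p$A1 * exp(-force * p$delta / p$kBT)
  list(k_plus = with_unit(kp, "1/s"),
       k_minus = with_unit(rep(p$koff, length(kp)), "1/s"))
}

#' Stall force of actin polymerization
#'
#' The force at which net assembly stops:
#' `f0 = kBT * log(A1 / A1_crit) / delta`, with `A1_crit = koff/kon`.
#' Requires `A1 > A1_crit` (above the critical concentration).
#'
#' @param p a [ratchet_params()].
#' @return stall force, pN (unit-tagged).
#' @export
stall_force <- function(p) {
  if (!inherits(p, "ratchet_params")) stopf("'p' must be ratchet_params")
  if (p$A1 < p$A1_crit) {
    stopf("stall force requires A1 > critical concentration (%g uM)",
          p$A1_crit)
  }
  with_unit(p$kBT * log(p$A1 / p$A1_crit) / p$delta, "pN")
}

#' Crosslinker parameters
#'
#' @param koff0 unbinding rate at zero force, 1/s (default 0.025).
#' @param fu unbinding force scale, pN (default 10).
#' @return a `crosslinker_params` list.
#' @export
crosslinker_params <- function(koff0 = 0.025, fu = 10) {
  check_number(koff0, "koff0", 0, strict = TRUE)
  check_number(fu, "fu", 0, strict = TRUE)
  structure(list(koff0 = koff0, fu = fu), class = "crosslinker_params")
}

#' Kramers-law crosslinker unbinding rate
#'
#' Force-accelerated dissociation: `ku = koff0 * exp(f / fu)`.
#'
#' @param c a [crosslinker_params()].
#' @param force load on the bond, pN (>= 0; vectorized).
#' @return unbinding rate, 1/s (unit-tagged).
#' @export
crosslinker_unbinding_rate <- function(c, force = 0) {
  if (!inherits(c, "crosslinker_params")) {
    stopf("'c' must be crosslinker_params")
  }
  if (any(force < 0)) stopf("'force' must be >= 0")
  with_unit(c$koff0 * exp(force / c$fu), "1/s")
}

#' Invagination resistance law
#'
#' @param f0 lift-off force, pN (default 200: force needed to initially
#'   lift the membrane against turgor).
#' @param L0 snap-through depth, nm (default 60).
#' @param peak_force force at the snap-through depth, pN (default 1000);
#'   sets the slope `k_pi = (peak_force - f0) / L0`.
#' @return an `invagination_law` list with `f0`, `L0`, `k_pi`.
#' @export
invagination_law <- function(f0 = 200, L0 = 60, peak_force = 1000) {
  check_number(f0, "f0", 0)
  check_number(L0, "L0", 0, strict = TRUE)
  check_number(peak_force, "peak_force", f0)
  structure(list(f0 = f0, L0 = L0, k_pi = (peak_force - f0) / L0),
            class = "invagination_law")
}

#' Membrane resistance at invagination depth L
#'
#' Piecewise force opposing invagination: 0 for `L <= 0`; `f0 + k_pi * L`
#' for `0 < L < L0`; 0 for `L >= L0` (the snap-through transition, beyond
#' which endocytosis is regarded as successful).
#'
#' @param law an [invagination_law()].
#' @param L invagination depth, nm (vectorized).
#' @return resisting force, pN (unit-tagged).
#' @export
invagination_resistance <- function(law, L) {
  if (!inherits(law, "invagination_law")) {
    stopf("'law' must be an invagination_law")
  }
  f <- ifelse(L <= 0 | L >= law$L0, 0, law$f0 + law$k_pi * L)
  with_unit(f, "pN")
}
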