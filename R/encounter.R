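#' Mean encounter time with a trap on a spherical membrane
#'
#' Closed-form mean first-encounter time of a particle diffusing on the
#' surface of a sphere of radius `R_s` with a static absorbing trap of radius
#' `r_t`:
#' \deqn{\tau = \frac{R_s^2}{D}\left(-2\ln\frac{r_t}{R_s} + 2\ln 2 - 1\right).}
#' Used both to sanity-check simulated protein-only search times and, with
#' the relative diffusion constant of two monomers, to bound the
#' dimerization timescale (see [dimer_encounter_time()]).
#'
#' @param R_s sphere radius (micrometres).
#' @param r_t trap radius (micrometres), `0 < r_t < R_s`.
#' @param D surface diffusion constant (micrometres^2 per second).
#' @param unit `"s"` (default) or `"min"`.
#' @return Mean encounter time in the requested unit.
#' @examples
#' sphere_trap_time(R_s = 0.69, r_t = 0.050, D = 0.20)  # ~13 s
#' @export
sphere_trap_time <- function(R_s, r_t, D, unit = c("s", "min")) {
  unit <- match.arg(unit)
  if (any(r_t <= 0) || any(R_s <= 0) || any(D <= 0))
    stop("R_s, r_t and D must be positive")
  if (any(r_t >= R_s)) stop("trap radius must be smaller than sphere radius")
  tau <- (R_s^2 / D) * (-2 * log(r_t / R_s) + 2 * log(2) - 1)
  if (unit == "min") tau / 60 else tau
}

#' Mean dimerization time of two membrane monomers
#'
#' Two monomers diffusing on a spherical membrane meet, on average, after the
#' sphere-surface trap time evaluated with the relative diffusion constant
#' `D = 2 * D1` and contact radius `r_t = 2 * r1`.  The sphere radius is
#' derived from the membrane surface area, `R_s = sqrt(A / (4 pi))`.
#'
#' @param D1 monomer diffusion constant (micrometres^2 per second).
#' @param r1 monomer radius (micrometres).
#' @param surface_area membrane area (micrometres^2).
#' @param unit `"s"` or `"min"`.
#' @return Mean first-encounter time.
#' @examples
#' # typical E. coli surface area, single-TM-helix monomer
#' dimer_encounter_time(D1 = 0.34, r1 = 0.0024, surface_area = 4.40)
#' @export
dimer_encounter_time <- function(D1, r1, surface_area, unit = c("s", "min")) {
  if (surface_area <= 0) stop("surface_area must be positive")
  R_s <- sqrt(surface_area / (4 * pi))
  sphere_trap_time(R_s = R_s, r_t = 2 * r1, D = 2 * D1, unit = unit)
}

#' Mean encounter time with a membrane target from a confined volume
#'
#' Mean time for a particle with diffusion constant `D` in a confining
#' domain of volume `V` to locate a target of radius `r_t` on the domain
#' surface, \eqn{\tau \approx V / (4 r_t D)}.  Brackets the DNA-only search:
#' evaluated with the single-bead diffusion constant it underestimates the
#' lattice-simulation result, with the chain-scaled constant `D0 / N` it
#' overestimates it, because neither limit accounts for polymer dynamics.
#'
#' @param V domain volume (micrometres^3).
#' @param r_t target radius (micrometres).
#' @param D diffusion constant (micrometres^2 per second).
#' @param unit `"s"` or `"min"`.
#' @return Mean encounter time.
#' @examples
#' volume_trap_time(V = 1, r_t = 0.05, D = 0.006, unit = "min")      # ~14 min
#' volume_trap_time(V = 1, r_t = 0.05, D = 0.006 / 100, unit = "min")  # ~1400
#' @export
volume_trap_time <- function(V, r_t, D, unit = c("s", "min")) {
  unit <- match.arg(unit)
  if (any(V <= 0) || any(r_t <= 0) || any(D <= 0))
    stop("V, r_t and D must be positive")
  tau <- V / (4 * r_t * D)
  if (unit == "min") tau / 60 else tau
}
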