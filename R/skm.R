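## Spiegler-Kedem transport core: Arrhenius permeability, film-theory
## polarization, explicit water-flux model and implicit solution-flux model.

#' Membrane parameter set
#'
#' Collects the parameters of the Spiegler-Kedem transport model:
#' \describe{
#'   \item{lp0}{pre-exponential hydraulic permeability, L/m2/h/bar.}
#'   \item{dh_over_r}{Arrhenius activation parameter dH/R (dissolution
#'     enthalpy over the gas constant), K.  0 disables the temperature
#'     dependence.}
#'   \item{sigma}{reflection coefficient, dimensionless in \[0, 1\]; the
#'     fraction of the osmotic pressure difference effective in opposing
#'     flux.}
#'   \item{k}{film-theory mass-transfer coefficient, L/m2/h.  `Inf` is an
#'     explicit sentinel meaning "no concentration polarization".}
#'   \item{ps}{solute permeability, L/m2/h; optional (`NA`) unless solute-flux
#'     computations are requested.}
#'   \item{t_ref}{reference temperature of the Arrhenius law, K.}
#' }
#'
#' @param lp0,dh_over_r,sigma,k,ps,t_ref see above.
#' @return An object of class `membrane_params`.
#' @examples
#' membrane_params(lp0 = 2.8, dh_over_r = 3181, sigma = 0.999, k = 13)
#' @export
membrane_params <- function(lp0, dh_over_r = 0, sigma = 1, k = Inf,
                            ps = NA_real_, t_ref = 293.15) {
  chk <- function(ok, msg) if (!isTRUE(ok)) skm_stop(msg, "skm_domain_error")
  chk(is.numeric(lp0) && length(lp0) == 1 && is.finite(lp0) && lp0 > 0,
      "lp0 must be a single positive number")
  chk(is.numeric(dh_over_r) && length(dh_over_r) == 1 &&
        is.finite(dh_over_r) && dh_over_r >= 0,
      "dh_over_r must be a single non-negative number (K)")
  chk(is.numeric(sigma) && length(sigma) == 1 && sigma >= 0 && sigma <= 1,
      "sigma must lie in [0, 1]")
  chk(is.numeric(k) && length(k) == 1 && k > 0,
      "k must be positive (Inf disables polarization)")
  chk(length(ps) == 1 && (is.na(ps) || (is.numeric(ps) && ps >= 0)),
      "ps must be NA or a single non-negative number")
  chk(is.numeric(t_ref) && length(t_ref) == 1 && is.finite(t_ref) &&
        t_ref > 0, "t_ref must be a single positive temperature (K)")
  structure(list(lp0 = lp0, dh_over_r = dh_over_r, sigma = sigma, k = k,
                 ps = as.numeric(ps), t_ref = t_ref),
            class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("Spiegler-Kedem membrane parameters\n")
  cat(sprintf("  Lp0   = %g L/m2/h/bar   (reference T = %g K)\n",
              x$lp0, x$t_ref))
  cat(sprintf("  dH/R  = %g K\n", x$dh_over_r))
  cat(sprintf("  sigma = %g\n", x$sigma))
  cat(sprintf("  k     = %g L/m2/h%s\n", x$k,
              if (is.infinite(x$k)) "  (no polarization)" else ""))
  if (!is.na(x$ps)) cat(sprintf("  Ps    = %g L/m2/h\n", x$ps))
  invisible(x)
}

.check_temperature <- function(temperature) {
  if (any(!is.finite(temperature) | temperature <= 0))
    skm_stop("temperature must be positive (K)", "skm_domain_error")
}

#' Temperature-dependent hydraulic permeability
#'
#' Arrhenius law
#' `Lp(T) = Lp0 * exp(-(dH/R) * (1/T - 1/T0))`,
#' so `Lp(T0) = Lp0` and permeability rises with temperature for positive
#' activation parameter.
#'
#' @param params a [membrane_params].
#' @param temperature process temperature(s), K.
#' @return Permeability in L/m2/h/bar, vectorized over `temperature`.
#' @export
hydraulic_permeability <- function(params, temperature) {
  .check_temperature(temperature)
  params$lp0 * exp(-params$dh_over_r * (1 / temperature - 1 / params$t_ref))
}

#' Pure-water permeate flux (explicit pressure model)
#'
#' With no solute there is no osmotic counter-pressure and the flux is linear
#' in the transmembrane pressure: `Jv = Lp(T) * dP`.
#'
#' @param params a [membrane_params].
#' @param tmp transmembrane pressure(s), bar.
#' @param temperature temperature(s), K.
#' @return Flux in L/m2/h.
#' @export
water_flux <- function(params, tmp, temperature) {
  if (any(!is.finite(tmp) | tmp < 0))
    skm_stop("transmembrane pressure must be non-negative (bar)",
             "skm_domain_error")
  hydraulic_permeability(params, temperature) * tmp
}

#' Film-theory wall concentration
#'
#' Concentration polarization accumulates solute at the membrane wall; the
#' steady-state film model gives
#' `Cm = Cp + (Cf - Cp) * exp(Jv / k)`,
#' which is never below the bulk feed concentration and collapses to `Cf`
#' when the flux is zero or back-transport is infinitely fast (`k = Inf`).
#'
#' @param c_feed,c_permeate bulk feed and permeate concentrations, mol/L.
#' @param jv permeate flux, L/m2/h.
#' @param k mass-transfer coefficient, L/m2/h (`Inf` disables polarization).
#' @return Wall concentration `Cm`, mol/L.
#' @export
wall_concentration <- function(c_feed, c_permeate, jv, k) {
  if (any(c_permeate < 0 | c_permeate > c_feed))
    skm_stop("need 0 <= c_permeate <= c_feed", "skm_domain_error")
  if (any(jv < 0)) skm_stop("jv must be non-negative", "skm_domain_error")
  if (any(k <= 0)) skm_stop("k must be positive", "skm_domain_error")
  if (any(jv / k > .EXP_OVERFLOW))
    skm_stop(paste0("jv/k exceeds ", .EXP_OVERFLOW,
                    ": polarization factor overflows; ",
                    "use a larger mass-transfer coefficient k"),
             "skm_overflow_error")
  c_permeate + (c_feed - c_permeate) * exp(jv / k)
}

#' Van 't Hoff osmotic pressure difference
#'
#' Ideal dilute-solution osmotic pressure across the membrane,
#' `dPi = R * T * (Cm - Cp)` with `R = 0.083145 L bar / (mol K)`, evaluated on
#' tyrosol-equivalent molarity (polyphenols are taken as the dominant osmotic
#' species).
#'
#' @param c_wall wall concentration `Cm`, mol/L.
#' @param c_permeate permeate concentration `Cp`, mol/L.
#' @param temperature temperature, K.
#' @return Osmotic pressure difference, bar.
#' @export
osmotic_pressure_difference <- function(c_wall, c_permeate, temperature) {
  .check_temperature(temperature)
  if (any(c_permeate < 0 | c_wall < c_permeate))
    skm_stop("need c_wall >= c_permeate >= 0", "skm_domain_error")
  .R_GAS_BAR * temperature * (c_wall - c_permeate)
}

#' Implicit Spiegler-Kedem permeate flux
#'
#' Solves the implicit flux equation of the polarized Spiegler-Kedem model,
#' `Jv = Lp(T) * [dP - sigma * R * T * (Cf - Cp) * exp(Jv / k)]`,
#' for the steady-state permeate flux.  The right-hand side is strictly
#' decreasing in `Jv`, so a root in `[0, Lp(T) * dP]` is unique when it
#' exists; it is located with a bisection-safeguarded Newton iteration started
#' from 20 L/m2/h and polished to a residual below `1e-10 * max(1, Jv)`.
#'
#' @param params a [membrane_params]; `sigma = 0` or zero concentration
#'   difference reduces to [water_flux()], `k = Inf` gives the closed-form
#'   unpolarized flux `Lp(T) * (dP - sigma * R * T * (Cf - Cp))`.
#' @param tmp transmembrane pressure(s), bar.
#' @param temperature temperature(s), K.
#' @param c_feed,c_permeate bulk concentrations, mol/L (permeate concentration
#'   is data here, not a model output).
#' @param on_no_root `"error"` (default) raises a no-solution error when the
#'   driving pressure cannot overcome the polarized osmotic pressure even at
#'   zero flux; `"na"` returns `NA` for such elements instead.
#' @return Flux(es) in L/m2/h; vectorized with recycling across the four
#'   state arguments.
#' @examples
#' p <- membrane_params(lp0 = 2.5, dh_over_r = 4529, sigma = 0.999, k = 13)
#' solve_flux(p, tmp = 9.5, temperature = 298.15,
#'            c_feed = 7.03e-3, c_permeate = 4.42e-4)
#' @export
solve_flux <- function(params, tmp, temperature, c_feed = 0, c_permeate = 0,
                       on_no_root = c("error", "na")) {
  on_no_root <- match.arg(on_no_root)
  n <- max(length(tmp), length(temperature), length(c_feed),
           length(c_permeate))
  tmp <- rep_len(tmp, n); temperature <- rep_len(temperature, n)
  c_feed <- rep_len(c_feed, n); c_permeate <- rep_len(c_permeate, n)
  if (any(!is.finite(tmp) | tmp <= 0))
    skm_stop("transmembrane pressure must be positive (bar)",
             "skm_domain_error")
  if (any(c_permeate < 0 | c_permeate > c_feed))
    skm_stop("need 0 <= c_permeate <= c_feed", "skm_domain_error")
  lp <- hydraulic_permeability(params, temperature)
  osm0 <- params$sigma * .R_GAS_BAR * temperature * (c_feed - c_permeate)

  # Infeasible cells: even at Jv = 0 the polarized osmotic pressure (equal to
  # the bulk osmotic pressure there) exceeds the applied pressure.
  deficit <- osm0 - tmp
  infeasible <- deficit > 0
  if (any(infeasible) && on_no_root == "error")
    skm_stop(sprintf(
      paste0("no non-negative flux solution: osmotic pressure exceeds the ",
             "applied pressure by %.4g bar (first offending element %d)"),
      max(deficit), which(infeasible)[1]), "skm_no_solution_error",
      osmotic_deficit = deficit[infeasible])

  jv <- rep(NA_real_, n)
  act <- which(!infeasible)
  if (length(act) > 0L) {
    lpA <- lp[act]; tmpA <- tmp[act]; osmA <- osm0[act]
    kk <- params$k
    x <- rep(NA_real_, length(act))
    # explicit cases: no polarization feedback, or zero permeability
    closed <- osmA <= 0 | is.infinite(kk) | lpA == 0
    x[closed] <- lpA[closed] * (tmpA[closed] - pmax(osmA[closed], 0))
    gen <- which(!closed)
    if (length(gen) > 0L) {
      lpG <- lpA[gen]; tmpG <- tmpA[gen]; losm <- log(osmA[gen])
      # Bracket: the root cannot exceed either the unopposed flux Lp*dP or
      # the osmotic balance point k*log(dP/osm) (where the polarized osmotic
      # pressure equals the applied pressure), so exp(Jv/k) stays <= dP/osm
      # on the bracket and the polarization term, evaluated in log space,
      # never overflows.  The iteration works on the scaled residual
      # phi(j) = j/Lp - (dP - osm*exp(j/k)), which stays finite even when an
      # extreme Arrhenius argument drives Lp itself to overflow; phi has the
      # same unique root and is strictly increasing, with phi(0) <= 0 on
      # feasible cells.
      lo <- rep(0, length(gen))
      hi <- pmin(lpG * tmpG, kk * (log(tmpG) - losm))
      phi <- function(j) j / lpG - (tmpG - exp(losm + j / kk))
      # The contract tolerance is on the unscaled residual Lp*phi, i.e.
      # |phi| < tol * max(1, Jv) / Lp.  That is representable in double
      # precision for any physically meaningful permeability; for the
      # unphysically large Lp an optimizer may probe (overflow-scale
      # Arrhenius arguments) the criterion switches to the accuracy of the
      # root itself.
      tol <- function(g, eps) ifelse(lpG <= 1e3, eps * pmax(1, g) / lpG,
                                     eps * pmax(tmpG, g))
      g <- pmin(pmax(20, lo), hi)        # documented Newton starting guess
      for (it in seq_len(200L)) {
        fg <- phi(g)
        if (all(abs(fg) <= tol(g, 1e-12))) break
        lo[fg < 0] <- g[fg < 0]
        hi[fg > 0] <- g[fg > 0]
        fp <- 1 / lpG + exp(losm + g / kk) / kk
        gn <- g - fg / fp
        outside <- !is.finite(gn) | gn < lo | gn > hi
        gn[outside] <- (lo[outside] + hi[outside]) / 2
        # accept the Newton point only if it halves the residual;
        # otherwise fall back to bisection, which always makes progress
        stall <- abs(phi(gn)) > 0.5 * abs(fg)
        gn[stall] <- (lo[stall] + hi[stall]) / 2
        g <- gn
      }
      stopifnot(all(abs(phi(g)) < tol(g, 1e-10)))
      x[gen] <- g
    }
    jv[act] <- x
  }
  jv
}

#' Spiegler-Kedem solute flux
#'
#' `Js = Ps * (Cm - Cp) + (1 - sigma) * Cm * Jv`: a diffusive term driven by
#' the wall-to-permeate concentration difference plus convective drag of the
#' fraction of solute not reflected by the membrane.
#'
#' @param params a [membrane_params] with `ps` set.
#' @param c_wall,c_permeate wall and permeate concentrations, mol/L.
#' @param jv permeate flux, L/m2/h.
#' @return Solute flux in (mol/L) * L/m2/h.
#' @export
solute_flux <- function(params, c_wall, c_permeate, jv) {
  if (is.na(params$ps))
    skm_stop("solute flux needs the solute permeability ps in membrane_params",
             "skm_config_error")
  params$ps * (c_wall - c_permeate) + (1 - params$sigma) * c_wall * jv
}

#' Per-observation solute permeability estimate
#'
#' Inverts the solute-flux relation using the mass balance `Js = Jv * Cp`
#' (what leaves in the permeate must have crossed the membrane):
#' `Ps = (Jv * Cp - (1 - sigma) * Cm * Jv) / (Cm - Cp)`,
#' with the wall concentration computed by [wall_concentration()] from the
#' parameter set's mass-transfer coefficient.  A diagnostic, one value per
#' observation.
#'
#' @param params a [membrane_params] (`sigma`, `k` used).
#' @param c_feed,c_permeate,jv observed state; `jv` must be positive.
#' @return Estimated `Ps`, L/m2/h, vectorized.
#' @export
estimate_solute_permeability <- function(params, c_feed, c_permeate, jv) {
  if (any(jv <= 0))
    skm_stop("solute permeability estimation needs jv > 0",
             "skm_domain_error")
  cm <- wall_concentration(c_feed, c_permeate, jv, params$k)
  if (any(cm - c_permeate <= 0))
    skm_stop("degenerate state: wall concentration equals permeate concentration",
             "skm_domain_error")
  (jv * c_permeate - (1 - params$sigma) * cm * jv) / (cm - c_permeate)
}

#' Observed solute rejection
#'
#' `R = 1 - Cp / Cf`, the fraction of solute retained as seen from the bulk
#' concentrations.
#'
#' @param c_feed,c_permeate bulk concentrations, mol/L; `c_feed` must be
#'   positive.
#' @return Rejection fraction in \[0, 1\], vectorized.
#' @export
observed_rejection <- function(c_feed, c_permeate) {
  if (any(c_feed <= 0))
    skm_stop("rejection needs c_feed > 0", "skm_domain_error")
  if (any(c_permeate < 0 | c_permeate > c_feed))
    skm_stop("need 0 <= c_permeate <= c_feed", "skm_domain_error")
  1 - c_permeate / c_feed
}

#' Irreversible fouling index
#'
#' Percentage loss of pure-water flux after the membrane has processed the
#' feed stream, at matched pressure and temperature:
#' `FI = 100 * (1 - jv_used / jv_new)`.
#'
#' @param jv_new flux of the pristine membrane, L/m2/h (positive).
#' @param jv_used flux of the used membrane at the same condition, L/m2/h.
#' @return Fouling index in percent, vectorized.
#' @export
fouling_index <- function(jv_new, jv_used) {
  if (any(jv_new <= 0))
    skm_stop("fouling index needs jv_new > 0", "skm_domain_error")
  if (any(jv_used < 0))
    skm_stop("jv_used must be non-negative", "skm_domain_error")
  100 * (1 - jv_used / jv_new)
}

#' Fouling-index table from the bundled water series
#'
#' Matches the series-I (pristine) and series-II (used) pure-water fluxes cell
#' by cell over the shared (pressure, temperature) grid and applies
#' [fouling_index()].
#'
#' @return Data frame with columns `tmp`, `temperature`, `jv_new`, `jv_used`,
#'   `fi_pct`.
#' @export
fouling_index_table <- function() {
  a <- as.data.frame(load_water_fluxes("I"))
  b <- as.data.frame(load_water_fluxes("II"))
  m <- merge(a[, c("tmp", "temperature", "jv")],
             b[, c("tmp", "temperature", "jv")],
             by = c("tmp", "temperature"), suffixes = c("_new", "_used"))
  m <- m[order(m$tmp, m$temperature), ]
  rownames(m) <- NULL
  m$fi_pct <- fouling_index(m$jv_new, m$jv_used)
  names(m)[3:4] <- c("jv_new", "jv_used")
  m
}
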