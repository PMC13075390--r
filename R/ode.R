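#' Sampled time-concentration profile
#'
#' A container for a sampled concentration-time series with dose and route
#' metadata, used by [nca()] and for comparing closed forms against the
#' numeric integrator.
#'
#' @param times sampling times, h (strictly increasing, >= 0).
#' @param concentrations concentrations at `times` (>= 0, same length).
#' @param dose administered dose (recorded for NCA).
#' @param route free-text route tag (e.g. `"iv_bolus"`, `"oral"`).
#' @param conc_unit,time_unit unit strings recorded for reporting.
#' @return an object of class `pk_profile`.
#' @export
pk_profile <- function(times, concentrations, dose = NA_real_,
                       route = "unknown", conc_unit = "umol/mL",
                       time_unit = "h") {
  stopifnot(is.numeric(times), is.numeric(concentrations),
            length(times) == length(concentrations))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  structure(
    list(times = as.numeric(times),
         concentrations = as.numeric(concentrations),
         dose = dose, route = route,
         conc_unit = conc_unit, time_unit = time_unit),
    class = "pk_profile"
  )
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf("<pk_profile> %d samples over %g-%g %s, route %s, dose %g\n",
              length(x$times), min(x$times), max(x$times), x$time_unit,
              x$route, x$dose))
  invisible(x)
}

#' @rdname pk_profile
#' @param x a `pk_profile`.
#' @param ... unused.
#' @export
as.data.frame.pk_profile <- function(x, ...) {
  data.frame(time = x$times, concentration = x$concentrations)
}

#' Numeric integration of the linear kinetic models
#'
#' Stiff-safe numeric integration (via `deSolve::lsoda`) of the catenary
#' chain or the one-compartment model, used as the independent oracle for
#' the closed-form expressions.
#'
#' @param spec a [chain_spec()] or [one_compartment_spec()].
#' @param times output time grid, h (starting at 0).
#' @param route for a one-compartment spec: `"iv_bolus"` or `"oral"`.
#' @param species for a chain spec: which species to return.
#' @param rtol,atol integrator tolerances.
#' @return a [pk_profile()] of the requested species/route concentration.
#' @examples
#' sp <- chain_spec(0.07, 0.12, 0.42, 90, 20)
#' simulate_ode(sp, seq(0, 24, 0.5), species = "M2")
#' @export
simulate_ode <- function(spec, times, route = c("iv_bolus", "oral"),
                         species = c("D", "M1", "M2", "M3"),
                         rtol = 1e-10, atol = 1e-12) {
  stopifnot(is.numeric(times), length(times) >= 2L)
  if (times[1L] != 0) times <- c(0, times)
  if (inherits(spec, "chain_spec")) {
    species <- match.arg(species)
    deriv <- function(t, y, parms) {
      list(c(-spec$k_D * y[1L],
             spec$k_D * y[1L] - spec$k_M1 * y[2L],
             spec$k_M1 * y[2L] - spec$k_M2 * y[3L],
             spec$k_M2 * y[3L]))
    }
    y0 <- c(D = spec$dose, M1 = 0, M2 = 0, M3 = 0)
    out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    conc <- pmax(out[, species] / spec$V, 0)
    return(pk_profile(out[, "time"], conc, dose = spec$dose,
                      route = paste0("chain:", species)))
  }
  if (inherits(spec, "one_compartment_spec")) {
    route <- match.arg(route)
    if (route == "iv_bolus") {
      deriv <- function(t, y, parms) list(-spec$k_d * y)
      y0 <- c(A = spec$dose)
      out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                            rtol = rtol, atol = atol)
      conc <- pmax(out[, "A"] / spec$V_body, 0)
    } else {
      deriv <- function(t, y, parms) {
        list(c(-spec$k_a * y[1L],
               spec$k_a * spec$F_bio * y[1L] - spec$k_d * y[2L]))
      }
      y0 <- c(G = spec$dose, A = 0)
      out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                            rtol = rtol, atol = atol)
      conc <- pmax(out[, "A"] / spec$V_body, 0)
    }
    return(pk_profile(out[, "time"], conc, dose = spec$dose, route = route))
  }
  stop("spec must be a chain_spec or one_compartment_spec", call. = FALSE)
}
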