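#' Hepatic process parameter bundle
#'
#' Parameters for the series hepatic clearance model. The entering clearance
#' is hepatic blood flow; the leaving rate-defining processes are the
#' unbound intrinsic clearance `f_uB * CL_H_int` (metabolism plus biliary
#' excretion, in parallel) and, when basolateral transport is rate-defining,
#' the unbound net transport `f_uB * (CL_int_influx - CL_int_efflux)`.
#'
#' When `transport_relevant = TRUE`, influx must exceed efflux: a negative
#' net basolateral transport can never be a rate-defining process.
#'
#' @param Q_H hepatic blood flow, mL/min (> 0; `Inf` or
#'   [infinite_process()] for the flow-unlimited form).
#' @param f_uB fraction unbound in blood, (0, 1].
#' @param CL_int_metabolism,CL_int_biliary intrinsic metabolic and biliary
#'   clearances, mL/min (>= 0, not both 0).
#' @param CL_int_influx,CL_int_efflux basolateral transporter intrinsic
#'   clearances, mL/min (>= 0).
#' @param transport_relevant logical; include the net transport term as a
#'   rate-defining process.
#' @return an object of class `hepatic_processes`.
#' @examples
#' hepatic_processes(Q_H = 1500, f_uB = 1, CL_int_metabolism = 1500)
#' @export
hepatic_processes <- function(Q_H, f_uB = 1,
                              CL_int_metabolism = 0, CL_int_biliary = 0,
                              CL_int_influx = 0, CL_int_efflux = 0,
                              transport_relevant = FALSE) {
  qh <- process_num(Q_H)
  stopifnot(qh > 0, f_uB > 0, f_uB <= 1,
            CL_int_metabolism >= 0, CL_int_biliary >= 0,
            CL_int_influx >= 0, CL_int_efflux >= 0)
  if (CL_int_metabolism + CL_int_biliary <= 0) {
    stop("hepatic intrinsic clearance (metabolism + biliary) must be > 0",
         call. = FALSE)
  }
  if (isTRUE(transport_relevant) && CL_int_influx <= CL_int_efflux) {
    stop("basolateral transport can only be rate-defining when influx > efflux ",
         "(got influx = ", CL_int_influx, ", efflux = ", CL_int_efflux, ")",
         call. = FALSE)
  }
  structure(
    list(Q_H = qh, f_uB = f_uB,
         CL_int_metabolism = CL_int_metabolism,
         CL_int_biliary = CL_int_biliary,
         CL_H_int = CL_int_metabolism + CL_int_biliary,
         CL_int_influx = CL_int_influx, CL_int_efflux = CL_int_efflux,
         transport_relevant = isTRUE(transport_relevant)),
    class = "hepatic_processes"
  )
}

#' @export
print.hepatic_processes <- function(x, ...) {
  cat(sprintf("<hepatic_processes> Q_H = %g, f_uB = %g, CL_H,int = %g mL/min%s\n",
              x$Q_H, x$f_uB, x$CL_H_int,
              if (x$transport_relevant)
                sprintf(", net transport = %g", x$CL_int_influx - x$CL_int_efflux)
              else ""))
  invisible(x)
}

#' Hepatic intrinsic clearance
#'
#' Metabolism and biliary excretion are parallel elimination pathways, so
#' the hepatic intrinsic clearance is their sum.
#'
#' @param CL_int_metabolism,CL_int_biliary intrinsic clearances, mL/min.
#' @return intrinsic clearance, mL/min (numeric scalar).
#' @examples
#' hepatic_intrinsic(3, 2)   # 5
#' @export
hepatic_intrinsic <- function(CL_int_metabolism, CL_int_biliary = 0) {
  stopifnot(CL_int_metabolism >= 0, CL_int_biliary >= 0)
  # an absent pathway contributes nothing; at least one must be active
  terms <- Filter(function(x) x > 0, list(CL_int_metabolism, CL_int_biliary))
  if (length(terms) == 0L) {
    stop("hepatic intrinsic clearance must be > 0", call. = FALSE)
  }
  combine_parallel(terms, label = "CL_H,int")$value
}

#' Hepatic clearance from in-series rate-defining processes
#'
#' Series combination of up to three rate-defining processes:
#' `1/CL_H = 1/Q_H + 1/(f_uB*CL_H_int) + 1/(f_uB*(influx - efflux))`.
#' Without the transport term this solves to the familiar
#' `Q_H * f_uB * CL_H_int / (Q_H + f_uB * CL_H_int)` — derived here purely
#' from series composition, with no mechanistic liver model assumed. With
#' `Q_H = Inf` it reduces to the flow-unlimited transport/metabolism form.
#'
#' @param p a [hepatic_processes()] bundle.
#' @return hepatic clearance as a `pk_process` in mL/min.
#' @examples
#' # flow and unbound intrinsic clearance both 1500 -> 750 mL/min
#' hepatic_clearance(hepatic_processes(1500, 1, 1500))
#' @export
hepatic_clearance <- function(p) {
  stopifnot(inherits(p, "hepatic_processes"))
  terms <- list(
    if (is.infinite(p$Q_H)) infinite_process("clearance", label = "Q_H")
    else process_value(p$Q_H, "clearance", label = "Q_H"),
    process_value(p$f_uB * p$CL_H_int, "clearance", label = "fuB*CL_H,int")
  )
  if (p$transport_relevant) {
    terms <- c(terms, list(process_value(
      p$f_uB * (p$CL_int_influx - p$CL_int_efflux), "clearance",
      label = "fuB*(influx - efflux)")))
  }
  combine_series(terms, label = "CL_H")
}

#' Extended clearance model hepatic clearance
#'
#' The extended clearance model (ECM) form
#' `CL_H = CL_int_influx * f_uB * CL_H_int / (CL_H_int + CL_int_efflux)`,
#' implemented for side-by-side comparison with the series composition
#' form. Unlike [hepatic_clearance()], it is evaluated even when efflux
#' exceeds influx (the ECM does not treat the net difference as a single
#' rate-defining process, which is precisely what the comparison exposes).
#'
#' @param p a [hepatic_processes()] bundle (with `transport_relevant`
#'   ignored).
#' @return clearance in mL/min (numeric scalar).
#' @examples
#' p <- hepatic_processes(Inf, 1, 1000, CL_int_influx = 10, CL_int_efflux = 5)
#' ecm_clearance(p)   # 9.95
#' @export
ecm_clearance <- function(p) {
  stopifnot(inherits(p, "hepatic_processes"))
  p$CL_int_influx * p$f_uB * p$CL_H_int / (p$CL_H_int + p$CL_int_efflux)
}

#' Hepatic availability
#'
#' The model-independent fraction of an oral dose escaping first-pass
#' hepatic extraction, `F_H = 1 - CL_H / Q_H`.
#'
#' @param CL_H hepatic clearance (same units as `Q_H`), with
#'   `0 <= CL_H <= Q_H`.
#' @param Q_H hepatic blood flow.
#' @return availability in `[0, 1]`.
#' @examples
#' hepatic_availability(750, 1500)   # 0.5
#' @export
hepatic_availability <- function(CL_H, Q_H) {
  CL_H <- process_num(CL_H)
  stopifnot(Q_H > 0, CL_H >= 0)
  if (CL_H > Q_H) {
    stop("hepatic clearance cannot exceed hepatic blood flow", call. = FALSE)
  }
  1 - CL_H / Q_H
}

#' Hepatic efficiency number
#'
#' The dimensionless extraction driver `f_u * CL_int / Q_H`.
#'
#' @param f_u fraction unbound.
#' @param CL_int intrinsic clearance (same units as `Q_H`).
#' @param Q_H hepatic blood flow.
#' @return dimensionless numeric.
#' @examples
#' efficiency_number(0.5, 3000, 1500)   # 1
#' @export
efficiency_number <- function(f_u, CL_int, Q_H) {
  stopifnot(f_u > 0, f_u <= 1, CL_int >= 0, Q_H > 0)
  f_u * CL_int / Q_H
}

#' Kp_uu implied by the mechanistic liver models
#'
#' The steady-state unbound liver-to-blood partition coefficient that each
#' mechanistic model of hepatic elimination implies as a function of hepatic
#' availability, when the conventional steady-state clearance relation
#' (measured clearance times blood concentration equals intrinsic clearance
#' times average unbound liver concentration) is taken at face value:
#'
#' * well-stirred (`"WSM"`): the liver unbound concentration equals the
#'   exiting unbound concentration, so `Kp_uu = F_H`;
#' * parallel-tube (`"PTM"`): the liver concentration is the log-mean of
#'   inlet and outlet, so `Kp_uu = (1 - F_H) / (-log(F_H))`;
#' * extended clearance (`"ECM"`): from the flow-unlimited hepatocyte mass
#'   balance `influx * C_in_u = (efflux + CL_H_int) * C_H_u`, so
#'   `Kp_uu = CL_int_influx / (CL_int_efflux + CL_H_int)`.
#'
#' All three are bounded by 1 in their applicable regimes — the point of the
#' exercise, since measured Kp_uu values routinely exceed 1. The systemic
#' reference concentration is the unbound inlet concentration (steady-state
#' infusion context).
#'
#' @param model `"WSM"`, `"PTM"` or `"ECM"`.
#' @param F_H hepatic availability in (0, 1] (WSM/PTM; vectorized).
#' @param CL_int_influx,CL_int_efflux,CL_H_int ECM intrinsic clearances,
#'   mL/min (ECM only; influx > 0, efflux >= 0, CL_H_int > 0).
#' @return Kp_uu (numeric, vectorized over `F_H` for WSM/PTM).
#' @examples
#' kpuu_curve("WSM", F_H = 0.5)    # 0.5
#' kpuu_curve("PTM", F_H = 0.5)    # 0.7213
#' kpuu_curve("ECM", CL_int_influx = 50, CL_int_efflux = 20, CL_H_int = 100)
#' @export
kpuu_curve <- function(model = c("WSM", "PTM", "ECM"), F_H = NULL,
                       CL_int_influx = NULL, CL_int_efflux = NULL,
                       CL_H_int = NULL) {
  model <- match.arg(model)
  if (model %in% c("WSM", "PTM")) {
    if (is.null(F_H) || any(F_H <= 0) || any(F_H > 1)) {
      stop("F_H must lie in (0, 1]", call. = FALSE)
    }
    if (model == "WSM") return(F_H)
    # log-mean of inlet and outlet unbound concentrations over the inlet;
    # continuous limit 1 at F_H = 1
    out <- ifelse(F_H == 1, 1, (1 - F_H) / (-log(F_H)))
    return(as.numeric(out))
  }
  stopifnot(!is.null(CL_int_influx), !is.null(CL_H_int))
  if (is.null(CL_int_efflux)) CL_int_efflux <- 0
  stopifnot(CL_int_influx > 0, CL_int_efflux >= 0, CL_H_int > 0)
  CL_int_influx / (CL_int_efflux + CL_H_int)
}

#' Saturable parameter bundle and saturable hepatic clearance
#'
#' In vivo saturable (Michaelis-Menten) clearance with hepatic blood flow as
#' an in-series rate-defining process:
#' `1/CL = K_M/V_max + S/V_max + 1/Q_H`. With `Q_H = Inf` this is the
#' classical `V_max / (K_M + S)`; the blood-flow term caps the clearance of
#' high-capacity substrates (ethanol being the motivating case).
#'
#' @param V_max maximum elimination rate, mass/time (> 0).
#' @param K_M Michaelis constant, mass/volume (> 0).
#' @param S substrate concentration, mass/volume (>= 0).
#' @param Q_H hepatic blood flow, volume/time (> 0; `Inf` or
#'   [infinite_process()] allowed). Units of `V_max/K_M` and `Q_H` must
#'   agree; the result is in those units.
#' @return clearance (numeric scalar, vectorized over `S`).
#' @examples
#' saturable_clearance(V_max = 100, K_M = 10, S = 10, Q_H = 90)  # 4.737 L/h
#' saturable_clearance(V_max = 100, K_M = 10, S = 10, Q_H = Inf) # 5 L/h
#' @export
saturable_clearance <- function(V_max, K_M, S = 0, Q_H = Inf) {
  Q_H <- process_num(Q_H)
  stopifnot(V_max > 0, K_M > 0, all(S >= 0), Q_H > 0)
  inv <- K_M / V_max + S / V_max + (if (is.infinite(Q_H)) 0 else 1 / Q_H)
  1 / inv
}
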