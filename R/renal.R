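#' Renal process parameter bundle
#'
#' Parameters for the series/parallel renal clearance model: renal blood
#' flow is the entering clearance, and the parallel leaving clearances are
#' glomerular filtration (`f_uB * GFR`) and the net tubular transport
#' difference (secretion minus reabsorption).
#'
#' @param Q_R renal blood flow, mL/min (> 0; may be [infinite_process()] or
#'   `Inf` to ignore flow).
#' @param f_uB fraction unbound in blood, in (0, 1].
#' @param GFR glomerular filtration rate, mL/min (>= 0).
#' @param CL_secretion tubular secretion clearance, mL/min (>= 0).
#' @param CL_reabsorption tubular reabsorption clearance, mL/min (>= 0).
#' @return an object of class `renal_processes`.
#' @details The leaving total `f_uB*GFR + (CL_secretion - CL_reabsorption)`
#'   must be strictly positive: the combined leaving pathway is a
#'   rate-defining process. The signed net transport itself may be negative
#'   (net reabsorption) so long as the parallel total stays positive.
#' @examples
#' renal_processes(Q_R = 1100, f_uB = 1, GFR = 124, CL_secretion = 888)
#' @export
renal_processes <- function(Q_R, f_uB = 1, GFR = 0,
                            CL_secretion = 0, CL_reabsorption = 0) {
  qr <- process_num(Q_R)
  stopifnot(qr > 0, f_uB > 0, f_uB <= 1, GFR >= 0,
            CL_secretion >= 0, CL_reabsorption >= 0)
  cl_filt <- f_uB * GFR
  leaving <- cl_filt + (CL_secretion - CL_reabsorption)
  if (leaving <= 0) {
    stop("total leaving clearance (filtration + net transport) must be > 0; got ",
         leaving, " mL/min", call. = FALSE)
  }
  structure(
    list(Q_R = qr, f_uB = f_uB, GFR = GFR,
         CL_secretion = CL_secretion, CL_reabsorption = CL_reabsorption,
         CL_filtration = cl_filt),
    class = "renal_processes"
  )
}

#' @export
print.renal_processes <- function(x, ...) {
  cat(sprintf(
    "<renal_processes> Q_R = %g, CL_filtration = %g, net transport = %g mL/min\n",
    x$Q_R, x$CL_filtration, x$CL_secretion - x$CL_reabsorption))
  invisible(x)
}

#' Renal clearance from entering and leaving processes
#'
#' Measured renal clearance as the series combination of the entering
#' clearance (renal blood flow) with the parallel leaving clearances
#' (filtration plus net tubular transport):
#' `1/CL_R = 1/Q_R + 1/(CL_filtration + CL_secretion - CL_reabsorption)`.
#'
#' @param p a [renal_processes()] bundle.
#' @return measured renal clearance as a `pk_process` in mL/min.
#' @examples
#' # metformin, control arm: filtration 124 + net secretion 888 behind a
#' # 1100 mL/min renal blood flow gives the measured 527 mL/min
#' renal_clearance(renal_processes(1100, 1, 124, CL_secretion = 888))
#' @export
renal_clearance <- function(p) {
  stopifnot(inherits(p, "renal_processes"))
  leaving <- process_value(
    p$CL_filtration + (p$CL_secretion - p$CL_reabsorption),
    "clearance", label = "CL_filtration + net transport")
  entering <- if (is.infinite(p$Q_R)) {
    infinite_process("clearance", label = "Q_R")
  } else {
    process_value(p$Q_R, "clearance", label = "Q_R")
  }
  combine_series(list(entering, leaving), label = "CL_R")
}

#' Renal clearance ignoring renal blood flow
#'
#' The flow-free parallel form
#' `CL_R = CL_filtration + (CL_secretion - CL_reabsorption)`, valid when
#' renal blood flow greatly exceeds the leaving clearances.
#'
#' @param CL_filtration filtration clearance `f_uB * GFR`, mL/min.
#' @param CL_secretion,CL_reabsorption tubular transport clearances, mL/min.
#' @return clearance in mL/min (numeric scalar).
#' @examples
#' renal_clearance_no_flow(124, 403, 0)   # 527
#' @export
renal_clearance_no_flow <- function(CL_filtration, CL_secretion = 0,
                                    CL_reabsorption = 0) {
  stopifnot(CL_filtration >= 0, CL_secretion >= 0, CL_reabsorption >= 0)
  cl <- CL_filtration + (CL_secretion - CL_reabsorption)
  if (cl <= 0) {
    stop("renal clearance must be > 0; net reabsorption exceeds filtration",
         call. = FALSE)
  }
  cl
}

#' Solve for net tubular transport from measured renal clearance
#'
#' Inverts the series/parallel renal model for the net secretion-minus-
#' reabsorption clearance:
#' `CL_secretion - CL_reabsorption = 1/(1/CL_R - 1/Q_R) - CL_filtration`.
#' With `Q_R = Inf` this reduces to the flow-free difference
#' `CL_R - CL_filtration`. The result is a signed difference and may be
#' negative (net reabsorption); it is reported as a plain number, not a
#' `pk_process`.
#'
#' @param CL_R_measured measured renal clearance, mL/min (> 0).
#' @param Q_R renal blood flow, mL/min; may be `Inf`.
#' @param CL_filtration filtration clearance `f_uB * GFR`, mL/min.
#' @return net tubular transport clearance, mL/min (signed numeric).
#' @examples
#' net_tubular_transport(527, 1100, 124)  # 888 (metformin control)
#' net_tubular_transport(378, 1100, 124)  # 452 (with cimetidine)
#' net_tubular_transport(527, Inf, 124)   # 403 (flow ignored)
#' @export
net_tubular_transport <- function(CL_R_measured, Q_R, CL_filtration) {
  Q_R <- process_num(Q_R)
  stopifnot(CL_R_measured > 0, Q_R > 0, CL_filtration >= 0)
  if (CL_R_measured >= Q_R) {
    stop("measured clearance exceeds organ flow (", CL_R_measured, " >= ",
         Q_R, " mL/min): no finite leaving clearance can produce it",
         call. = FALSE)
  }
  if (is.infinite(Q_R)) {
    return(CL_R_measured - CL_filtration)
  }
  leaving <- 1 / (1 / CL_R_measured - 1 / Q_R)
  leaving - CL_filtration
}

#' Traditional differential-equation renal clearance
#'
#' The textbook mass-balance form
#' `CL_R = f_uB*GFR + f_uB*CL_int_sec - f_uTub*(P_int_reab + CL_int_reab)`,
#' which requires four clinically unmeasurable intracellular/tubular
#' parameters. Provided for side-by-side comparison with the composition
#' form; it is never combined with it.
#'
#' @param f_uB fraction unbound in blood, (0, 1].
#' @param GFR glomerular filtration rate, mL/min.
#' @param CL_int_sec intrinsic secretory transport clearance, mL/min.
#' @param f_uTub fraction unbound in tubule, (0, 1] (0 allowed to drop the
#'   reabsorption term).
#' @param P_int_reab intrinsic passive reabsorption permeability-clearance,
#'   mL/min.
#' @param CL_int_reab intrinsic transporter reabsorption clearance, mL/min.
#' @return clearance in mL/min (numeric scalar); errors if the balance is
#'   non-positive.
#' @examples
#' renal_clearance_traditional(f_uB = 0.5, GFR = 100, CL_int_sec = 200)
#' @export
renal_clearance_traditional <- function(f_uB, GFR, CL_int_sec = 0,
                                        f_uTub = 0, P_int_reab = 0,
                                        CL_int_reab = 0) {
  stopifnot(f_uB > 0, f_uB <= 1, GFR >= 0, CL_int_sec >= 0,
            f_uTub >= 0, f_uTub <= 1, P_int_reab >= 0, CL_int_reab >= 0)
  cl <- f_uB * GFR + f_uB * CL_int_sec - f_uTub * (P_int_reab + CL_int_reab)
  if (cl <= 0) {
    stop("traditional renal clearance is non-positive (reabsorption terms ",
         "exceed filtration + secretion)", call. = FALSE)
  }
  cl
}

#' Classify renal handling from clinically measurable quantities
#'
#' Compares measured renal clearance with the filtration clearance
#' `f_uB * GFR`. A ratio above 1 means tubular secretion exceeds
#' reabsorption; below 1, reabsorption exceeds secretion; near 1 (within
#' `tol`, relative) the drug is handled by filtration alone and dosing can
#' track GFR.
#'
#' @param CL_R_measured measured renal clearance, mL/min (> 0).
#' @param f_uB fraction unbound in blood, (0, 1].
#' @param GFR glomerular filtration rate, mL/min (> 0).
#' @param tol relative tolerance for calling the ratio equal to 1
#'   (default 0.05).
#' @return list with `ratio` (`CL_R / CL_filtration`) and `class`, one of
#'   `"filtration_only"`, `"net_secretion"`, `"net_reabsorption"`.
#' @examples
#' classify_renal_handling(3.9 * 124, 1, 124)   # acyclovir-like: secretion
#' classify_renal_handling(0.44 * 124, 1, 124)  # omarigliptin-like: reabsorption
#' @export
classify_renal_handling <- function(CL_R_measured, f_uB, GFR, tol = 0.05) {
  stopifnot(CL_R_measured > 0, f_uB > 0, f_uB <= 1, GFR > 0, tol >= 0)
  ratio <- CL_R_measured / (f_uB * GFR)
  cls <- if (abs(ratio - 1) <= tol) {
    "filtration_only"
  } else if (ratio > 1) {
    "net_secretion"
  } else {
    "net_reabsorption"
  }
  list(ratio = ratio, class = cls)
}
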