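#' Gut clearance from absorption parameters
#'
#' For first-order absorption, the entering clearance from the absorption
#' site is `CL_gut = k_a * V_gut`, where `V_gut` is the apparent volume of
#' distribution at the absorption site (amount in the gut divided by
#' concentration in the gut — a formal pharmacokinetic volume with no more
#' physiological meaning than Vss). `CL_gut` may also be supplied directly
#' to the downstream functions, bypassing this helper.
#'
#' @param k_a first-order absorption rate constant, 1/h (> 0).
#' @param V_gut apparent absorption-site volume, mL (> 0).
#' @return gut clearance, mL/h (numeric scalar).
#' @examples
#' gut_clearance(k_a = 0.5, V_gut = 2000)
#' @export
gut_clearance <- function(k_a, V_gut) {
  stopifnot(k_a > 0, V_gut > 0)
  k_a * V_gut
}

#' Total clearance following extravascular dosing
#'
#' The clearance measured after oral (or other extravascular) dosing is the
#' series combination of the entering clearance from the absorption site and
#' the iv-bolus (systemic) clearance:
#' `1/CL_total = 1/CL_gut + 1/CL_iv_bolus`. The traditional assumption
#' `CL_oral = CL_iv_bolus` is the `CL_gut = Inf` limit.
#'
#' @param CL_gut clearance from the absorption site (`Inf` or
#'   [infinite_process()] for instantaneous input).
#' @param CL_iv_bolus systemic clearance from an iv bolus (same units).
#' @param framework `"kirchhoff"` (series combination) or `"traditional"`
#'   (returns `CL_iv_bolus` unchanged). Every caller sees which prediction
#'   it asked for; the two are never mixed.
#' @return total clearance (numeric scalar, same units as inputs).
#' @examples
#' total_clearance_oral(CL_gut = 16, CL_iv_bolus = 10)
#' total_clearance_oral(CL_gut = 16, CL_iv_bolus = 10, framework = "traditional")
#' @export
total_clearance_oral <- function(CL_gut, CL_iv_bolus,
                                 framework = c("kirchhoff", "traditional")) {
  framework <- match.arg(framework)
  CL_gut <- process_num(CL_gut)
  CL_iv_bolus <- process_num(CL_iv_bolus)
  stopifnot(CL_gut > 0, CL_iv_bolus > 0, is.finite(CL_iv_bolus))
  if (framework == "traditional") return(CL_iv_bolus)
  if (is.infinite(CL_gut)) return(CL_iv_bolus)
  1 / (1 / CL_gut + 1 / CL_iv_bolus)
}

#' Mean residence time after oral dosing
#'
#' Mean times in series add: `MRT_oral = MRT_iv + MAT`. This is the
#' time-domain face of the harmonic combination of the corresponding
#' average rate constants (see [k_oral()]).
#'
#' @param MRT_iv mean residence time after an iv bolus, h (> 0).
#' @param MAT mean absorption time, h (>= 0).
#' @return mean residence time after oral dosing, h.
#' @examples
#' mrt_oral(1, 2)   # 3 h
#' @export
mrt_oral <- function(MRT_iv, MAT) {
  stopifnot(MRT_iv > 0, MAT >= 0)
  MRT_iv + MAT
}

#' Terminal rate constant after oral dosing
#'
#' Harmonic combination of the average iv-bolus elimination rate constant
#' and the average absorption rate constant:
#' `1/k_oral = 1/k_avg_iv + 1/k_a_avg`. This is the mathematical statement
#' of flip-flop kinetics — when absorption is slow the measured terminal
#' slope is dominated by `k_a`, not by elimination.
#'
#' @param k_avg_iv average elimination rate constant from iv bolus, 1/h.
#' @param k_a_avg average absorption rate constant, 1/h (`Inf` allowed).
#' @return rate constant, 1/h.
#' @examples
#' k_oral(k_avg_iv = 0.42, k_a_avg = 0.07)   # 0.06: absorption-dominated
#' @export
k_oral <- function(k_avg_iv, k_a_avg) {
  k_a_avg <- process_num(k_a_avg)
  stopifnot(k_avg_iv > 0, k_a_avg > 0)
  if (is.infinite(k_a_avg)) return(k_avg_iv)
  combine_series(list(k_avg_iv, k_a_avg), kind = "rate_constant",
                 label = "k_oral")$value
}

#' Flip-flop resolvability of oral exponential terms
#'
#' Exponential terms can only be separated in a fit when they differ
#' several-fold; with human-study variability the working range is 3- to
#' 4-fold. Reports whether the absorption and disposition exponents are
#' resolvable at a configurable fold-threshold, and whether the terminal
#' phase is flip-flopped (absorption slower than elimination).
#'
#' @param k_a absorption rate constant, 1/h.
#' @param k_d disposition (elimination) rate constant, 1/h.
#' @param threshold fold-separation below which the exponents are reported
#'   as not resolvable (default 3).
#' @return list with `ratio` (max/min fold separation), `resolvable`
#'   (logical), `flip_flop` (logical: `k_a < k_d`), and `terminal_slope`
#'   (the harmonic-combined observable slope from [k_oral()]).
#' @examples
#' flip_flop_check(k_a = 0.07, k_d = 0.42)
#' @export
flip_flop_check <- function(k_a, k_d, threshold = 3) {
  stopifnot(k_a > 0, k_d > 0, threshold >= 1)
  ratio <- max(k_a, k_d) / min(k_a, k_d)
  list(ratio = ratio,
       resolvable = ratio >= threshold,
       flip_flop = k_a < k_d,
       terminal_slope = k_oral(k_d, k_a))
}

#' Apparent systemic bioavailability under slow input
#'
#' If the measured oral clearance is the series combination of gut and
#' systemic clearance, then the dose-corrected AUC ratio used to estimate
#' bioavailability inflates to
#' `F_apparent = F_true * (1 + CL_iv_bolus / CL_gut)`, which exceeds
#' `F_true` whenever the gut clearance is finite and can exceed 1 — the
#' mechanism behind reported bioavailabilities above unity for linear
#' systems. Under the traditional framework (`CL_oral = CL_iv`) the ratio
#' is simply `F_true`.
#'
#' @param F_true true fraction of the dose reaching the circulation, (0, 1].
#' @param CL_iv_bolus systemic iv-bolus clearance (> 0).
#' @param CL_gut absorption-site clearance (> 0, `Inf` allowed).
#' @param framework `"kirchhoff"` or `"traditional"`.
#' @return apparent bioavailability (numeric; may exceed 1).
#' @examples
#' apparent_bioavailability(1, CL_iv_bolus = 10, CL_gut = 90)   # 1.111
#' @export
apparent_bioavailability <- function(F_true, CL_iv_bolus, CL_gut,
                                     framework = c("kirchhoff", "traditional")) {
  framework <- match.arg(framework)
  CL_gut <- process_num(CL_gut)
  stopifnot(F_true > 0, F_true <= 1, CL_iv_bolus > 0, CL_gut > 0)
  if (framework == "traditional") return(F_true)
  if (is.infinite(CL_gut)) return(F_true)
  F_true * (1 + CL_iv_bolus / CL_gut)
}

#' Route ratio of renal clearance (oral over iv)
#'
#' Renal clearance is amount excreted unchanged over the AUC driving
#' elimination. Slow input inflates the oral AUC without changing the
#' excreted fraction, so the measured oral renal clearance falls below the
#' iv value by `CL_total / CL_iv = 1 / (1 + CL_iv_bolus / CL_gut)`. This
#' depression and the AUC inflation of [apparent_bioavailability()] are
#' exact reciprocals: their product is always `F_true`.
#'
#' @inheritParams apparent_bioavailability
#' @return ratio in (0, 1].
#' @examples
#' renal_clearance_route_ratio(CL_iv_bolus = 10, CL_gut = 16)   # 0.615
#' @export
renal_clearance_route_ratio <- function(CL_iv_bolus, CL_gut,
                                        framework = c("kirchhoff", "traditional")) {
  framework <- match.arg(framework)
  CL_gut <- process_num(CL_gut)
  stopifnot(CL_iv_bolus > 0, CL_gut > 0)
  if (framework == "traditional") return(1)
  if (is.infinite(CL_gut)) return(1)
  1 / (1 + CL_iv_bolus / CL_gut)
}

#' Side-by-side oral-input predictions under both frameworks
#'
#' Computes total clearance, apparent bioavailability, renal-clearance route
#' ratio and the terminal slope from the same inputs under both the series
#' composition ("kirchhoff") and the traditional (`CL_oral = CL_iv`)
#' frameworks, each row tagged with its framework. The divergence of the two
#' columns is the quantity of interest; they are never averaged or mixed.
#'
#' @param CL_iv_bolus systemic iv-bolus clearance, mL/min (> 0).
#' @param CL_gut absorption-site clearance, mL/min (> 0); alternatively give
#'   `k_a` and `V_gut`.
#' @param F_true true bioavailable fraction, (0, 1].
#' @param k_a,V_gut optional absorption rate constant (1/h) and gut volume
#'   (mL) from which `CL_gut` is formed when not supplied directly.
#' @param k_avg_iv optional average iv elimination rate constant (1/h) for
#'   the terminal-slope row.
#' @return data.frame with columns `quantity`, `unit`, `traditional`,
#'   `kirchhoff`.
#' @examples
#' oral_comparison(CL_iv_bolus = 600, CL_gut = 960, F_true = 0.8)
#' @export
oral_comparison <- function(CL_iv_bolus, CL_gut = NULL, F_true = 1,
                            k_a = NULL, V_gut = NULL, k_avg_iv = NULL) {
  if (is.null(CL_gut)) {
    if (is.null(k_a) || is.null(V_gut)) {
      stop("supply CL_gut, or both k_a and V_gut", call. = FALSE)
    }
    CL_gut <- gut_clearance(k_a, V_gut) / 60   # mL/h -> mL/min
  }
  rows <- list(
    c("CL_total", "mL/min",
      total_clearance_oral(CL_gut, CL_iv_bolus, "traditional"),
      total_clearance_oral(CL_gut, CL_iv_bolus, "kirchhoff")),
    c("F_apparent", "",
      apparent_bioavailability(F_true, CL_iv_bolus, CL_gut, "traditional"),
      apparent_bioavailability(F_true, CL_iv_bolus, CL_gut, "kirchhoff")),
    c("CL_R_oral/CL_R_iv", "",
      renal_clearance_route_ratio(CL_iv_bolus, CL_gut, "traditional"),
      renal_clearance_route_ratio(CL_iv_bolus, CL_gut, "kirchhoff"))
  )
  if (!is.null(k_a) && !is.null(k_avg_iv)) {
    rows <- c(rows, list(c("terminal_slope", "1/h",
                           k_avg_iv, k_oral(k_avg_iv, k_a))))
  }
  out <- data.frame(
    quantity = vapply(rows, `[[`, "", 1L),
    unit = vapply(rows, `[[`, "", 2L),
    traditional = as.numeric(vapply(rows, `[[`, "", 3L)),
    kirchhoff = as.numeric(vapply(rows, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  out
}
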