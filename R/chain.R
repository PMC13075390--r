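#' Catenary metabolite chain specification
#'
#' The in-series first-order chain D -> M1 -> M2 -> M3 of a drug incubated
#' in a fixed volume (a microsomal mixture): the drug and each metabolite
#' are eliminated by a single first-order step, and M3 is terminal (no
#' further elimination).
#'
#' @param k_D,k_M1,k_M2 first-order loss rate constants of D, M1, M2, 1/h
#'   (> 0).
#' @param dose amount of drug placed in the incubation, micromol (> 0).
#' @param V incubation volume, mL (> 0).
#' @return an object of class `chain_spec`.
#' @examples
#' chain_spec(k_D = 0.07, k_M1 = 0.12, k_M2 = 0.42, dose = 90, V = 20)
#' @export
chain_spec <- function(k_D, k_M1, k_M2, dose, V) {
  stopifnot(k_D > 0, k_M1 > 0, k_M2 > 0, dose > 0, V > 0)
  structure(list(k_D = k_D, k_M1 = k_M1, k_M2 = k_M2, dose = dose, V = V),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("<chain_spec> D ->(%g) M1 ->(%g) M2 ->(%g) M3; dose %g umol in %g mL\n",
              x$k_D, x$k_M1, x$k_M2, x$dose, x$V))
  invisible(x)
}

chain_rates <- function(spec) c(D = spec$k_D, M1 = spec$k_M1, M2 = spec$k_M2)

#' Closed-form concentration of a chain species
#'
#' The Bateman-type closed-form concentration-time expression for any
#' species of the catenary chain, as an [exp_sum()]. For distinct rate
#' constants the M2 expression has the classic three-exponential form with
#' coefficients `k_D*k_M1*dose / (prod_j(rate_j - rate_i) * V)`; repeated
#' rate constants produce the confluent polynomial-times-exponential form
#' and are only accepted behind `degenerate_ok = TRUE` (the distinct-rate
#' coefficients divide by rate differences and are undefined at equality;
#' equality is judged at relative tolerance `tol`).
#'
#' The terminal species M3 accumulates; its expression contains a rate-0
#' plateau term, so it can be evaluated but has no finite moments.
#'
#' @param spec a [chain_spec()].
#' @param species `"D"`, `"M1"`, `"M2"` or `"M3"`.
#' @param degenerate_ok allow (near-)repeated rate constants and return the
#'   confluent form.
#' @param tol relative tolerance for treating two rates as repeated
#'   (default 1e-9).
#' @return an [exp_sum()] for the species concentration, micromol/mL.
#' @examples
#' sp <- chain_spec(0.07, 0.12, 0.42, 90, 20)
#' chain_solution(sp, "M2")   # 2.16 e^-0.07t - 2.52 e^-0.12t + 0.36 e^-0.42t
#' @export
chain_solution <- function(spec, species = c("D", "M1", "M2", "M3"),
                           degenerate_ok = FALSE, tol = 1e-9) {
  stopifnot(inherits(spec, "chain_spec"))
  species <- match.arg(species)
  k <- chain_rates(spec)
  sep <- outer(k, k, function(a, b) abs(a - b) / pmax(a, b))
  if (!degenerate_ok && any(sep[upper.tri(sep)] <= tol)) {
    stop("chain has (near-)repeated rate constants; the distinct-rate closed ",
         "form is undefined there. Set degenerate_ok = TRUE for the confluent form.",
         call. = FALSE)
  }
  # amounts by repeated convolution; divide by V at the end
  a_d <- exp_sum(spec$dose, spec$k_D)
  if (species == "D") return(exp_sum(a_d$coef / spec$V, a_d$rate, a_d$power))
  a_m1 <- convolve_exp_sum(a_d, spec$k_D, spec$k_M1, tol)
  if (species == "M1") return(exp_sum(a_m1$coef / spec$V, a_m1$rate, a_m1$power))
  a_m2 <- convolve_exp_sum(a_m1, spec$k_M1, spec$k_M2, tol)
  if (species == "M2") return(exp_sum(a_m2$coef / spec$V, a_m2$rate, a_m2$power))
  # M3 by conservation: dose - D - M1 - M2 (terminal species)
  exp_sum(c(spec$dose, -a_d$coef, -a_m1$coef, -a_m2$coef) / spec$V,
          c(0, a_d$rate, a_m1$rate, a_m2$rate),
          c(0L, a_d$power, a_m1$power, a_m2$power))
}

#' Mean residence time of a downstream species by series composition
#'
#' For a catenary chain, the mean residence time of a species measured
#' after dosing the head of the chain is the reciprocal of the harmonic
#' combination of the in-series rate constants — equivalently, the sum of
#' the reciprocals `sum(1/k_i)`. This one-line shortcut reproduces exactly
#' the MRT obtained from the full closed-form solution and its statistical
#' moments.
#'
#' @param rates vector of in-series first-order rate constants, 1/h (> 0).
#' @return mean residence time, h.
#' @examples
#' mrt_kirchhoff(c(0.07, 0.12, 0.42))   # 25.0 h
#' mrt_kirchhoff(0.42)                  # 2.38 h: M2 dosed directly
#' @export
mrt_kirchhoff <- function(rates) {
  stopifnot(is.numeric(rates), length(rates) >= 1L, all(rates > 0))
  k_total <- combine_series(as.list(rates), kind = "rate_constant",
                            label = "measured elimination")$value
  1 / k_total
}
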