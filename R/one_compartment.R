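#' One-compartment disposition specification
#'
#' A first-order one-compartment body model with first-order absorption:
#' elimination rate constant `k_d = k_m + k_r` (parallel metabolic and
#' renal pathways), absorption rate constant `k_a`, bioavailable fraction
#' `F`, dose and body volume. Either give `k_d` directly or give `k_m` and
#' `k_r`.
#'
#' @param k_a first-order absorption rate constant, 1/h (> 0).
#' @param k_d first-order elimination rate constant, 1/h (> 0); defaults to
#'   `k_m + k_r`.
#' @param k_m,k_r parallel metabolic and renal elimination rate constants,
#'   1/h (>= 0).
#' @param F_bio systemic bioavailable fraction, (0, 1].
#' @param dose administered dose, mass units (> 0).
#' @param V_body body volume of distribution, mL (> 0).
#' @return an object of class `one_compartment_spec`.
#' @examples
#' one_compartment_spec(k_a = 1, k_m = 0.15, k_r = 0.05, F_bio = 0.8,
#'                      dose = 100, V_body = 10000)
#' @export
one_compartment_spec <- function(k_a, k_d = NULL, k_m = NULL, k_r = NULL,
                                 F_bio = 1, dose, V_body) {
  if (is.null(k_d)) {
    if (is.null(k_m) && is.null(k_r)) {
      stop("give k_d, or k_m and/or k_r", call. = FALSE)
    }
    k_m <- if (is.null(k_m)) 0 else k_m
    k_r <- if (is.null(k_r)) 0 else k_r
    stopifnot(k_m >= 0, k_r >= 0)
    # parallel elimination pathways add
    k_d <- k_m + k_r
  } else {
    if (is.null(k_m)) k_m <- k_d
    if (is.null(k_r)) k_r <- 0
  }
  stopifnot(k_a > 0, k_d > 0, F_bio > 0, F_bio <= 1, dose > 0, V_body > 0)
  structure(list(k_a = k_a, k_d = k_d, k_m = k_m, k_r = k_r,
                 F_bio = F_bio, dose = dose, V_body = V_body),
            class = "one_compartment_spec")
}

#' @export
print.one_compartment_spec <- function(x, ...) {
  cat(sprintf("<one_compartment_spec> k_a = %g, k_d = %g 1/h, F = %g, dose %g, V %g mL\n",
              x$k_a, x$k_d, x$F_bio, x$dose, x$V_body))
  invisible(x)
}

#' Closed-form one-compartment concentration curve
#'
#' The concentration-time expression as an [exp_sum()]:
#' iv bolus `C = dose/V * exp(-k_d t)`; oral
#' `C = k_a F dose / ((k_a - k_d) V) * (exp(-k_d t) - exp(-k_a t))` — two
#' terms of opposite sign summing to zero at t = 0. For `k_a` equal to
#' `k_d` (within `tol` relative) the oral curve takes the confluent
#' `F dose k t exp(-k t) / V` form, behind `degenerate_ok = TRUE`.
#'
#' @param spec a [one_compartment_spec()].
#' @param route `"iv_bolus"` or `"oral"`.
#' @param degenerate_ok allow `k_a == k_d` and return the confluent form.
#' @param tol relative tolerance for treating `k_a` and `k_d` as equal.
#' @return an [exp_sum()], concentration units of `dose/V_body`.
#' @examples
#' sp <- one_compartment_spec(k_a = 1, k_d = 0.2, F_bio = 0.9,
#'                            dose = 100, V_body = 5000)
#' one_compartment_profile(sp, "oral")
#' @export
one_compartment_profile <- function(spec, route = c("iv_bolus", "oral"),
                                    degenerate_ok = FALSE, tol = 1e-9) {
  stopifnot(inherits(spec, "one_compartment_spec"))
  route <- match.arg(route)
  if (route == "iv_bolus") {
    return(exp_sum(spec$dose / spec$V_body, spec$k_d))
  }
  close_rates <- abs(spec$k_a - spec$k_d) <= tol * max(spec$k_a, spec$k_d)
  if (close_rates && !degenerate_ok) {
    stop("k_a and k_d are (nearly) equal; the two-exponential form is ",
         "undefined. Set degenerate_ok = TRUE for the confluent form.",
         call. = FALSE)
  }
  if (close_rates) {
    k <- (spec$k_a + spec$k_d) / 2
    return(exp_sum(spec$F_bio * spec$dose * k / spec$V_body, k, power = 1L))
  }
  a <- spec$k_a * spec$F_bio * spec$dose / ((spec$k_a - spec$k_d) * spec$V_body)
  exp_sum(c(a, -a), c(spec$k_d, spec$k_a))
}
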