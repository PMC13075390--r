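#' Sum-of-exponentials curves
#'
#' An `exp_sum` represents an amount- or concentration-time course as
#' `sum(coef * t^power * exp(-rate * t))`. The `power` column is 0 for the
#' ordinary distinct-rate case and positive for the confluent (repeated
#' rate) case, where the closed form acquires polynomial-in-t factors.
#'
#' @param coef term coefficients (concentration or amount units).
#' @param rate decay rates, 1/h (>= 0; a zero rate encodes a plateau term,
#'   which is valid for evaluation but not for moments).
#' @param power non-negative integer powers of t (default all 0).
#' @return an object of class `exp_sum` (a data.frame of terms).
#' @examples
#' m2 <- exp_sum(c(2.16, -2.52, 0.36), c(0.07, 0.12, 0.42))
#' eval_exp_sum(m2, c(0, 1, 10))
#' @export
exp_sum <- function(coef, rate, power = 0) {
  stopifnot(is.numeric(coef), is.numeric(rate), length(coef) == length(rate))
  power <- rep_len(as.integer(power), length(coef))
  if (any(rate < 0)) stop("negative decay rates are not allowed", call. = FALSE)
  if (any(power < 0)) stop("powers must be non-negative integers", call. = FALSE)
  out <- data.frame(coef = as.numeric(coef), rate = as.numeric(rate),
                    power = power)
  # merge duplicate (rate, power) terms, drop exact zeros
  key <- paste(signif(out$rate, 15), out$power)
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(coef ~ rate + power, data = out, FUN = sum)
    out <- agg[, c("coef", "rate", "power")]
  }
  out <- out[out$coef != 0 | nrow(out) == 1L, , drop = FALSE]
  out <- out[order(out$rate, out$power), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("exp_sum", "data.frame")
  out
}

#' @export
print.exp_sum <- function(x, digits = 4, ...) {
  terms <- vapply(seq_len(nrow(x)), function(i) {
    co <- signif(x$coef[i], digits)
    tpart <- if (x$power[i] > 0) sprintf("t^%d*", x$power[i]) else ""
    sprintf("%s%se^(-%s t)", format(co), tpart, format(signif(x$rate[i], digits)))
  }, "")
  cat("<exp_sum> ", paste(terms, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' @rdname exp_sum
#' @param e an `exp_sum`.
#' @param t numeric vector of times, h.
#' @export
eval_exp_sum <- function(e, t) {
  stopifnot(inherits(e, "exp_sum"), is.numeric(t))
  vapply(t, function(ti) {
    sum(e$coef * ti^e$power * exp(-e$rate * ti))
  }, numeric(1L))
}

#' Statistical moments of a sum-of-exponentials curve
#'
#' The zeroth and first moments of the curve over all time, and their
#' ratio: `AUC = sum(coef * p! / rate^(p+1))`,
#' `AUMC = sum(coef * (p+1)! / rate^(p+2))`, `MRT = AUMC / AUC`. For the
#' ordinary `power = 0` case these are the familiar
#' coefficient-over-exponent and coefficient-over-exponent-squared sums.
#'
#' @param e an [exp_sum()] with all rates strictly positive (a zero rate
#'   means a divergent integral and is an error).
#' @return list with `AUC`, `AUMC`, `MRT` (units follow the coefficients:
#'   concentration*h, concentration*h^2, h).
#' @examples
#' m2 <- exp_sum(c(2.16, -2.52, 0.36), c(0.07, 0.12, 0.42))
#' moments(m2)   # AUC 10.71, AUMC 267.9, MRT 25.0 h
#' @export
moments <- function(e) {
  stopifnot(inherits(e, "exp_sum"))
  if (any(e$rate <= 0)) {
    stop("moments require strictly positive decay rates (divergent integral)",
         call. = FALSE)
  }
  auc <- sum(e$coef * factorial(e$power) / e$rate^(e$power + 1))
  aumc <- sum(e$coef * factorial(e$power + 1) / e$rate^(e$power + 2))
  if (auc <= 0) stop("AUC of the curve is non-positive", call. = FALSE)
  list(AUC = auc, AUMC = aumc, MRT = aumc / auc)
}

# convolve one (coef, power, rate) term with exp(-k t) under a first-order
# transfer: returns the term rows of integral_0^t s^p e^{-rate s} e^{-k(t-s)} ds
# times coef. Confluent branch when |rate - k| is below rel tol.
convolve_exp_term <- function(coef, power, rate, k, tol = 1e-9) {
  mu <- rate - k
  scale <- max(abs(rate), abs(k), 1e-300)
  if (abs(mu) <= tol * scale) {
    # integral s^p e^{-k t} ds = t^(p+1)/(p+1) e^{-k t}
    return(data.frame(coef = coef / (power + 1), rate = k, power = power + 1L))
  }
  # integral_0^t s^p e^{-mu s} ds = p!/mu^(p+1) - e^{-mu t} sum_j p!/j! t^j/mu^(p+1-j)
  j <- 0:power
  data.frame(
    coef = c(coef * factorial(power) / mu^(power + 1),
             -coef * factorial(power) / (factorial(j) * mu^(power + 1 - j))),
    rate = c(k, rep(rate, length(j))),
    power = c(0L, as.integer(j))
  )
}

# closed-form solution of a linear catenary chain by repeated convolution:
# amounts[[n+1]](t) = k_n * int_0^t e^{-k_out(t-s)} amounts[[n]](s) ds
convolve_exp_sum <- function(e, k_in, k_out, tol = 1e-9) {
  rows <- do.call(rbind, lapply(seq_len(nrow(e)), function(i) {
    convolve_exp_term(k_in * e$coef[i], e$power[i], e$rate[i], k_out, tol)
  }))
  exp_sum(rows$coef, rows$rate, rows$power)
}
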