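#' Rate-defining process values
#'
#' A `pk_process` is one rate-defining process: either a clearance
#' (volume/time) or a first-order rate constant (1/time), together with its
#' unit and a free-text label. Rate-defining processes are the only objects
#' the composition calculus combines: a process that could, alone, equal the
#' measured total under limiting conditions (organ blood flow for a
#' high-extraction drug, the parent elimination rate constant for a
#' downstream metabolite, ...).
#'
#' Values must be strictly positive. A measured net difference (influx minus
#' efflux, secretion minus reabsorption) that comes out non-positive is not a
#' rate-defining process and is rejected here; compute the signed difference
#' first and only construct the process from a positive net value.
#'
#' @param value strictly positive numeric scalar.
#' @param kind `"clearance"` or `"rate_constant"`.
#' @param unit unit string. Clearances use `"mL/min"` or `"L/h"`; rate
#'   constants use `"1/h"` or `"1/min"`. Defaults to the canonical unit for
#'   the kind (`"mL/min"`, `"1/h"`).
#' @param label free-text label recorded for reporting.
#' @return an object of class `pk_process`.
#' @seealso [combine_parallel()], [combine_series()], [infinite_process()]
#' @examples
#' process_value(124, "clearance", label = "CL_filtration")
#' process_value(0.07, "rate_constant", label = "k_D")
#' @export
process_value <- function(value,
                          kind = c("clearance", "rate_constant"),
                          unit = NULL,
                          label = "") {
  kind <- match.arg(kind)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("'value' must be a single finite number (use infinite_process() for an infinite process)",
         call. = FALSE)
  }
  if (value <= 0) {
    stop("a rate-defining process must be strictly positive; got ", value,
         " (a non-positive net difference such as efflux > influx is not rate-defining)",
         call. = FALSE)
  }
  if (is.null(unit)) unit <- canonical_unit(kind)
  check_unit(kind, unit)
  structure(
    list(value = as.numeric(value), kind = kind, unit = unit,
         label = as.character(label)),
    class = "pk_process"
  )
}

#' Infinite process sentinel
#'
#' An explicit sentinel for an infinitely fast process: the identity element
#' of series combination (its reciprocal contributes exactly 0) and an
#' absorbing element of parallel combination. The canonical use is the
#' entering clearance of an intravenous bolus dose, where all drug enters the
#' circulation instantaneously.
#'
#' The sentinel is a distinct type, not a large float, so that identities
#' like `combine_series(list(infinite_process(), x)) == x` hold exactly.
#'
#' @param kind `"clearance"` or `"rate_constant"`.
#' @param unit unit string, defaulting to the canonical unit for the kind.
#' @param label free-text label.
#' @return an object of class `pk_process_inf`.
#' @examples
#' iv_entry <- infinite_process(label = "CL_entering (iv bolus)")
#' @export
infinite_process <- function(kind = c("clearance", "rate_constant"),
                             unit = NULL, label = "infinite") {
  kind <- match.arg(kind)
  if (is.null(unit)) unit <- canonical_unit(kind)
  check_unit(kind, unit)
  structure(
    list(kind = kind, unit = unit, label = as.character(label)),
    class = "pk_process_inf"
  )
}

#' @rdname infinite_process
#' @param x object to test.
#' @export
is_infinite_process <- function(x) inherits(x, "pk_process_inf")

canonical_unit <- function(kind) {
  switch(kind, clearance = "mL/min", rate_constant = "1/h")
}

.clearance_units <- c("mL/min", "L/h")
.rate_units <- c("1/h", "1/min")

check_unit <- function(kind, unit) {
  ok <- switch(kind,
               clearance = unit %in% .clearance_units,
               rate_constant = unit %in% .rate_units)
  if (!ok) {
    stop("unit '", unit, "' is not valid for kind '", kind, "' (expected one of: ",
         paste(switch(kind, clearance = .clearance_units,
                      rate_constant = .rate_units), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(unit)
}

#' @export
print.pk_process <- function(x, ...) {
  cat(sprintf("<pk_process> %s = %g %s (%s)\n",
              if (nzchar(x$label)) x$label else "unnamed",
              x$value, x$unit, x$kind))
  invisible(x)
}

#' @export
print.pk_process_inf <- function(x, ...) {
  cat(sprintf("<pk_process> %s = Inf %s (%s)\n",
              if (nzchar(x$label)) x$label else "unnamed", x$unit, x$kind))
  invisible(x)
}

# coerce bare numerics in a list of operands; shared validation for the
# combinators: >= 1 operand, uniform kind and unit after conversion helpers
normalize_operands <- function(processes, default_kind, default_unit) {
  if (!is.list(processes) || length(processes) == 0L) {
    stop("need at least one process to combine", call. = FALSE)
  }
  processes <- lapply(processes, function(p) {
    if (inherits(p, "pk_process") || is_infinite_process(p)) return(p)
    if (is.numeric(p) && length(p) == 1L) {
      if (is.infinite(p)) return(infinite_process(default_kind, default_unit))
      return(process_value(p, default_kind, default_unit))
    }
    stop("operands must be pk_process objects or numeric scalars", call. = FALSE)
  })
  kinds <- vapply(processes, `[[`, "", "kind")
  units <- vapply(processes, `[[`, "", "unit")
  if (length(unique(kinds)) != 1L) {
    stop("cannot combine processes of mixed kind: ",
         paste(unique(kinds), collapse = ", "), call. = FALSE)
  }
  if (length(unique(units)) != 1L) {
    stop("cannot combine processes with mixed units: ",
         paste(unique(units), collapse = ", "),
         " (convert first, e.g. with convert_clearance())", call. = FALSE)
  }
  processes
}

#' Combine rate-defining processes in parallel
#'
#' Parallel processes add: the total measured coefficient of proportionality
#' is the sum of the rate-defining processes. In the liver, metabolic and
#' biliary intrinsic clearances combine this way; in the kidney, filtration
#' and net tubular transport do.
#'
#' @param processes a list of [process_value()] objects (bare positive
#'   numerics are coerced using `kind`/`unit`). All operands must share kind
#'   and unit. An [infinite_process()] operand makes the parallel total
#'   infinite.
#' @param kind,unit kind and unit applied to bare numeric operands and used
#'   for the result label.
#' @param label label for the combined process; by default built from the
#'   operand labels.
#' @return a `pk_process` (or `pk_process_inf` if any operand is infinite).
#' @examples
#' combine_parallel(list(
#'   process_value(3, label = "CL_int,metabolism"),
#'   process_value(2, label = "CL_int,biliary")
#' ))
#' @export
combine_parallel <- function(processes,
                             kind = c("clearance", "rate_constant"),
                             unit = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (is.null(unit)) unit <- canonical_unit(kind)
  processes <- normalize_operands(processes, kind, unit)
  kind <- processes[[1L]]$kind
  unit <- processes[[1L]]$unit
  if (is.null(label)) label <- operand_label(processes, " + ")
  if (any(vapply(processes, is_infinite_process, logical(1L)))) {
    return(infinite_process(kind, unit, label))
  }
  total <- sum(vapply(processes, `[[`, numeric(1L), "value"))
  process_value(total, kind, unit, label)
}

#' Combine rate-defining processes in series
#'
#' In-series processes combine harmonically: the reciprocal of the total
#' equals the sum of the reciprocals of the rate-defining processes. This is
#' the entering/leaving clearance form of every organ clearance equation and
#' the mean-residence-time additivity of a catenary chain (MRTs are
#' reciprocals of average rate constants, and reciprocals of a harmonic
#' combination add).
#'
#' [infinite_process()] operands contribute exactly zero to the reciprocal
#' sum and are dropped, so an iv bolus (infinite entering clearance) leaves
#' the leaving clearance unchanged, exactly.
#'
#' @inheritParams combine_parallel
#' @return a `pk_process` (or `pk_process_inf` if all operands are infinite).
#' @examples
#' # a 0.07, 0.12, 0.42 1/h chain is measured with a 0.04 1/h terminal
#' # rate constant, i.e. a 25 h mean residence time
#' combine_series(list(0.07, 0.12, 0.42), kind = "rate_constant")
#' @export
combine_series <- function(processes,
                           kind = c("clearance", "rate_constant"),
                           unit = NULL, label = NULL) {
  kind <- match.arg(kind)
  if (is.null(unit)) unit <- canonical_unit(kind)
  processes <- normalize_operands(processes, kind, unit)
  kind <- processes[[1L]]$kind
  unit <- processes[[1L]]$unit
  if (is.null(label)) label <- operand_label(processes, " -> ")
  finite <- processes[!vapply(processes, is_infinite_process, logical(1L))]
  if (length(finite) == 0L) {
    return(infinite_process(kind, unit, label))
  }
  if (length(finite) == 1L) {
    # exact identity: series with only infinite partners returns the operand
    p <- finite[[1L]]
    return(process_value(p$value, kind, unit, label))
  }
  inv <- sum(1 / vapply(finite, `[[`, numeric(1L), "value"))
  process_value(1 / inv, kind, unit, label)
}

operand_label <- function(processes, sep) {
  labs <- vapply(processes, function(p) {
    if (nzchar(p$label)) p$label else format(if (is_infinite_process(p)) Inf else p$value)
  }, "")
  paste(labs, collapse = sep)
}

#' Unit conversion for clearances and rate constants
#'
#' The calculus enforces a single unit across any one combination; these
#' helpers convert between the two clearance units in common use
#' (1 L/h = 1000/60 mL/min) and the two rate-constant units.
#'
#' @param x a `pk_process` of the appropriate kind, or a bare numeric.
#' @param to target unit.
#' @return same type as `x`, converted.
#' @examples
#' convert_clearance(90, to = "mL/min")      # 90 L/h -> 1500 mL/min
#' convert_clearance(1500, from = "mL/min", to = "L/h")
#' @export
convert_clearance <- function(x, to = c("mL/min", "L/h"), from = NULL) {
  # from: source unit; taken from the object for pk_process input
  to <- match.arg(to)
  if (inherits(x, "pk_process")) {
    stopifnot(x$kind == "clearance")
    v <- convert_clearance(x$value, to = to, from = x$unit)
    return(process_value(v, "clearance", to, x$label))
  }
  if (is_infinite_process(x)) return(infinite_process(x$kind, to, x$label))
  if (is.null(from)) from <- setdiff(.clearance_units, to)
  from <- match.arg(from, .clearance_units)
  if (from == to) return(x)
  if (from == "L/h") x * 1000 / 60 else x * 60 / 1000
}

#' @rdname convert_clearance
#' @param from source unit (taken from the object for `pk_process` input;
#'   for numerics defaults to the other unit).
#' @export
convert_rate_constant <- function(x, to = c("1/h", "1/min"), from = NULL) {
  to <- match.arg(to)
  if (inherits(x, "pk_process")) {
    stopifnot(x$kind == "rate_constant")
    v <- convert_rate_constant(x$value, to = to, from = x$unit)
    return(process_value(v, "rate_constant", to, x$label))
  }
  if (is.null(from)) from <- setdiff(.rate_units, to)
  from <- match.arg(from, .rate_units)
  if (from == to) return(x)
  if (from == "1/h") x / 60 else x * 60
}

# numeric value of a process, Inf for the sentinel (internal)
process_num <- function(p) {
  if (is_infinite_process(p)) Inf else if (inherits(p, "pk_process")) p$value else as.numeric(p)
}
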