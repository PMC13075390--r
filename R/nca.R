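#' Noncompartmental analysis of a sampled profile
#'
#' Moment-based estimation of exposure and clearance from a sampled
#' concentration-time profile: AUC and AUMC over the observed range by the
#' trapezoid rule (linear up/down by default; log-down optional), terminal
#' rate constant `lambda_z` by least squares on the log concentrations of
#' the terminal window, extrapolation to infinity by `C_last/lambda_z`
#' (and the matching AUMC tail), `MRT = AUMC/AUC`, `CL = dose/AUC`, and —
#' when the amount excreted unchanged is supplied — `CL_R = Ae/AUC`.
#'
#' The terminal window defaults to all points later than three times the
#' peak of the moment curve `t*C(t)`, or the last three positive
#' concentrations, whichever set is larger.
#'
#' @param profile a [pk_profile()] with at least 3 points.
#' @param dose administered dose; defaults to the profile's recorded dose.
#' @param amount_excreted optional amount excreted unchanged in urine, for
#'   `CL_R`.
#' @param terminal_points optional integer: use exactly the last this-many
#'   positive points for the `lambda_z` fit (overrides the default window).
#' @param method `"linear"` (linear up/down trapezoid) or `"linear-log"`
#'   (log trapezoid on descending segments).
#' @return list with `AUC_last`, `AUC_inf`, `AUMC_inf`, `MRT`, `lambda_z`,
#'   `CL`, `CL_R` (NA unless `amount_excreted` given), and
#'   `terminal_window` (indices used for the fit).
#' @examples
#' sp <- one_compartment_spec(k_a = 1, k_d = 0.1, dose = 100, V_body = 5000)
#' prof <- simulate_ode(sp, seq(0, 72, 0.5), route = "iv_bolus")
#' nca(prof)$CL   # ~ k_d * V_body = 500
#' @export
nca <- function(profile, dose = NULL, amount_excreted = NULL,
                terminal_points = NULL, method = c("linear", "linear-log")) {
  stopifnot(inherits(profile, "pk_profile"))
  method <- match.arg(method)
  t <- profile$times
  c0 <- profile$concentrations
  if (length(t) < 3L) stop("need at least 3 points for NCA", call. = FALSE)
  if (all(c0 == 0)) stop("profile is all zeros; nothing to analyze", call. = FALSE)
  if (is.null(dose)) dose <- profile$dose

  # trapezoid AUC/AUMC over the observed range
  dt <- diff(t)
  cl_ <- c0[-length(c0)]; cr <- c0[-1L]
  if (method == "linear") {
    auc_seg <- dt * (cl_ + cr) / 2
  } else {
    # log trapezoid on strictly descending positive segments, linear otherwise
    desc <- cr < cl_ & cr > 0 & cl_ > 0
    auc_seg <- ifelse(desc, dt * (cl_ - cr) / log(cl_ / cr), dt * (cl_ + cr) / 2)
  }
  tc <- t * c0
  aumc_seg <- dt * (tc[-length(tc)] + tc[-1L]) / 2
  auc_last <- sum(auc_seg)
  aumc_last <- sum(aumc_seg)

  # terminal window
  pos <- which(c0 > 0)
  if (!is.null(terminal_points)) {
    stopifnot(terminal_points >= 2L)
    idx <- utils::tail(pos, terminal_points)
  } else {
    tstar <- t[which.max(tc)]
    idx <- pos[t[pos] > 3 * tstar]
    last3 <- utils::tail(pos, 3L)
    if (length(idx) < length(last3)) idx <- last3
  }
  if (length(idx) < 2L) {
    stop("fewer points than the terminal-fit window", call. = FALSE)
  }
  fit <- stats::lm(log(c0[idx]) ~ t[idx])
  lambda_z <- -unname(stats::coef(fit)[2L])
  if (!is.finite(lambda_z) || lambda_z <= 0) {
    stop("terminal phase is not log-linearly declining (lambda_z <= 0)",
         call. = FALSE)
  }

  c_last <- c0[max(pos)]
  t_last <- t[max(pos)]
  auc_inf <- auc_last + c_last / lambda_z
  aumc_inf <- aumc_last + c_last * t_last / lambda_z + c_last / lambda_z^2
  cl <- if (is.finite(dose)) dose / auc_inf else NA_real_
  clr <- if (!is.null(amount_excreted)) amount_excreted / auc_inf else NA_real_
  list(AUC_last = auc_last, AUC_inf = auc_inf, AUMC_inf = aumc_inf,
       MRT = aumc_inf / auc_inf, lambda_z = lambda_z,
       CL = cl, CL_R = clr, terminal_window = idx)
}

#' Read and write the profile CSV format
#'
#' Profiles are exchanged as a two-column CSV `time,concentration`, with
#' optional leading comment lines beginning `#` (e.g.
#' `# units: h, umol/mL`).
#'
#' @param path file path.
#' @param dose,route metadata attached to the returned profile.
#' @return [read_profile_csv()] returns a [pk_profile()];
#'   [write_profile_csv()] returns `path` invisibly.
#' @export
read_profile_csv <- function(path, dose = NA_real_, route = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("input file is empty: ", path, call. = FALSE)
  }
  units <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  need <- c("time", "concentration")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns 'time' and 'concentration': ", path,
         call. = FALSE)
  }
  time_unit <- "h"; conc_unit <- "umol/mL"
  if (length(units)) {
    m <- regmatches(units[1L],
                    regexec("units:\\s*([^,]+),\\s*(.+)$", units[1L]))[[1L]]
    if (length(m) == 3L) { time_unit <- trimws(m[2L]); conc_unit <- trimws(m[3L]) }
  }
  pk_profile(df$time, df$concentration, dose = dose, route = route,
             conc_unit = conc_unit, time_unit = time_unit)
}

#' @rdname read_profile_csv
#' @param profile a [pk_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "pk_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s, %s", profile$time_unit, profile$conc_unit),
             con)
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE)
  invisible(path)
}
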