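# Oral-dose time courses: one-compartment plasma input, quasi-
# equilibrium arterial driving functions, and the seven stiff ODEs for
# the capillary and brain compartments, plus trapezoid AUC summaries.

#' Total plasma drug concentration after a single oral dose
#'
#' One-compartment model with first-order absorption and first-order
#' elimination (Bateman input):
#' LT0(t) = (b*s*k / (V*(k-d))) * (exp(-d*t) - exp(-k*t)).
#'
#' @param pk an [oral_pk] object.
#' @param t time after dosing (min); vectorized.
#' @return Plasma concentration(s) (nM).
#' @export
#' @examples
#' pk <- builtin_oral_pk("propranolol")
#' oral_plasma_concentration(pk, c(0, 60, 120, 420))
oral_plasma_concentration <- function(pk, t) {
  stopifnot(inherits(pk, "oral_pk"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  (pk$b * pk$s * pk$k / (pk$V * (pk$k - pk$d))) *
    (exp(-pk$d * t) - exp(-pk$k * t))
}

# Right-hand side of the capillary/brain ODE system. `input` maps time
# to total plasma drug concentration (nM).
.brain_rhs <- function(t, y, p, input) {
  art <- solve_arterial_equilibrium(p, input(t))
  GL <- y[["GL"]]; AL <- y[["AL"]]; LF <- y[["LF"]]; GF <- y[["GF"]]
  LM <- y[["LM"]]; PF <- y[["PF"]]; PL <- y[["PL"]]
  bind_G <- p$k2 * LF * GF
  bind_A <- p$k8 * p$AF * LF
  bind_P <- p$k5 * LM * PF
  list(c(
    GL = p$k10 * art$GL0 + bind_G - p$k1 * GL - p$k10 * GL,
    AL = p$k10 * art$AL0 + bind_A - p$k7 * AL - p$k10 * AL,
    LF = p$k10 * art$LF0 + p$k1 * GL + p$k7 * AL +
      p$k4 * LM * (p$VT / p$VP) - bind_G - bind_A -
      p$k3 * LF - p$k10 * LF,
    GF = p$k10 * art$GF0 + p$k1 * GL - bind_G - p$k10 * GF,
    LM = p$k3 * LF * (p$VP / p$VT) - (p$k4 + p$k9) * LM -
      bind_P + p$k6 * PL,
    PF = p$k6 * PL - bind_P,
    PL = bind_P - p$k6 * PL),
    c(GL0 = art$GL0, AL0 = art$AL0, LF0 = art$LF0, GF0 = art$GF0,
      LT0 = art$LT0))
}

#' Simulate the brain delivery time course after an oral dose
#'
#' Integrates the seven capillary/brain differential equations with the
#' arterial variables supplied as algebraic quasi-equilibrium driving
#' functions of the oral plasma input. Initial conditions: all drug
#' species zero, free globulin at GT0, free tissue protein at PT. The
#' rate constants span roughly six orders of magnitude, so a stiff
#' integrator (backward differentiation via [deSolve::ode()] with
#' `method = "lsoda"`) is used with tight tolerances.
#'
#' @param params a [drug_params] object. The oral simulations of the
#'   reference study use metastatic-cancer plasma protein levels
#'   (AF = 600,000 nM, GT0 = 70,000 nM); set those on `params` with
#'   [with_overrides()] if wanted — no override is applied here.
#' @param pk an [oral_pk] object.
#' @param horizon simulation end time (min).
#' @param grid_step output grid spacing (min).
#' @param constant_input if not `NULL`, replaces the oral input with a
#'   constant total plasma concentration (nM) — used for steady-state
#'   cross-validation.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @param method integration method passed to [deSolve::ode()].
#' @return An object of class `time_course`: list with `data` (a
#'   data.frame with columns `t`, arterial `LT0`, `GL0`, `AL0`, `LF0`,
#'   `GF0` and capillary/brain `GL`, `AL`, `LF`, `GF`, `LM`, `PL`,
#'   `PF`), plus `params` and `pk`.
#' @export
#' @examples
#' p <- with_overrides(builtin_parameters("propranolol"),
#'                     list(AF = 600000, GT0 = 70000))
#' tc <- simulate_oral(p, builtin_oral_pk("propranolol"),
#'                     horizon = 240, grid_step = 2)
#' tail(tc$data[, c("t", "LT0", "LF0", "LF", "LM")], 3)
simulate_oral <- function(params, pk = NULL, horizon = 1440, grid_step = 1,
                          constant_input = NULL,
                          rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(inherits(params, "drug_params"))
  if (!is.numeric(horizon) || horizon <= 0) stop("horizon must be > 0",
                                                 call. = FALSE)
  if (!is.numeric(grid_step) || grid_step <= 0)
    stop("grid_step must be > 0", call. = FALSE)
  if (is.null(constant_input)) {
    stopifnot(inherits(pk, "oral_pk"))
    input <- function(t) oral_plasma_concentration(pk, t)
  } else {
    if (!is.numeric(constant_input) || constant_input < 0)
      stop("constant_input must be >= 0", call. = FALSE)
    input <- function(t) constant_input
  }
  times <- seq(0, horizon, by = grid_step)
  if (times[length(times)] < horizon) times <- c(times, horizon)
  y0 <- c(GL = 0, AL = 0, LF = 0, GF = params$GT0, LM = 0,
          PF = params$PT, PL = 0)
  out <- deSolve::ode(y = y0, times = times, func = .brain_rhs,
                      parms = params, input = input,
                      method = method, rtol = rtol, atol = atol)
  diagn <- attributes(out)
  if (!is.null(diagn$istate) && diagn$istate[1] < 0)
    stop("stiff integration failed (istate = ", diagn$istate[1],
         "); consider a smaller grid_step or looser tolerances",
         call. = FALSE)
  d <- as.data.frame(out)
  names(d)[1] <- "t"
  d <- d[, c("t", "LT0", "GL0", "AL0", "LF0", "GF0",
             "GL", "AL", "LF", "GF", "LM", "PL", "PF")]
  structure(list(data = d, params = params, pk = pk,
                 constant_input = constant_input),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  d <- x$data
  cat("<time_course> ", x$params$label, ": ", nrow(d), " points over [0, ",
      max(d$t), "] min\n", sep = "")
  print(utils::head(d, 3))
  cat("...\n")
  invisible(x)
}

#' Trapezoid area under the curve
#'
#' Composite trapezoid rule on the stored grid, truncated at horizon
#' `T_end` (with linear interpolation if `T_end` falls between grid
#' points).
#'
#' @param t time grid (min), strictly increasing from 0.
#' @param y concentrations on the grid (nM).
#' @param T_end upper integration limit (min); defaults to the last grid
#'   point.
#' @return AUC in nM*min (equivalently nmol*min/L).
#' @export
auc_trapezoid <- function(t, y, T_end = max(t)) {
  if (length(t) != length(y) || length(t) < 2L)
    stop("t and y must be equal-length vectors with >= 2 points",
         call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("t must be strictly increasing", call. = FALSE)
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  if (T_end > max(t) || T_end < min(t))
    stop("T_end = ", T_end, " lies outside the stored grid [",
         min(t), ", ", max(t), "]", call. = FALSE)
  keep <- t <= T_end
  tt <- t[keep]; yy <- y[keep]
  if (tt[length(tt)] < T_end) {
    yT <- stats::approx(t, y, xout = T_end)$y
    tt <- c(tt, T_end); yy <- c(yy, yT)
  }
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' AUC summary of a simulated time course
#'
#' Trapezoid AUCs over `[0, T_end]` for the arterial pools (LT0, LF0,
#' GL0, AL0), the capillary pools (LF, GL, AL), and the brain pools
#' (LM, PL, LM+PL), plus the two headline ratios: the excess of
#' bioavailable over in-vitro free exposure (AUC_LF / AUC_LF0) and the
#' total-brain to total-plasma exposure ratio (AUC_(LM+PL) / AUC_LT0).
#'
#' @param tc a `time_course` from [simulate_oral()].
#' @param T_end integration horizon (min).
#' @return An object of class `auc_summary`: list with `auc` (named
#'   numeric vector, nM*min), `T_end`, `ratio_LF_LF0`, and
#'   `ratio_brain_LT0`.
#' @export
summarize_auc <- function(tc, T_end = max(tc$data$t)) {
  stopifnot(inherits(tc, "time_course"))
  d <- tc$data
  vars <- c("LT0", "LF0", "GL0", "AL0", "LF", "GL", "AL", "LM", "PL")
  auc <- vapply(vars, function(v) auc_trapezoid(d$t, d[[v]], T_end),
                numeric(1))
  auc <- c(auc, `LM+PL` = auc_trapezoid(d$t, d$LM + d$PL, T_end))
  structure(list(
    auc = auc, T_end = T_end,
    ratio_LF_LF0 = if (auc[["LF0"]] > 0) auc[["LF"]] / auc[["LF0"]]
                   else NA_real_,
    ratio_brain_LT0 = if (auc[["LT0"]] > 0) auc[["LM+PL"]] / auc[["LT0"]]
                      else NA_real_),
    class = "auc_summary")
}

#' @export
print.auc_summary <- function(x, ...) {
  cat("<auc_summary> over [0, ", x$T_end, "] min (nM*min)\n", sep = "")
  print(signif(x$auc, 4))
  cat(sprintf("AUC_LF/AUC_LF0 = %.3g; AUC_(LM+PL)/AUC_LT0 = %.3g\n",
              x$ratio_LF_LF0, x$ratio_brain_LT0))
  invisible(x)
}

#' Interpolated total-brain partition coefficient along a time course
#'
#' Kp_brain(t) = (LM(t) + PL(t)) / LT0(t), linearly interpolated at the
#' requested times.
#'
#' @param tc a `time_course`.
#' @param at times (min) at which to evaluate.
#' @return Numeric vector of Kp_brain values.
#' @export
kp_brain_at <- function(tc, at) {
  stopifnot(inherits(tc, "time_course"))
  d <- tc$data
  num <- stats::approx(d$t, d$LM + d$PL, xout = at)$y
  den <- stats::approx(d$t, d$LT0, xout = at)$y
  num / den
}

#' Export a time course to CSV
#'
#' @param tc a `time_course`.
#' @param path output file.
#' @param long if `TRUE`, write long format (`t`, `variable`, `value`)
#'   instead of one column per variable.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(tc, path, long = FALSE) {
  stopifnot(inherits(tc, "time_course"))
  d <- tc$data
  if (long) {
    vars <- setdiff(names(d), "t")
    d <- data.frame(t = rep(d$t, length(vars)),
                    variable = rep(vars, each = nrow(d)),
                    value = unlist(d[vars], use.names = FALSE))
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
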