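# Closed-form steady-state solution for the capillary and brain
# compartments, plus an independent stationary-point oracle that root-
# finds the non-steady-state right-hand sides directly.

#' Closed-form steady state of the brain delivery model
#'
#' Solves all eleven model variables at a constant total plasma drug
#' concentration (IV-infusion conditions). The arterial variables come
#' from [solve_arterial_equilibrium()]; the free drug in brain LM is the
#' nonnegative root of a quadratic in aggregate coefficients,
#'
#' a1 = k10*GF0 - k10*LF0 - k7*k10*AL0/(k7+k10)
#' a2 = k9 + (k10*(k4+k9)/k3) * (1 + k8*AF/(k7+k10))
#' b1 = k2*(k4+k9) / (k3*(k1+k10))
#' b2 = k10*GF0 + k1*k10*GL0/(k1+k10)
#'
#' LM = (VP/VT) * (sqrt((a2+a1*b1)^2 + 4*a2*b1*(b2-a1)) - (a2+a1*b1))
#'      / (2*a2*b1)
#'
#' followed by GF = (a1 + a2*LM*VT/VP)/k10,
#' LF = ((k4+k9)/k3)*(VT/VP)*LM, AL = (k10*AL0 + k8*AF*LF)/(k7+k10),
#' GL = (k10*GL0 + k2*LF*GF)/(k1+k10), PF = PT/(1 + (k5/k6)*LM),
#' PL = PT - PF, and Kp_brain = (PL+LM)/LT0.
#'
#' When brain metabolism is nil (k9 = 0) the unbound brain-to-plasma
#' ratio LM/LF reduces to the permeability-surface area ratio
#' (k3*VP)/(k4*VT); with k9 > 0 it is the realized LM/LF.
#'
#' @param params a [drug_params] object.
#' @param total_drug total plasma drug concentration (nM); defaults to
#'   `params$LT0`.
#' @return An object of class `steady_state`: list with the arterial
#'   sub-state (`arterial`), capillary and brain concentrations `GL`,
#'   `AL`, `LF`, `GF`, `LM`, `PL`, `PF` (nM), the ratios `Kp_brain`
#'   (total brain over total plasma), `kpuu` (LM/LF), `fu_in_vitro`
#'   (LF0/LT0), `fu_in_vivo` (LF/LT0), and the quadratic
#'   `intermediates` (`B`, `a1`, `a2`, `b1`, `b2`).
#' @seealso [stationary_oracle()], [kp_uu()], [run_scenario()]
#' @export
#' @examples
#' sol <- solve_steady_state(builtin_parameters("propranolol"))
#' round(c(LF = sol$LF, LM = sol$LM, Kp = sol$Kp_brain), 1)
solve_steady_state <- function(params, total_drug = params$LT0) {
  stopifnot(inherits(params, "drug_params"))
  art <- solve_arterial_equilibrium(params, total_drug)
  p <- params
  GL0 <- art$GL0; AL0 <- art$AL0; LF0 <- art$LF0; GF0 <- art$GF0
  LT0 <- art$LT0

  a1 <- p$k10 * GF0 - p$k10 * LF0 - p$k7 * p$k10 * AL0 / (p$k7 + p$k10)
  a2 <- p$k9 + (p$k10 * (p$k4 + p$k9) / p$k3) *
    (1 + p$k8 * p$AF / (p$k7 + p$k10))
  b1 <- p$k2 * (p$k4 + p$k9) / (p$k3 * (p$k1 + p$k10))
  b2 <- p$k10 * GF0 + p$k1 * p$k10 * GL0 / (p$k1 + p$k10)
  B <- 1 + (if (p$AF > 0) p$AF / p$KA_in_vitro else 0) +
    (if (p$GT0 > 0) (p$GT0 + LT0) / p$KG_in_vitro else 0)
  inter <- list(B = B, a1 = a1, a2 = a2, b1 = b1, b2 = b2)

  if (a2 <= 0)
    stop("degenerate steady state: a2 <= 0 (k4 + k9 and k9 both zero?); ",
         "intermediates: ", .fmt_inter(inter), call. = FALSE)
  if (b1 > 0) {
    disc <- (a2 + a1 * b1)^2 + 4 * a2 * b1 * (b2 - a1)
    if (disc < 0)
      stop("negative discriminant in the free-brain-drug quadratic; ",
           "intermediates: ", .fmt_inter(inter), call. = FALSE)
    u <- (sqrt(disc) - (a2 + a1 * b1)) / (2 * a2 * b1)
  } else {
    # no globulin association in the capillary: the quadratic collapses
    u <- (b2 - a1) / a2
  }
  if (u < 0) {
    if (u > -1e-12 * max(1, LT0)) u <- 0 else
      stop("steady-state solution has negative free brain drug; ",
           "intermediates: ", .fmt_inter(inter), call. = FALSE)
  }
  LM <- (p$VP / p$VT) * u
  GF <- (a1 + a2 * u) / p$k10
  LF <- ((p$k4 + p$k9) / p$k3) * u
  AL <- (p$k10 * AL0 + p$k8 * p$AF * LF) / (p$k7 + p$k10)
  GL <- (p$k10 * GL0 + p$k2 * LF * GF) / (p$k1 + p$k10)
  if (p$k5 > 0 && p$k6 <= 0) {
    PF <- if (LM > 0) 0 else p$PT
  } else if (p$k5 <= 0) {
    PF <- p$PT
  } else {
    PF <- p$PT / (1 + (p$k5 / p$k6) * LM)
  }
  PL <- p$PT - PF
  structure(list(
    arterial = art,
    GL = GL, AL = AL, LF = LF, GF = GF, LM = LM, PL = PL, PF = PF,
    Kp_brain = if (LT0 > 0) (PL + LM) / LT0 else NA_real_,
    kpuu = if (LF > 0) LM / LF else NA_real_,
    fu_in_vitro = if (LT0 > 0) LF0 / LT0 else NA_real_,
    fu_in_vivo = if (LT0 > 0) LF / LT0 else NA_real_,
    intermediates = inter, params = params),
    class = "steady_state")
}

.fmt_inter <- function(inter)
  paste(sprintf("%s=%.6g", names(inter), unlist(inter)), collapse = ", ")

#' @export
print.steady_state <- function(x, digits = 4, ...) {
  cat("<steady_state> ", x$params$label, " (LT0 = ", x$arterial$LT0,
      " nM)\n", sep = "")
  print(signif(unlist(x[c("GL", "AL", "LF", "GF", "LM", "PL", "PF")]),
               digits))
  cat(sprintf("Kp_brain = %.*g, kpuu = %.*g, fu_in_vitro = %.*g, fu_in_vivo = %.*g\n",
              digits, x$Kp_brain, digits, x$kpuu,
              digits, x$fu_in_vitro, digits, x$fu_in_vivo))
  invisible(x)
}

#' @export
#' @rdname solve_steady_state
#' @param x a `steady_state` object.
#' @param row.names,optional,... passed on conventions of
#'   [base::as.data.frame()]; unused.
as.data.frame.steady_state <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(label = x$params$label,
             GL0 = x$arterial$GL0, AL0 = x$arterial$AL0,
             LF0 = x$arterial$LF0,
             GL = x$GL, AL = x$AL, LF = x$LF, LM = x$LM,
             PL = x$PL, PF = x$PF, Kp_brain = x$Kp_brain,
             stringsAsFactors = FALSE)
}

#' Unbound brain-to-plasma partition coefficient
#'
#' Kp,uu,brain, the ratio of free drug in brain to free (bioavailable)
#' drug in the capillary plasma. Without brain metabolism (k9 = 0) it
#' equals the ratio of the influx to efflux permeability-surface area
#' products, (k3*VP)/(k4*VT), independent of tissue binding; with
#' metabolism it is computed as LM/LF from the full steady-state solve.
#'
#' @param params a [drug_params] object.
#' @return Dimensionless scalar.
#' @export
#' @examples
#' kp_uu(builtin_parameters("propranolol"))
kp_uu <- function(params) {
  stopifnot(inherits(params, "drug_params"))
  if (params$k4 <= 0) stop("kp_uu requires k4 > 0", call. = FALSE)
  if (params$k9 == 0)
    (params$k3 * params$VP) / (params$k4 * params$VT)
  else
    solve_steady_state(params)$kpuu
}

#' Stationary-point oracle for the steady state
#'
#' Independent cross-check of [solve_steady_state()]: solves the
#' capillary/brain balance equations directly by damped Newton root
#' search on the non-steady-state right-hand sides (see
#' [simulate_oral()]) with the total plasma drug concentration held
#' constant, started from the arterial state. No part of the closed-form
#' algebra is reused.
#'
#' @param params a [drug_params] object.
#' @param total_drug total plasma drug concentration (nM).
#' @param tol convergence tolerance on the scaled residual norm.
#' @param max_iter maximum Newton iterations.
#' @return A `steady_state` object (without closed-form intermediates).
#' @export
stationary_oracle <- function(params, total_drug = params$LT0,
                              tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(params, "drug_params"))
  p <- params
  art <- solve_arterial_equilibrium(p, total_drug)

  rhs <- function(x) {
    GL <- x[1]; AL <- x[2]; LF <- x[3]; GF <- x[4]; LM <- x[5]; PF <- x[6]
    PL <- p$PT - PF
    c(p$k10 * art$GL0 + p$k2 * LF * GF - (p$k1 + p$k10) * GL,
      p$k10 * art$AL0 + p$k8 * p$AF * LF - (p$k7 + p$k10) * AL,
      p$k10 * art$LF0 + p$k1 * GL + p$k7 * AL + p$k4 * LM * (p$VT / p$VP) -
        p$k2 * LF * GF - p$k8 * p$AF * LF - (p$k3 + p$k10) * LF,
      p$k10 * art$GF0 + p$k1 * GL - p$k2 * LF * GF - p$k10 * GF,
      p$k3 * LF * (p$VP / p$VT) - (p$k4 + p$k9) * LM -
        p$k5 * LM * PF + p$k6 * PL,
      p$k6 * PL - p$k5 * LM * PF)
  }

  x <- c(art$GL0, art$AL0, art$LF0, art$GF0, art$LF0,
         if (p$k5 > 0 && p$k6 > 0)
           p$PT / (1 + (p$k5 / p$k6) * max(art$LF0, 0)) else p$PT)
  scale <- pmax(abs(x), c(rep(max(art$LT0, 1), 5), max(p$PT, 1)))
  res_scale <- p$k10 * pmax(scale[1:4], scale[3])
  res_scale <- c(res_scale, max(p$k3, p$k4 + p$k9 + 1) * scale[5],
                 max(p$k6, p$k5 * scale[5], 1) * scale[6])

  jac <- function(x) {
    n <- length(x)
    J <- matrix(0, n, n)
    f0 <- rhs(x)
    h <- pmax(abs(x), scale) * 1e-8
    for (j in seq_len(n)) {
      xp <- x; xp[j] <- xp[j] + h[j]
      J[, j] <- (rhs(xp) - f0) / h[j]
    }
    J
  }

  f <- rhs(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(f / res_scale)) < tol) break
    step <- tryCatch(solve(jac(x), -f), error = function(e)
      stop("stationary oracle: singular Jacobian at iteration ", it,
           call. = FALSE))
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- rhs(xn)
      if (sum((fn / res_scale)^2) < sum((f / res_scale)^2) || lambda < 1e-6)
        break
      lambda <- lambda / 2
    }
    x <- xn; f <- fn
  }
  if (max(abs(f / res_scale)) >= tol)
    stop("stationary oracle did not converge; scaled residual norm = ",
         signif(max(abs(f / res_scale)), 3), call. = FALSE)

  GL <- x[1]; AL <- x[2]; LF <- x[3]; GF <- x[4]; LM <- x[5]; PF <- x[6]
  PL <- p$PT - PF
  structure(list(
    arterial = art,
    GL = GL, AL = AL, LF = LF, GF = GF, LM = LM, PL = PL, PF = PF,
    Kp_brain = if (art$LT0 > 0) (PL + LM) / art$LT0 else NA_real_,
    kpuu = if (LF > 0) LM / LF else NA_real_,
    fu_in_vitro = if (art$LT0 > 0) art$LF0 / art$LT0 else NA_real_,
    fu_in_vivo = if (art$LT0 > 0) LF / art$LT0 else NA_real_,
    intermediates = NULL, params = params),
    class = "steady_state")
}
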