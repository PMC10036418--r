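# Systemic (arterial) drug / albumin / AGP binding equilibrium.
#
# The arterial compartment is assumed to be in binding equilibrium at
# the in-vitro dissociation constants: albumin is so concentrated
# relative to drug that free albumin equals total albumin (AF), which
# linearises the albumin term, while globulin occupancy requires the
# quadratic in the globulin-bound drug concentration GL0.

#' Solve the arterial plasma binding equilibrium
#'
#' Partitions a total plasma drug concentration among the globulin-bound
#' (GL0), albumin-bound (AL0), and free (LF0) pools at the in-vitro
#' dissociation constants, together with the free globulin pool (GF0).
#' LF0 is the free drug concentration that equilibrium dialysis of
#' plasma would measure in vitro.
#'
#' With B = 1 + AF/KA + (GT0 + LT0)/KG, the globulin-bound drug is the
#' smaller root of the mass-action quadratic,
#' GL0 = (KG/2) * (B - sqrt(B^2 - 4*GT0*LT0/KG^2)),
#' then GF0 = GT0 - GL0, LF0 = LT0 / (1 + AF/KA + GF0/KG) and
#' AL0 = (AF*LT0/KA) / (1 + AF/KA + GF0/KG).
#'
#' @param params a [drug_params] object (supplies AF, GT0 and the
#'   in-vitro dissociation constants).
#' @param total_drug total plasma drug concentration LT0 (nM); defaults
#'   to `params$LT0`.
#' @return An object of class `arterial_state`: list with fields `GL0`,
#'   `AL0`, `LF0`, `GF0`, `LT0` (all nM).
#' @export
#' @examples
#' solve_arterial_equilibrium(builtin_parameters("propranolol"))
solve_arterial_equilibrium <- function(params, total_drug = params$LT0) {
  stopifnot(inherits(params, "drug_params"))
  LT0 <- total_drug
  if (!is.numeric(LT0) || length(LT0) != 1L || !is.finite(LT0) || LT0 < 0)
    stop("total_drug must be a single finite number >= 0", call. = FALSE)
  AF <- params$AF; GT0 <- params$GT0
  KA <- params$KA_in_vitro; KG <- params$KG_in_vitro

  alb <- if (AF > 0) AF / KA else 0
  if (GT0 <= 0 || LT0 <= 0) {
    GL0 <- 0
  } else {
    B <- 1 + alb + (GT0 + LT0) / KG
    disc <- B^2 - 4 * GT0 * LT0 / KG^2
    # the discriminant is (1 + alb + (GT0 - LT0)/KG)^2 + 4*LT0/KG*(1 + alb)
    # rewritten, hence nonnegative for valid inputs
    stopifnot(disc >= 0)
    GL0 <- 0.5 * KG * (B - sqrt(disc))
  }
  GF0 <- GT0 - GL0
  den <- 1 + alb + (if (GT0 > 0) GF0 / KG else 0)
  LF0 <- LT0 / den
  AL0 <- alb * LT0 / den
  structure(list(GL0 = GL0, AL0 = AL0, LF0 = LF0, GF0 = GF0, LT0 = LT0),
            class = "arterial_state")
}

#' @export
print.arterial_state <- function(x, ...) {
  cat("<arterial_state> LT0 =", x$LT0, "nM\n")
  print(unlist(x[c("GL0", "AL0", "LF0", "GF0")]))
  invisible(x)
}

#' Arterial state at a given time after an oral dose
#'
#' Evaluates the arterial binding equilibrium at the total plasma drug
#' concentration produced by the one-compartment oral input function at
#' time `t`. The systemic compartment is treated as in quasi-equilibrium
#' (its rates of change are slow relative to the capillary), so the
#' free fraction LF0/LT0 is time-invariant for fixed protein levels.
#'
#' @param params a [drug_params] object.
#' @param pk an [oral_pk] object.
#' @param t time after the oral dose (min), scalar, >= 0.
#' @return An `arterial_state` (see [solve_arterial_equilibrium()]).
#' @export
arterial_time_course <- function(params, pk, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("t must be a single finite number >= 0", call. = FALSE)
  solve_arterial_equilibrium(params, oral_plasma_concentration(pk, t))
}
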