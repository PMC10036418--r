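# Random valid parameter draws for property tests. Ranges bracket the
# two reference drugs: plasma proteins 10^4.5-10^6 nM (albumin) and
# 10^3-10^5 nM (AGP), dissociation constants spanning the in-vitro
# values, capillary kinetics allowing up to ~30-fold enhanced
# dissociation, and flow/permeability around the physiological values.

random_drug_params <- function(with_metabolism = FALSE) {
  KG <- 10^stats::runif(1, 2.5, 4)
  KA <- 10^stats::runif(1, 4, 5.7)
  k2 <- 10^stats::runif(1, -2.5, -0.5)
  k8 <- 10^stats::runif(1, -3, -1.5)
  k10 <- 10^stats::runif(1, 0.5, 2)
  k3 <- k10 * stats::runif(1, 0.5, 3)
  VP <- 0.01; VT <- 0.7
  drug_params(
    LT0 = stats::runif(1, 10, 200),
    AF = 10^stats::runif(1, 4.5, 6),
    GT0 = 10^stats::runif(1, 3, 5),
    KA_in_vitro = KA, KG_in_vitro = KG,
    PT = 10^stats::runif(1, 2, 4), VP = VP, VT = VT,
    k1 = k2 * KG * 10^stats::runif(1, 0, 1.5),
    k2 = k2, k3 = k3,
    k4 = k3 * VP / VT * 10^stats::runif(1, -0.5, 1),
    k5 = 10^stats::runif(1, -3.5, -1.5),
    k6 = 10^stats::runif(1, -1, 0.5),
    k7 = k8 * KA * 10^stats::runif(1, 0, 1.5),
    k8 = k8,
    k9 = if (with_metabolism) stats::runif(1, 0, 6) else 0,
    k10 = k10, label = "draw")
}

# residual of the mass-action arterial system at a candidate state
arterial_residual <- function(p, st) {
  c(balance = st$GL0 + st$AL0 + st$LF0 - st$LT0,
    globulin = st$GL0 + st$GF0 - p$GT0,
    # GL0 mass action: GL0 = GF0*LF0/KG
    mass_action = if (p$GT0 > 0) st$GL0 - st$GF0 * st$LF0 / p$KG_in_vitro
                  else 0,
    albumin = if (p$AF > 0) st$AL0 - p$AF * st$LF0 / p$KA_in_vitro else 0)
}

# independent brute-force arterial solver: 1-D root search on the free
# drug concentration satisfying total mass balance
arterial_bruteforce <- function(p, LT0) {
  if (LT0 == 0)
    return(list(GL0 = 0, AL0 = 0, LF0 = 0, GF0 = p$GT0, LT0 = 0))
  f <- function(LF0) {
    GF0 <- if (p$GT0 > 0) p$GT0 / (1 + LF0 / p$KG_in_vitro) else 0
    bound_A <- if (p$AF > 0) p$AF * LF0 / p$KA_in_vitro else 0
    bound_G <- if (p$GT0 > 0) GF0 * LF0 / p$KG_in_vitro else 0
    LF0 + bound_A + bound_G - LT0
  }
  LF0 <- stats::uniroot(f, c(0, LT0), tol = 1e-14 * LT0)$root
  GF0 <- if (p$GT0 > 0) p$GT0 / (1 + LF0 / p$KG_in_vitro) else 0
  list(GL0 = if (p$GT0 > 0) GF0 * LF0 / p$KG_in_vitro else 0,
       AL0 = if (p$AF > 0) p$AF * LF0 / p$KA_in_vitro else 0,
       LF0 = LF0, GF0 = GF0, LT0 = LT0)
}
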