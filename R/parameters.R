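# Parameter containers, validation, built-in drug sets, and config file I/O.
#
# Unit conventions, fixed globally: concentrations nM, time min, volumes
# L/kg, dose nmol/kg, association rate constants nM^-1 min^-1
# (1 nM^-1 min^-1 = 10^9/60 M^-1 s^-1).

.DRUG_FIELDS <- c("LT0", "AF", "GT0", "KA_in_vitro", "KG_in_vitro", "PT",
                  "VP", "VT", paste0("k", 1:10))
.ORAL_FIELDS <- c("b", "s", "k", "d", "V")

#' Drug parameter set for the brain delivery model
#'
#' Bundles the 18 steady-state parameters of the partly flow, partly
#' compartmental model of brain drug delivery: systemic drug and binding
#' protein concentrations, in-vitro dissociation constants for albumin and
#' alpha-1-acid glycoprotein (AGP, "globulin"), brain tissue binding
#' protein, compartment volumes, and the ten kinetic rate constants.
#'
#' @param LT0 total plasma drug concentration (nM).
#' @param AF total albumin concentration, systemic and capillary (nM).
#'   Free albumin is approximated by total albumin throughout, since
#'   albumin is log orders more concentrated than drug.
#' @param GT0 total globulin (AGP) concentration (nM).
#' @param KA_in_vitro dissociation constant of drug binding to albumin
#'   measured in vitro (nM).
#' @param KG_in_vitro dissociation constant of drug binding to AGP
#'   measured in vitro (nM).
#' @param PT total brain tissue binding protein concentration (nM).
#' @param VP brain capillary plasma volume (L/kg).
#' @param VT brain extravascular volume (L/kg).
#' @param k1 rate constant of drug dissociation from AGP in the brain
#'   capillary (min^-1); k1/k2 is the in-vivo AGP dissociation constant.
#' @param k2 rate constant of drug association with AGP in the brain
#'   capillary (nM^-1 min^-1).
#' @param k3 rate constant of drug influx across the blood-brain barrier
#'   (BBB), plasma to brain (min^-1); equals (PS/F)*k10.
#' @param k4 rate constant of drug efflux across the BBB, brain to plasma
#'   (min^-1).
#' @param k5 rate constant of drug association with brain tissue binding
#'   protein (nM^-1 min^-1).
#' @param k6 rate constant of drug dissociation from brain tissue binding
#'   protein (min^-1); k6/k5 is the tissue-binding dissociation constant.
#' @param k7 rate constant of drug dissociation from albumin in the brain
#'   capillary (min^-1); k7/k8 is the in-vivo albumin dissociation
#'   constant.
#' @param k8 rate constant of drug association with albumin in the brain
#'   capillary (nM^-1 min^-1).
#' @param k9 rate constant of drug metabolism in brain (min^-1).
#' @param k10 rate constant of brain capillary plasma flow (min^-1).
#' @param label free-text drug or scenario name.
#'
#' @return An object of class `drug_params`: a named list of the 18
#'   parameters plus `label`.
#' @seealso [builtin_parameters()], [derived_constants()],
#'   [solve_steady_state()]
#' @export
#' @examples
#' p <- builtin_parameters("propranolol")
#' p$k3
drug_params <- function(LT0, AF, GT0, KA_in_vitro, KG_in_vitro, PT, VP, VT,
                        k1, k2, k3, k4, k5, k6, k7, k8, k9, k10,
                        label = "custom") {
  p <- list(LT0 = LT0, AF = AF, GT0 = GT0,
            KA_in_vitro = KA_in_vitro, KG_in_vitro = KG_in_vitro, PT = PT,
            VP = VP, VT = VT,
            k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
            k6 = k6, k7 = k7, k8 = k8, k9 = k9, k10 = k10,
            label = as.character(label))
  validate_drug_params(p)
  structure(p, class = "drug_params")
}

validate_drug_params <- function(p) {
  for (f in .DRUG_FIELDS) {
    v <- p[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", f, "' must be >= 0 (got ", v, ")", call. = FALSE)
  }
  for (f in c("VP", "VT", "k3", "k10"))
    if (p[[f]] <= 0)
      stop("parameter '", f, "' must be > 0 (got ", p[[f]], ")", call. = FALSE)
  # binding present requires a finite dissociation constant
  if (p$AF > 0 && p$KA_in_vitro <= 0)
    stop("KA_in_vitro must be > 0 when albumin (AF) is present", call. = FALSE)
  if (p$GT0 > 0 && p$KG_in_vitro <= 0)
    stop("KG_in_vitro must be > 0 when globulin (GT0) is present", call. = FALSE)
  invisible(p)
}

#' One-compartment oral pharmacokinetic parameters
#'
#' Parameters of the first-order absorption / first-order elimination
#' model that drives the total plasma drug concentration after a single
#' oral dose.
#'
#' @param b fractional oral bioavailability (dimensionless, 0 < b <= 1).
#' @param s dose (nmol/kg).
#' @param k absorption rate constant (min^-1).
#' @param d systemic elimination rate constant (min^-1); must differ
#'   from `k`.
#' @param V systemic volume of distribution (L/kg).
#' @return An object of class `oral_pk`.
#' @seealso [oral_plasma_concentration()], [simulate_oral()]
#' @export
oral_pk <- function(b, s, k, d, V) {
  p <- list(b = b, s = s, k = k, d = d, V = V)
  for (f in .ORAL_FIELDS) {
    v <- p[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop("oral PK parameter '", f, "' must be a single finite number",
           call. = FALSE)
  }
  if (b <= 0 || b > 1) stop("b must satisfy 0 < b <= 1", call. = FALSE)
  if (s <= 0) stop("dose s must be > 0", call. = FALSE)
  if (V <= 0) stop("volume V must be > 0", call. = FALSE)
  if (k <= 0 || d <= 0) stop("k and d must be > 0", call. = FALSE)
  if (k == d)
    stop("absorption and elimination rate constants must differ (k != d)",
         call. = FALSE)
  structure(p, class = "oral_pk")
}

#' Built-in basal parameter sets
#'
#' Basal model parameters for the two reference drugs. Propranolol
#' undergoes modest plasma-protein-mediated uptake (PMU) from the
#' AGP-bound pool only; imipramine undergoes extensive PMU from both the
#' albumin- and AGP-bound pools. For imipramine the literature constrains
#' k6 (<= 0.5 min^-1) and k7 (>= 6,000 min^-1) by inequalities; the basal
#' set pins them at those bounds.
#'
#' @param drug `"propranolol"` or `"imipramine"`.
#' @return A [drug_params] object. For propranolol the one-compartment
#'   oral PK parameters are attached as attribute `"oral_pk"` (also
#'   retrievable with [builtin_oral_pk()]); no oral parameter set exists
#'   for imipramine.
#' @export
#' @examples
#' builtin_parameters("imipramine")$k3
builtin_parameters <- function(drug = c("propranolol", "imipramine")) {
  if (!is.character(drug) || length(drug) != 1L ||
      !(drug %in% c("propranolol", "imipramine")))
    stop("unknown drug '", paste(drug, collapse = ","),
         "'; supported drugs are: propranolol, imipramine", call. = FALSE)
  p <- switch(drug,
    propranolol = drug_params(
      LT0 = 100, AF = 800000, GT0 = 20000,
      KA_in_vitro = 290000, KG_in_vitro = 3300, PT = 5000,
      VP = 0.01, VT = 0.7,
      k1 = 1140, k2 = 0.06, k3 = 66, k4 = 0.943,
      k5 = 0.006, k6 = 0.52, k7 = 1740, k8 = 0.006,
      k9 = 0, k10 = 60, label = "propranolol"),
    imipramine = drug_params(
      LT0 = 100, AF = 800000, GT0 = 20000,
      KA_in_vitro = 42000, KG_in_vitro = 1200, PT = 5000,
      VP = 0.01, VT = 0.7,
      k1 = 5400, k2 = 0.06, k3 = 150, k4 = 2.1,
      k5 = 0.006, k6 = 0.5, k7 = 6000, k8 = 0.006,
      k9 = 0, k10 = 60, label = "imipramine"))
  if (drug == "propranolol")
    attr(p, "oral_pk") <- oral_pk(b = 0.3, s = 4600, k = 0.023,
                                  d = 0.0027, V = 5.0)
  p
}

#' @rdname builtin_parameters
#' @export
builtin_oral_pk <- function(drug = "propranolol") {
  p <- builtin_parameters(drug)
  pk <- attr(p, "oral_pk")
  if (is.null(pk))
    stop("no oral pharmacokinetic parameters are available for '", drug, "'",
         call. = FALSE)
  pk
}

#' Derive capillary and BBB rate constants from equilibrium quantities
#'
#' Applies the model's parameter-derivation rules: the dissociation rate
#' constants in the brain capillary are the product of the association
#' rate constant and the in-vivo dissociation constant
#' (`k1 = k2 * KG_in_vivo`, `k7 = k8 * KA_in_vivo`); the BBB influx rate
#' constant is the permeability-surface area product expressed relative
#' to flow (`k3 = PS_over_F * k10`); and efflux assumes symmetric
#' transport (`k4 = k3 * VP/VT`).
#'
#' @param KG_in_vivo in-vivo dissociation constant, drug-AGP (nM).
#' @param k2 association rate constant, drug-AGP (nM^-1 min^-1).
#' @param KA_in_vivo in-vivo dissociation constant, drug-albumin (nM).
#' @param k8 association rate constant, drug-albumin (nM^-1 min^-1).
#' @param PS_over_F BBB permeability-surface area product divided by
#'   cerebral plasma flow (dimensionless).
#' @param k10 capillary plasma flow rate constant (min^-1).
#' @param VP,VT capillary plasma and brain extravascular volumes (L/kg).
#' @return Named list with elements `k1`, `k7`, `k3`, `k4` (min^-1).
#' @export
#' @examples
#' derive_rate_constants(19000, 0.06, 290000, 0.006, 1.1, 60, 0.01, 0.7)
derive_rate_constants <- function(KG_in_vivo, k2, KA_in_vivo, k8,
                                  PS_over_F, k10, VP, VT) {
  args <- list(KG_in_vivo = KG_in_vivo, k2 = k2, KA_in_vivo = KA_in_vivo,
               k8 = k8, PS_over_F = PS_over_F, k10 = k10, VP = VP, VT = VT)
  for (nm in names(args))
    if (!is.numeric(args[[nm]]) || length(args[[nm]]) != 1L ||
        !is.finite(args[[nm]]) || args[[nm]] <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  k3 <- PS_over_F * k10
  list(k1 = k2 * KG_in_vivo, k7 = k8 * KA_in_vivo,
       k3 = k3, k4 = k3 * VP / VT)
}

#' In-vivo dissociation constants implied by a parameter set
#'
#' @param params a [drug_params] object.
#' @return Named list: `KG_in_vivo = k1/k2`, `KA_in_vivo = k7/k8`,
#'   `KP = k6/k5` (all nM; `NA` where the association rate is zero).
#' @export
derived_constants <- function(params) {
  stopifnot(inherits(params, "drug_params"))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  list(KG_in_vivo = rat(params$k1, params$k2),
       KA_in_vivo = rat(params$k7, params$k8),
       KP = rat(params$k6, params$k5))
}

#' @export
print.drug_params <- function(x, ...) {
  cat("<drug_params> ", x$label, "\n", sep = "")
  v <- unlist(x[.DRUG_FIELDS])
  print(v)
  dc <- derived_constants(x)
  cat(sprintf("KG_in_vivo = %g nM, KA_in_vivo = %g nM, KP = %g nM\n",
              dc$KG_in_vivo, dc$KA_in_vivo, dc$KP))
  if (!is.null(attr(x, "oral_pk"))) cat("(oral PK parameters attached)\n")
  invisible(x)
}

#' @export
print.oral_pk <- function(x, ...) {
  cat("<oral_pk>\n")
  print(unlist(x[.ORAL_FIELDS]))
  invisible(x)
}

# ---- config file I/O --------------------------------------------------

.parse_config_file <- function(path, simplify = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = simplify),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format '", ext, "' (use .json, .yaml or .yml)",
         call. = FALSE))
  if (!is.list(vals)) vals <- as.list(vals)
  vals
}

#' Read a drug parameter configuration file
#'
#' Reads a flat JSON or YAML mapping whose keys are the parameter names
#' of [drug_params()] (plus an optional `label`, and optionally the five
#' oral PK keys `b`, `s`, `k`, `d`, `V`, which are attached as attribute
#' `"oral_pk"`). All values pass the same validation as the constructors.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A [drug_params] object (with an `"oral_pk"` attribute when the
#'   oral keys are present).
#' @seealso [write_config()]
#' @export
read_config <- function(path) {
  vals <- .parse_config_file(path)
  missing <- setdiff(.DRUG_FIELDS, names(vals))
  if (length(missing))
    stop("config file '", path, "' is missing required parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (f in .DRUG_FIELDS)
    if (!is.numeric(vals[[f]]))
      stop("parameter '", f, "' in '", path, "' is not numeric", call. = FALSE)
  args <- vals[.DRUG_FIELDS]
  args$label <- if (!is.null(vals$label)) vals$label else
    tools::file_path_sans_ext(basename(path))
  p <- do.call(drug_params, args)
  oral_present <- intersect(.ORAL_FIELDS, names(vals))
  if (length(oral_present) == length(.ORAL_FIELDS)) {
    attr(p, "oral_pk") <- do.call(oral_pk, vals[.ORAL_FIELDS])
  } else if (length(oral_present)) {
    stop("config file '", path, "' has an incomplete oral PK block; ",
         "missing: ", paste(setdiff(.ORAL_FIELDS, oral_present),
                            collapse = ", "), call. = FALSE)
  }
  p
}

#' Write a drug parameter configuration file
#'
#' @param params a [drug_params] object; any attached `"oral_pk"`
#'   attribute is written alongside (or pass `pk` explicitly).
#' @param path output path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @param pk optional [oral_pk] object to include.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, pk = attr(params, "oral_pk")) {
  stopifnot(inherits(params, "drug_params"))
  out <- c(params[.DRUG_FIELDS], list(label = params$label))
  if (!is.null(pk)) {
    stopifnot(inherits(pk, "oral_pk"))
    out <- c(out, pk[.ORAL_FIELDS])
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(out, path),
    stop("unsupported config format '", ext, "' (use .json, .yaml or .yml)",
         call. = FALSE))
  invisible(path)
}
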