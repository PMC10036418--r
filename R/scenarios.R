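# Declarative scenario engine: named parameter overrides on a base
# drug, batch steady-state / oral runs, the paper-style percent and
# fold comparisons, and parameter sweeps. The packaged scenario files
# under extdata/scenarios mirror the perturbation studies verbatim
# (base + overrides), so they double as documentation of each run.

#' Apply parameter overrides to a drug parameter set
#'
#' @param params a [drug_params] object.
#' @param overrides named list mapping parameter names (fields of
#'   [drug_params()] or [oral_pk()]) to replacement values. Oral keys
#'   require an attached oral PK set.
#' @param label optional new label; defaults to the old label.
#' @return A validated [drug_params] object with the overrides applied.
#' @export
#' @examples
#' with_overrides(builtin_parameters("propranolol"), list(k4 = 9.4))$k4
with_overrides <- function(params, overrides, label = NULL) {
  stopifnot(inherits(params, "drug_params"))
  if (is.null(overrides)) overrides <- list()
  if (length(overrides) && (is.null(names(overrides)) ||
                            any(!nzchar(names(overrides)))))
    stop("overrides must be a named list", call. = FALSE)
  drug_keys <- intersect(names(overrides), .DRUG_FIELDS)
  oral_keys <- intersect(names(overrides), .ORAL_FIELDS)
  bad <- setdiff(names(overrides), c(.DRUG_FIELDS, .ORAL_FIELDS, "label"))
  if (length(bad))
    stop("unknown override parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- params[.DRUG_FIELDS]
  args[drug_keys] <- overrides[drug_keys]
  args$label <- label %||% overrides$label %||% params$label
  out <- do.call(drug_params, args)
  pk <- attr(params, "oral_pk")
  if (length(oral_keys)) {
    if (is.null(pk))
      stop("oral PK override(s) (", paste(oral_keys, collapse = ", "),
           ") but the base parameter set has no oral PK component",
           call. = FALSE)
    pka <- pk[.ORAL_FIELDS]
    pka[oral_keys] <- overrides[oral_keys]
    pk <- do.call(oral_pk, pka)
  }
  attr(out, "oral_pk") <- pk
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a simulation scenario
#'
#' @param label scenario name (e.g. `"sim7"`).
#' @param base a drug name accepted by [builtin_parameters()], a config
#'   file path, or a [drug_params] object.
#' @param overrides named list of parameter overrides (may be empty).
#' @param mode `"steady"` for the closed-form steady state or `"oral"`
#'   for the non-steady-state oral simulation.
#' @param horizon,grid_step oral-mode integration settings (min).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, base, overrides = list(),
                          mode = c("steady", "oral"),
                          horizon = 1440, grid_step = 1) {
  mode <- match.arg(mode)
  structure(list(label = as.character(label), base = base,
                 overrides = overrides, mode = mode,
                 horizon = horizon, grid_step = grid_step),
            class = "scenario_spec")
}

.resolve_base <- function(base) {
  if (inherits(base, "drug_params")) return(base)
  if (is.character(base) && length(base) == 1L) {
    if (base %in% c("propranolol", "imipramine"))
      return(builtin_parameters(base))
    if (file.exists(base)) return(read_config(base))
    stop("scenario base '", base, "' is neither a built-in drug ",
         "(propranolol, imipramine) nor an existing config file",
         call. = FALSE)
  }
  stop("scenario base must be a drug name, a config file path, or a ",
       "drug_params object", call. = FALSE)
}

#' Percent change and fold ratio
#'
#' Conventions used for all reported comparisons:
#' `pct_change(x, ref) = 100*(x - ref)/ref` and
#' `fold_change(x, ref) = x/ref`. Both return `NA` (with a warning) for
#' a zero reference.
#'
#' @param x,ref numeric vectors.
#' @return Numeric vector.
#' @export
pct_change <- function(x, ref) {
  out <- 100 * (x - ref) / ref
  if (any(ref == 0)) {
    warning("percent change undefined for zero reference")
    out[ref == 0] <- NA_real_
  }
  out
}

#' @rdname pct_change
#' @export
fold_change <- function(x, ref) {
  out <- x / ref
  if (any(ref == 0)) {
    warning("fold change undefined for zero reference")
    out[ref == 0] <- NA_real_
  }
  out
}

#' Run a single scenario
#'
#' Resolves the base parameters, applies the overrides, and dispatches
#' to [solve_steady_state()] (`mode = "steady"`) or [simulate_oral()]
#' plus [summarize_auc()] (`mode = "oral"`). Steady reports carry the
#' headline comparisons of bioavailable (LF) and free-brain (LM) drug
#' against the in-vitro free concentration LF0.
#'
#' @param spec a [scenario_spec] (or a plain list with the same fields).
#' @return An object of class `scenario_report`: list with `label`,
#'   `mode`, `params`, and either `solution` (a `steady_state`) plus
#'   `pct_LF_vs_LF0`, `pct_LM_vs_LF0`, `fold_LF_LF0`, `fold_LM_LF0`, or
#'   `time_course` plus `auc` (an `auc_summary`).
#' @export
#' @examples
#' rep <- run_scenario(scenario_spec("AET", "propranolol",
#'                                   list(k4 = 9.4)))
#' round(c(rep$solution$LF, rep$solution$LM), 1)
run_scenario <- function(spec) {
  if (!inherits(spec, "scenario_spec")) {
    if (!is.list(spec) || is.null(spec$label) || is.null(spec$base))
      stop("spec must be a scenario_spec or a list with at least ",
           "'label' and 'base'", call. = FALSE)
    spec <- scenario_spec(spec$label, spec$base,
                          spec$overrides %||% list(),
                          spec$mode %||% "steady",
                          spec$horizon %||% 1440,
                          spec$grid_step %||% 1)
  }
  params <- with_overrides(.resolve_base(spec$base), spec$overrides,
                           label = spec$label)
  if (spec$mode == "steady") {
    sol <- solve_steady_state(params)
    LF0 <- sol$arterial$LF0
    structure(list(label = spec$label, mode = "steady", params = params,
                   solution = sol,
                   pct_LF_vs_LF0 = pct_change(sol$LF, LF0),
                   pct_LM_vs_LF0 = pct_change(sol$LM, LF0),
                   fold_LF_LF0 = fold_change(sol$LF, LF0),
                   fold_LM_LF0 = fold_change(sol$LM, LF0)),
              class = "scenario_report")
  } else {
    pk <- attr(params, "oral_pk")
    if (is.null(pk))
      stop("scenario '", spec$label, "': oral mode requires oral PK ",
           "parameters on the base drug", call. = FALSE)
    tc <- simulate_oral(params, pk, horizon = spec$horizon,
                        grid_step = spec$grid_step)
    structure(list(label = spec$label, mode = "oral", params = params,
                   time_course = tc, auc = summarize_auc(tc)),
              class = "scenario_report")
  }
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report> ", x$label, " [", x$mode, "]\n", sep = "")
  if (x$mode == "steady") {
    print(x$solution)
    cat(sprintf("LF vs LF0: %+.1f%% (%.3g-fold); LM vs LF0: %+.1f%%\n",
                x$pct_LF_vs_LF0, x$fold_LF_LF0, x$pct_LM_vs_LF0))
  } else {
    print(x$auc)
  }
  invisible(x)
}

#' Run a batch of steady-state scenarios as a table
#'
#' One row per scenario in the column order of the perturbation-study
#' tables (arterial GL0, AL0, LF0; capillary GL, AL, LF; brain LM, PL,
#' PF; Kp_brain), with the LF-vs-LF0 comparisons appended. A failing
#' scenario yields a row of `NA`s with the error message in the `error`
#' column rather than aborting the batch.
#'
#' @param specs a non-empty list of [scenario_spec]s (or plain lists).
#' @return A data.frame, one row per scenario.
#' @export
run_table <- function(specs) {
  if (!is.list(specs) || length(specs) == 0L)
    stop("specs must be a non-empty list of scenarios", call. = FALSE)
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  rows <- lapply(specs, function(s) {
    rep <- tryCatch(run_scenario(s), error = function(e) e)
    if (inherits(rep, "error")) {
      lab <- if (is.list(s) && !is.null(s$label)) s$label else NA_character_
      return(data.frame(label = lab, GL0 = NA_real_, AL0 = NA_real_,
                        LF0 = NA_real_, GL = NA_real_, AL = NA_real_,
                        LF = NA_real_, LM = NA_real_, PL = NA_real_,
                        PF = NA_real_, Kp_brain = NA_real_,
                        pct_LF_vs_LF0 = NA_real_, fold_LF_LF0 = NA_real_,
                        error = conditionMessage(rep),
                        stringsAsFactors = FALSE))
    }
    if (rep$mode != "steady")
      stop("run_table handles steady-mode scenarios only (got oral for '",
           rep$label, "')", call. = FALSE)
    sol <- rep$solution
    data.frame(label = rep$label,
               GL0 = sol$arterial$GL0, AL0 = sol$arterial$AL0,
               LF0 = sol$arterial$LF0,
               GL = sol$GL, AL = sol$AL, LF = sol$LF,
               LM = sol$LM, PL = sol$PL, PF = sol$PF,
               Kp_brain = sol$Kp_brain,
               pct_LF_vs_LF0 = rep$pct_LF_vs_LF0,
               fold_LF_LF0 = rep$fold_LF_LF0,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Steady-state parameter sweep
#'
#' Solves the steady state once per value of a single parameter and
#' tabulates the brain-relevant outputs. Sweeping the brain tissue
#' binding protein PT (or k5, k6) leaves the free drug in brain LM
#' unchanged — free brain drug is independent of tissue binding — while
#' PL and hence Kp_brain grow with PT.
#'
#' @param base a [drug_params] object (or drug name / config path).
#' @param param name of the parameter to sweep.
#' @param values ordered numeric vector of parameter values.
#' @return A data.frame with columns `value`, `LF`, `LM`, `PL`,
#'   `Kp_brain`.
#' @export
#' @examples
#' parameter_sweep(builtin_parameters("propranolol"), "PT",
#'                 c(500, 1000, 5000))
parameter_sweep <- function(base, param, values) {
  params <- .resolve_base(base)
  if (!is.character(param) || length(param) != 1L ||
      !(param %in% .DRUG_FIELDS))
    stop("param must be one of: ", paste(.DRUG_FIELDS, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(values) || length(values) == 0L)
    stop("values must be a non-empty numeric vector", call. = FALSE)
  rows <- lapply(values, function(v) {
    ov <- stats::setNames(list(v), param)
    sol <- solve_steady_state(with_overrides(params, ov))
    data.frame(value = v, LF = sol$LF, LM = sol$LM, PL = sol$PL,
               Kp_brain = sol$Kp_brain)
  })
  do.call(rbind, rows)
}

# ---- packaged scenario sets ------------------------------------------

#' Packaged perturbation-study scenario sets
#'
#' The steady-state simulation sets for the two reference drugs:
#' simulations 1-10 (propranolol) and 11-20 (imipramine) plus the
#' verifiable supplementary variants (reduced brain tissue binding
#' protein PT = 1,000 / 500 nM, tenfold higher / lower brain association
#' rate k5, and the no-plasma-binding case, simulation 30). Each entry
#' is declarative: base drug plus the overrides of the study's
#' "parameter change" column. The same sets ship as JSON under
#' `system.file("extdata/scenarios", package = "bbbpk")`.
#'
#' @param drug `"propranolol"` or `"imipramine"`.
#' @param supplementary include the supplementary variants
#'   (propranolol only).
#' @return A list of [scenario_spec]s.
#' @export
#' @examples
#' tab <- run_table(builtin_scenarios("imipramine"))
#' tab[, c("label", "LF", "LM", "Kp_brain")]
builtin_scenarios <- function(drug = c("propranolol", "imipramine"),
                              supplementary = FALSE) {
  drug <- match.arg(drug)
  sc <- function(label, overrides = list())
    scenario_spec(label, drug, overrides, mode = "steady")
  if (drug == "propranolol") {
    specs <- list(
      sc("sim1"),
      sc("sim2", list(k1 = 198)),
      sc("sim3", list(AF = 600000, GT0 = 70000)),
      sc("sim4", list(k1 = 11400, k2 = 0.6)),
      sc("sim5", list(k1 = 114, k2 = 0.006)),
      sc("sim6", list(k1 = 198, k3 = 66600, k4 = 940)),
      sc("sim7", list(k4 = 9.4)),
      sc("sim8", list(k9 = 6)),
      sc("sim9", list(k9 = 6, k10 = 6)),
      sc("sim10", list(k4 = 9.4, k9 = 6)))
    if (supplementary)
      specs <- c(specs, list(
        sc("PT1000", list(PT = 1000)),
        sc("PT500", list(PT = 500)),
        sc("k5x10", list(k5 = 0.06)),
        sc("k5d10", list(k5 = 0.0006)),
        sc("sim30", list(AF = 0, GT0 = 0))))
  } else {
    specs <- list(
      sc("sim11"),
      sc("sim12", list(k1 = 72, k7 = 252)),
      sc("sim13", list(AF = 600000, GT0 = 70000)),
      sc("sim14", list(k1 = 54000, k2 = 0.6)),
      sc("sim15", list(k1 = 540, k2 = 0.006)),
      sc("sim16", list(k1 = 72, k3 = 150000, k4 = 2100, k7 = 252)),
      sc("sim17", list(k4 = 21)),
      sc("sim18", list(k9 = 6)),
      sc("sim19", list(k9 = 6, k10 = 6)),
      sc("sim20", list(k4 = 21, k9 = 6)))
  }
  specs
}

#' Read scenario specs from a JSON/YAML file or directory
#'
#' A scenario file holds either one mapping or a list of mappings with
#' keys `label`, `base`, `overrides`, and optionally `mode`, `horizon`,
#' `grid_step`. A directory is read as all `.json`/`.yaml`/`.yml` files
#' it contains, sorted by name.
#'
#' @param path file or directory.
#' @return A list of [scenario_spec]s.
#' @export
read_scenarios <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(json|ya?ml)$",
                             full.names = TRUE))
    if (!length(files))
      stop("no scenario files found in directory: ", path, call. = FALSE)
    return(do.call(c, lapply(files, read_scenarios)))
  }
  vals <- .parse_config_file(path, simplify = FALSE)
  if (!is.null(vals$label)) vals <- list(vals)
  lapply(vals, function(v) {
    if (is.null(v$label) || is.null(v$base))
      stop("scenario entry in '", path, "' lacks 'label' or 'base'",
           call. = FALSE)
    scenario_spec(v$label, v$base, v$overrides %||% list(),
                  v$mode %||% "steady", v$horizon %||% 1440,
                  v$grid_step %||% 1)
  })
}
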