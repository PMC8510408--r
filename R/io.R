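## Tabular input with schema validation and unit canonicalization, plus the
## end-to-end pipeline driver.
##
## Canonical units: concentration mM, temperature K, time min, volume mL,
## conductivity uS/cm, percentages %, dimensionless quantities unscaled.

.unit_table <- list(
  ## unit = c(scale, offset): canonical = scale * x + offset
  mM = c(1, 0), M = c(1000, 0), uM = c(1e-3, 0),
  K = c(1, 0), C = c(1, 273.15),
  min = c(1, 0), s = c(1 / 60, 0), h = c(60, 0),
  mL = c(1, 0), L = c(1000, 0), uL = c(1e-3, 0),
  `uS/cm` = c(1, 0), `mS/cm` = c(1000, 0), `S/m` = c(1e4, 0),
  percent = c(1, 0), fraction = c(1, 0), none = c(1, 0)
)

#' Convert a numeric vector to the package's canonical unit
#'
#' @param x Numeric vector.
#' @param unit Declared unit of `x`; one of `mM`, `M`, `uM`, `K`, `C`,
#'   `min`, `s`, `h`, `mL`, `L`, `uL`, `uS/cm`, `mS/cm`, `S/m`, `percent`,
#'   `fraction`, `none`.
#' @return `x` expressed in the canonical unit of its quantity class
#'   (mM, K, min, mL, uS/cm, or unchanged for dimensionless units).
#' @export
convert_unit <- function(x, unit) {
  if (!unit %in% names(.unit_table)) {
    stop_schema("unknown unit `", unit, "`; known: ",
                paste(names(.unit_table), collapse = ", "))
  }
  u <- .unit_table[[unit]]
  u[1] * x + u[2]
}

#' Read and validate a CSV table against a column schema
#'
#' Every declared column must be present; numeric columns are parsed with
#' row-level error reporting and converted to the package's canonical units.
#' Undeclared columns are carried through untouched.
#'
#' @param path CSV file path.
#' @param schema Either a named list — one entry per declared column, each a
#'   list with `unit` (see [convert_unit()]; implies numeric) or
#'   `type = "character"`, plus optional `required` (default `TRUE`) — or the
#'   path to a YAML file holding that list under a `columns:` key.
#' @return A validated data frame in canonical units.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(cmc_M = 0.004), f, row.names = FALSE)
#' read_table(f, list(cmc_M = list(unit = "M")))  # 4 mM
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  if (is.character(schema) && length(schema) == 1) {
    schema <- yaml::read_yaml(schema)$columns
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  for (col in names(schema)) {
    spec <- schema[[col]]
    required <- !isFALSE(spec$required)
    if (!col %in% names(raw)) {
      if (required) {
        stop_schema("missing column `", col, "` in ", basename(path))
      }
      next
    }
    if (identical(spec$type, "character")) next
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(raw[[col]]) & !is.na(raw[[col]]))
    if (length(bad)) {
      stop_schema(sprintf(
        "column `%s` in %s: unparseable value(s) at data row(s) %s",
        col, basename(path), paste(utils::head(bad, 5), collapse = ", ")))
    }
    raw[[col]] <- convert_unit(v, spec$unit %||% "none")
  }
  raw
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full meta-analysis pipeline from a configuration
#'
#' Executes the stages requested by `config` — mixture interaction
#' parameters, conductometric CMC detection, molar solubilization ratios,
#' PLS/VIP meta-regression with group summaries and Welch tests, and
#' lipolysis kinetics — writing one CSV per stage plus a JSON run manifest
#' (package version, seed, per-stage status and row counts) to
#' `config$out_dir`. A failing stage is recorded in the manifest and does not
#' abort the remaining stages.
#'
#' @param config Named list (or path to a YAML file). Recognized entries:
#'   `out_dir` (required), `seed`, and per-stage blocks:
#'   \describe{
#'     \item{mixtures}{`list(path=)` — mixtures CSV with columns
#'       `pair_label, alpha, cmc_mix_mM, cmc1_mM, cmc2_mM`.}
#'     \item{titration}{`list(path=)` — CSV with
#'       `concentration_mM, conductivity_uS_cm`; both Phillips and segmented
#'       estimates are reported.}
#'     \item{solubility}{`list(path=, cmc=)` — CSV with
#'       `surfactant_conc_mM, solubilizate_conc_mM`.}
#'     \item{meta}{`list(path=, response=, levels=, numeric_cols=, ncomp=,
#'       compare=)` — meta-table CSV; `levels` as in [one_hot_encode()];
#'       `compare` an optional list of
#'       `list(column=, level_a=, level_b=, tail=)` Welch contrasts.}
#'     \item{lipolysis}{`list(path=, naoh_molarity=, lipid_mass=,
#'       lipid_molar_mass=, at_time=)` — time-series CSV with
#'       `time_min, naoh_mL, condition, replicate`; the two conditions are
#'       compared at `at_time`.}
#'   }
#' @return Invisibly, the manifest list; `$ok` is `TRUE` when every
#'   requested stage succeeded.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config) || length(config) == 0 || is.null(config$out_dir)) {
    stop_schema("empty or invalid config: `out_dir` is required")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  manifest <- list(
    package = "bilemix",
    version = as.character(utils::packageVersion("bilemix")),
    seed = config$seed, config = config, stages = list()
  )
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    manifest$stages[[name]] <<- if (inherits(res, "error")) {
      list(status = "error", message = conditionMessage(res))
    } else {
      c(list(status = "ok"), res)
    }
  }

  if (!is.null(config$mixtures)) {
    run_stage("mixtures", function() {
      schema <- list(alpha = list(unit = "fraction"),
                     cmc_mix_mM = list(unit = "mM"),
                     cmc1_mM = list(unit = "mM"),
                     cmc2_mM = list(unit = "mM"))
      mx <- read_table(config$mixtures$path, schema)
      out <- beta_table(mx)
      .write_csv(out, file.path(config$out_dir, "beta.csv"))
      list(rows_in = nrow(mx), rows_out = nrow(out), output = "beta.csv")
    })
  }

  if (!is.null(config$titration)) {
    run_stage("titration", function() {
      schema <- list(concentration_mM = list(unit = "mM"),
                     conductivity_uS_cm = list(unit = "uS/cm"))
      tt <- read_table(config$titration$path, schema)
      curve <- conductivity_titration(tt$concentration_mM,
                                      tt$conductivity_uS_cm)
      ph <- phillips_cmc(curve)
      sg <- segmented_cmc(curve)
      out <- data.frame(
        method = c("phillips", "segmented"),
        cmc_mM = c(ph$cmc, sg$cmc),
        uncertainty_mM = c(ph$uncertainty, sg$uncertainty),
        ionization_degree = c(NA, ionization_degree(
          sg$diagnostics$pre_slope, sg$diagnostics$post_slope))
      )
      .write_csv(out, file.path(config$out_dir, "cmc.csv"))
      list(rows_in = nrow(tt), rows_out = nrow(out), output = "cmc.csv")
    })
  }

  if (!is.null(config$solubility)) {
    run_stage("solubility", function() {
      schema <- list(surfactant_conc_mM = list(unit = "mM"),
                     solubilizate_conc_mM = list(unit = "mM"))
      sb <- read_table(config$solubility$path, schema)
      ser <- solubilization_series(sb$surfactant_conc_mM,
                                   sb$solubilizate_conc_mM,
                                   cmc = config$solubility$cmc)
      fit <- compute_msr(ser)
      out <- data.frame(msr = fit$msr, se = fit$se, n_used = fit$n_used,
                        cmc_mM = fit$cmc)
      .write_csv(out, file.path(config$out_dir, "msr.csv"))
      list(rows_in = nrow(sb), rows_out = 1, output = "msr.csv")
    })
  }

  if (!is.null(config$meta)) {
    run_stage("meta", function() {
      mc <- config$meta
      df <- utils::read.csv(mc$path, stringsAsFactors = FALSE)
      y <- df[[mc$response]]
      X <- one_hot_encode(df, lapply(mc$levels, unlist),
                          numeric_cols = unlist(mc$numeric_cols))
      fit <- fit_pls(X, y, ncomp = mc$ncomp %||% 2)
      vip <- vip_scores(fit)
      .write_csv(as.data.frame(vip),
                 file.path(config$out_dir, "vip.csv"))
      .write_csv(data.frame(variable = names(fit$coefficients),
                            coefficient = unname(fit$coefficients)),
                 file.path(config$out_dir, "coefficients.csv"))
      gcol <- names(mc$levels)[1]
      .write_csv(group_summary(df, mc$response, gcol),
                 file.path(config$out_dir, "group_summary.csv"))
      tests <- NULL
      for (cmp in mc$compare) {
        a <- y[df[[cmp$column]] == cmp$level_a]
        b <- y[df[[cmp$column]] == cmp$level_b]
        tt <- welch_t_test(a, b, tail = cmp$tail %||% "two")
        tests <- rbind(tests, data.frame(
          column = cmp$column, level_a = cmp$level_a, level_b = cmp$level_b,
          t = tt$t, df = tt$df, p_value = tt$p_value,
          significant = tt$significant))
      }
      if (!is.null(tests)) {
        .write_csv(tests, file.path(config$out_dir, "tests.csv"))
      }
      list(rows_in = nrow(df), rows_out = nrow(vip),
           output = "vip.csv, coefficients.csv, group_summary.csv")
    })
  }

  if (!is.null(config$lipolysis)) {
    run_stage("lipolysis", function() {
      lc <- config$lipolysis
      schema <- list(time_min = list(unit = "min"),
                     naoh_mL = list(unit = "mL"),
                     condition = list(type = "character"),
                     replicate = list(type = "character"))
      ts <- read_table(lc$path, schema)
      profs <- lapply(split(ts, list(ts$condition, ts$replicate),
                            drop = TRUE), function(d) {
        d <- d[order(d$time_min), ]
        ffa_percent(lipolysis_run(
          d$time_min, d$naoh_mL,
          naoh_molarity = lc$naoh_molarity %||% 0.1,
          lipid_mass = lc$lipid_mass %||% 0.075,
          lipid_molar_mass = lc$lipid_molar_mass %||% 880,
          condition = d$condition[1]))
      })
      conds <- vapply(profs, `[[`, character(1), "condition")
      fits <- lapply(profs, fit_first_order)
      out <- data.frame(
        condition = conds,
        phi_max = vapply(fits, `[[`, numeric(1), "phi_max"),
        k = vapply(fits, `[[`, numeric(1), "k"))
      .write_csv(out, file.path(config$out_dir, "lipolysis.csv"))
      extra <- list()
      uc <- unique(conds)
      if (length(uc) == 2 && !is.null(lc$at_time)) {
        cmpres <- compare_conditions(profs[conds == uc[1]],
                                     profs[conds == uc[2]],
                                     at_time = lc$at_time)
        .write_csv(data.frame(condition_a = uc[1], condition_b = uc[2],
                              at_time = lc$at_time,
                              difference = cmpres$difference,
                              p_value = cmpres$p_value),
                   file.path(config$out_dir, "lipolysis_comparison.csv"))
        extra <- list(comparison = "lipolysis_comparison.csv")
      }
      c(list(rows_in = nrow(ts), rows_out = nrow(out),
             output = "lipolysis.csv"), extra)
    })
  }

  if (length(manifest$stages) == 0) {
    stop_schema("config requests no stages")
  }
  manifest$ok <- all(vapply(manifest$stages, function(s)
    identical(s$status, "ok"), logical(1)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
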