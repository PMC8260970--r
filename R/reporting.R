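#' Per-bin baseline and mortality summary table
#'
#' Builds the analog of the published per-TB-bin baseline tables: for each
#' of the seven TB bins, the patient count, demographic and laboratory
#' summaries (mean/SD for age and scores, median/IQR for skewed
#' laboratories, counts/percentages for categorical rows), and 28-/90-day
#' transplantation-free death counts with percentages. Percentages are
#' rounded half-up to one decimal. Empty bins are emitted with `n = 0` and
#' missing summaries.
#'
#' @param cohort A filtered, scored cohort (needs `tb`, `death_28`,
#'   `death_90`; other columns are summarized when present).
#' @return A tibble with one row per TB bin plus an `overall` row.
#' @export
build_bin_table <- function(cohort) {
  cohort <- as_tibble(cohort)
  cohort <- filter(cohort, !is.na(.data$tb))
  cohort$tb_bin <- tb_bin(cohort$tb)

  med_iqr <- function(x) {
    if (!length(x) || all(is.na(x))) return(NA_character_)
    q <- quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE)
    sprintf("%.1f (%.1f, %.1f)", q[1], q[2], q[3])
  }
  mean_sd <- function(x) {
    if (!length(x) || all(is.na(x))) return(NA_character_)
    sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
  }
  opt <- function(x, f) if (is.null(x)) NA_character_ else f(x)

  summarise_chunk <- function(d, label) {
    n <- nrow(d)
    d28 <- sum(d$death_28, na.rm = TRUE)
    d90 <- sum(d$death_90, na.rm = TRUE)
    tibble(
      tb_bin = label,
      n = n,
      age = opt(d[["age"]], mean_sd),
      male_n = if (is.null(d[["sex"]])) NA_integer_ else sum(d[["sex"]], na.rm = TRUE),
      ascites_n = if (is.null(d[["ascites"]])) NA_integer_ else sum(d[["ascites"]], na.rm = TRUE),
      infection_n = if (is.null(d[["infection"]])) NA_integer_ else sum(d[["infection"]], na.rm = TRUE),
      hemoglobin = opt(d[["hemoglobin"]], med_iqr),
      platelets = opt(d[["platelets"]], med_iqr),
      inr = opt(d[["inr"]], med_iqr),
      creatinine = opt(d[["creatinine"]], med_iqr),
      albumin = opt(d[["albumin"]], med_iqr),
      alt = opt(d[["alt"]], med_iqr),
      ast = opt(d[["ast"]], med_iqr),
      sodium = opt(d[["sodium"]], med_iqr),
      meld = opt(d[["meld"]], mean_sd),
      ctp = opt(d[["ctp"]], mean_sd),
      deaths_28 = d28,
      pct_28 = if (n > 0) round_half_up(100 * d28 / n, 1) else NA_real_,
      deaths_90 = d90,
      pct_90 = if (n > 0) round_half_up(100 * d90 / n, 1) else NA_real_
    )
  }

  per_bin <- purrr::map(tb_bin_labels(), function(lab) {
    summarise_chunk(cohort[cohort$tb_bin == lab, , drop = FALSE], lab)
  })
  bind_rows(c(per_bin, list(summarise_chunk(cohort, "overall"))))
}

#' Run the full TB-mortality analysis pipeline
#'
#' Orchestrates every stage on a simulated or supplied cohort: scoring,
#' exclusion filtering, per-group Cox models (continuous and categorical,
#' with trend test), 28- and 90-day adjusted curves, acceleration and
#' inflection detection, the clinical cutoff, the cutoff exceedance
#' summary, and the per-bin table. When `out_dir` is given, the cohort and
#' tables are written as CSV and the reports as JSON.
#'
#' @param config A [cohort_config()] (used when `cohort` is `NULL`); may
#'   also be a path to a YAML/JSON configuration file, see [read_config()].
#' @param cohort Optionally, an existing cohort data frame.
#' @param horizons Curve horizons to fit, a subset of `c(28, 90)`.
#' @param grid_step TB grid step in mg/dL (default 0.1).
#' @param out_dir Optional output directory.
#' @return A named list per analysis group with elements `cox_continuous`,
#'   `cox_categorical`, `trend`, `gam` / `curve` / `acceleration` per
#'   horizon, `inflections`, `clinical_cutoff`, `cutoff_table`, `bin_table`,
#'   plus top-level `cohort`, `filter_report`, `seed`, and `config_hash`.
#' @export
run_tb_pipeline <- function(config = NULL, cohort = NULL,
                            horizons = c(28, 90), grid_step = 0.1,
                            out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(cohort)) {
    if (is.null(config)) {
      abort("supply either `config` or `cohort`.", class = "bilicurve_config_error")
    }
    cohort <- stage("simulate", simulate_cohort(config))
  }
  scored <- stage("score", add_scores(as_tibble(cohort)))
  analysis <- stage("filter", apply_exclusions(scored))
  report <- filter_report(analysis)
  grid <- seq(0, 50, by = grid_step)

  groups <- intersect(c("cirrhosis", "advanced_fibrosis"),
                      unique(analysis$analysis_group))
  results <- purrr::map(setNames(groups, groups), function(g) {
    sub <- filter(analysis, .data$analysis_group == g)
    res <- list(
      cox_continuous = stage("cox", fit_tb_cox(sub, "continuous")),
      cox_categorical = stage("cox", fit_tb_cox(sub, "categorical")),
      trend = stage("cox", tb_trend_test(sub)),
      bin_table = stage("tables", build_bin_table(sub))
    )
    curves <- list()
    for (h in horizons) {
      fit <- stage("curve", fit_tb_gam(sub, horizon = h))
      crv <- stage("curve", adjusted_risk_curve(fit, grid = grid))
      curves[[paste0("h", h)]] <- list(gam = fit, curve = crv)
    }
    res$curves <- curves
    crv90 <- curves$h90$curve
    crv28 <- curves$h28$curve
    main <- crv90 %||% crv28
    acc <- stage("cutoffs", acceleration_curve(main))
    infl <- stage("cutoffs", find_inflections(acc))
    res$acceleration <- acc
    res$inflections <- infl
    cuts <- c(mathematical = infl$peak, valley = infl$valley)
    if (!is.null(crv28)) {
      cc <- stage("cutoffs", clinical_cutoff(crv28))
      res$clinical_cutoff <- cc
      cuts <- c(cuts, clinical = as.numeric(cc))
    }
    res$cutoff_table <- stage(
      "cutoffs", summarize_cutoffs(sub, crv28, crv90, cuts))
    res
  })

  out <- list(cohort = scored, analysis = analysis, filter_report = report,
              groups = results,
              seed = if (!is.null(config)) config$seed else NA_integer_,
              config_hash = if (!is.null(config)) rlang::hash(config) else NA_character_)
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  invisible(out)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
          class = "bilicurve_pipeline_error", parent = e)
  })
}

write_pipeline <- function(res, out_dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("writing pipeline artifacts requires the jsonlite package.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(res$cohort, file.path(out_dir, "cohort.csv"))
  rep <- res$filter_report
  rep$dispositions <- NULL
  jsonlite::write_json(
    c(rep, list(seed = res$seed, config_hash = res$config_hash)),
    file.path(out_dir, "filter_report.json"), auto_unbox = TRUE, digits = NA)
  for (g in names(res$groups)) {
    r <- res$groups[[g]]
    readr::write_csv(tidy(r$cox_continuous),
                     file.path(out_dir, paste0(g, "_cox_continuous.csv")))
    readr::write_csv(tidy(r$cox_categorical),
                     file.path(out_dir, paste0(g, "_cox_categorical.csv")))
    readr::write_csv(r$bin_table, file.path(out_dir, paste0(g, "_bin_table.csv")))
    for (h in names(r$curves)) {
      readr::write_csv(r$curves[[h]]$curve,
                       file.path(out_dir, paste0(g, "_curve_", h, ".csv")))
    }
    readr::write_csv(r$cutoff_table,
                     file.path(out_dir, paste0(g, "_cutoffs.csv")))
  }
  invisible(res)
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' The file holds the [cohort_config()] arguments as top-level keys; `link`
#' is a mapping with a `shape` key plus the shape's parameters.
#'
#' @param path File path (`.yml`, `.yaml`, or `.json`).
#' @return A [cohort_config()].
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("reading JSON configs requires the jsonlite package.")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 parses a bare `n` key as a boolean; restore the field name
  names(raw)[names(raw) == "FALSE"] <- "n"
  if (!is.null(raw$link)) raw$link <- do.call(tb_link, raw$link)
  if (!is.null(raw$beta)) raw$beta <- unlist(raw$beta)
  if (!is.null(raw$tb_weights)) raw$tb_weights <- unlist(raw$tb_weights)
  do.call(cohort_config, raw)
}
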