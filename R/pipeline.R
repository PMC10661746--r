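#' Assemble a study configuration
#'
#' Two ingestion modes cover the two forms quantal interaction studies come
#' in: `"raw"` refits every curve from per-group protected/total counts,
#' while `"summary"` ingests published potency estimates (ED50, SEM, n) so a
#' printed interaction table can be reproduced exactly.
#'
#' @param mode `"summary"` or `"raw"`.
#' @param solo Solo potencies: data frame (or CSV path) with columns `drug`,
#'   `ed50`, `sem`, `n` (summary mode); in raw mode solo curves are fitted
#'   from `quantal` instead.
#' @param mixtures Summary mode only: data frame (or CSV path) with columns
#'   `combination`, `varied_drug`, `ed50_exp_total`, `sem_exp`, `n_exp` and
#'   optionally printed `sem_add`, `n_add` used for the interaction test in
#'   place of the delta-method/derived values.
#' @param quantal Raw mode only: [quantal_data] list or raw-mode CSV path;
#'   mixture curves are labelled by design id, solo curves by drug name.
#' @param designs List of design specs (`id`, `varied`, `adjuncts` as a list
#'   of `drug`/`dose` pairs, optional `pool_adjuncts_on`), or a JSON/YAML
#'   path containing `{"designs": [...]}`; may be empty for potency-only runs.
#' @param alpha Significance level for classification (default 0.05).
#' @param seed Optional integer recorded in the run log.
#' @return A `study_config` list.
#' @export
study_config <- function(mode = c("summary", "raw"), solo = NULL,
                         mixtures = NULL, quantal = NULL, designs = list(),
                         alpha = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  if (is.character(designs)) designs <- read_design_config(designs)$designs
  if (mode == "summary") {
    if (is.null(solo)) stop("summary mode needs a solo potency table",
                            call. = FALSE)
    if (is.character(solo)) solo <- utils::read.csv(solo)
    if (is.character(mixtures)) mixtures <- utils::read.csv(mixtures)
    if (length(designs) > 0 && is.null(mixtures)) {
      stop("summary mode with designs needs a mixture summary table",
           call. = FALSE)
    }
  } else {
    if (is.null(quantal)) stop("raw mode needs quantal datasets", call. = FALSE)
    if (is.character(quantal)) quantal <- read_quantal_csv(quantal)
  }
  structure(list(mode = mode, solo = solo, mixtures = mixtures,
                 quantal = quantal, designs = designs, alpha = alpha,
                 seed = seed),
            class = "study_config")
}

#' Read a mixture-design configuration (JSON or YAML)
#'
#' @param path File path; format chosen by extension (`.json` vs
#'   `.yml`/`.yaml`).
#' @return List with elements `designs` (list of design specs) and optionally
#'   `alpha`.
#' @export
read_design_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (is.null(cfg$designs)) stop("config has no 'designs' entry", call. = FALSE)
  cfg
}

# Resolve potency estimates for every drug a study needs.
resolve_potencies <- function(config) {
  if (config$mode == "summary") {
    solo <- config$solo
    ests <- lapply(seq_len(nrow(solo)), function(i) {
      potency_estimate(solo$ed50[i],
                       sem = suppressWarnings(as.numeric(solo$sem[i])),
                       n = solo$n[i], drug = solo$drug[i])
    })
    names(ests) <- solo$drug
    ests
  } else {
    fits <- lapply(config$quantal, fit_log_probit)
    names(fits) <- vapply(config$quantal, attr, character(1), "drug")
    fits
  }
}

lookup_potency <- function(potencies, drug, design_id) {
  if (!drug %in% names(potencies)) {
    stop("design '", design_id, "': no potency source for drug '", drug, "'",
         call. = FALSE)
  }
  potencies[[drug]]
}

build_design <- function(spec, potencies) {
  varied <- lookup_potency(potencies, spec$varied, spec$id)
  if (is.data.frame(spec$adjuncts)) {
    spec$adjuncts <- split(spec$adjuncts, seq_len(nrow(spec$adjuncts)))
  }
  adj <- do.call(rbind, lapply(spec$adjuncts, function(a) {
    p <- lookup_potency(potencies, a$drug, spec$id)
    data.frame(drug = a$drug, dose = a$dose, ed50 = p$ed50, sem = p$sem,
               n = p$n_probit)
  }))
  mixture_design(varied, adj,
                 pool_adjuncts_on = spec$pool_adjuncts_on, id = spec$id)
}

# Experimental mixture potency for one design, from either the summary table
# or a refit of the raw mixture curve (labelled by design id).
resolve_experimental <- function(config, spec, design, potencies) {
  fixed <- design$adjuncts$dose
  if (config$mode == "summary") {
    row <- config$mixtures[config$mixtures$combination == spec$id, ]
    if (nrow(row) != 1) {
      stop("design '", spec$id, "': no matching row in the mixture summary ",
           "table", call. = FALSE)
    }
    varied_mix <- potency_estimate(row$ed50_exp_total - sum(fixed),
                                   sem = row$sem_exp, n = row$n_exp,
                                   drug = spec$varied)
    list(exp = experimental_mixture_ed50(varied_mix, fixed), printed = row)
  } else {
    if (!spec$id %in% names(config$quantal)) {
      stop("design '", spec$id, "': no raw mixture dataset with that label",
           call. = FALSE)
    }
    fit <- fit_log_probit(config$quantal[[spec$id]])
    list(exp = experimental_mixture_ed50(fit, fixed), printed = NULL)
  }
}

significance_marker <- function(p) {
  if (p < 0.001) "***" else if (p < 0.05) "*" else ""
}

#' Run the full isobolographic interaction study
#'
#' For every design: resolves (summary mode) or fits (raw mode) the component
#' potencies, computes the experimental and theoretical additive mixture
#' ED50s, the Welch interaction test and classification, the per-drug
#' fraction breakdown, the percent change of the varied drug's ED50 versus
#' its solo value, and isobologram coordinates. In summary mode, printed
#' `sem_add`/`n_add` columns (when present) replace the delta-method SEM and
#' derived count in the interaction test, since published additive SEMs
#' cannot be recomputed without the component dispersions.
#'
#' @param config A [study_config].
#' @return A `study_report`: `potencies` (data frame), `table` (one row per
#'   design with the publication-style columns), `details` (per-design list
#'   of the underlying objects and operands), `coordinates` (long data frame
#'   of isobologram series) and `log`.
#' @examples
#' report <- run_study(isop_study_config())
#' report$table[, c("combination", "t", "df", "classification")]
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  potencies <- resolve_potencies(config)
  report <- list(potencies = potency_table(potencies))
  details <- list()
  rows <- list()
  coords <- list()
  for (spec in config$designs) {
    design <- build_design(spec, potencies)
    add <- additive_ed50(design)
    res <- resolve_experimental(config, spec, design, potencies)
    exp <- res$exp
    if (!is.null(res$printed)) {
      if ("sem_add" %in% names(res$printed) &&
          is.finite(res$printed$sem_add)) add$sem_add <- res$printed$sem_add
      if ("n_add" %in% names(res$printed) &&
          is.finite(res$printed$n_add)) add$n_add <- res$printed$n_add
    }
    inter <- classify_interaction(exp, add, alpha = config$alpha)
    fb <- fraction_breakdown(exp, design)
    pct <- percent_change(design$varied$ed50, exp$ed50_exp_varied)
    co <- isobologram_coordinates(design, add, exp)
    rows[[spec$id]] <- data.frame(
      combination = spec$id,
      ed50_exp = exp$ed50_exp_total, sem_exp = exp$sem_exp, n_exp = exp$n_exp,
      ed50_add = add$ed50_add_total, sem_add = add$sem_add, n_add = add$n_add,
      t = inter$t_statistic, df = inter$df, p = inter$p_value,
      marker = significance_marker(inter$p_value),
      classification = inter$classification,
      fractions = paste(sprintf("%.2f", fb$fractions$fraction),
                        collapse = " + "),
      sum_of_fractions = fb$fraction_index,
      pct_change_vs_solo = pct)
    details[[spec$id]] <- list(
      design = design, additive = add, experimental = exp,
      interaction = inter, fractions = fb, pct_change_vs_solo = pct,
      operands = list(
        ed50_varied_solo = design$varied$ed50,
        adjuncts = design$adjuncts,
        pooled_for_additivity = additive_adjuncts(design),
        ed50_exp_total = exp$ed50_exp_total, sem_exp = exp$sem_exp,
        n_exp = exp$n_exp, ed50_add_total = add$ed50_add_total,
        sem_add = add$sem_add, n_add = add$n_add, alpha = config$alpha))
    co$combination <- spec$id
    coords[[spec$id]] <- co
  }
  report$table <- if (length(rows) > 0) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else NULL
  report$details <- details
  report$coordinates <- if (length(coords) > 0) {
    out <- do.call(rbind, coords)
    rownames(out) <- NULL
    out
  } else NULL
  report$log <- list(mode = config$mode, alpha = config$alpha,
                     seed = config$seed, n_designs = length(config$designs),
                     package_version = as.character(
                       utils::packageVersion("quantiso")),
                     timestamp = format(Sys.time(), tz = "UTC"))
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Isobolographic study report (", x$log$mode, " mode, alpha = ",
      x$log$alpha, ")\n\n", sep = "")
  cat("Potencies:\n")
  print(x$potencies, digits = 4)
  if (!is.null(x$table)) {
    cat("\nInteractions:\n")
    show <- x$table[, c("combination", "ed50_exp", "ed50_add", "t", "df", "p",
                        "classification", "sum_of_fractions")]
    print(show, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `potency.csv`, `interaction_table.csv`,
#' `isobologram_coordinates.csv` and a traceable `report.json` carrying every
#' derived cell together with the operands it was computed from.
#'
#' @param report A `study_report` from [run_study].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$potencies, file.path(dir, "potency.csv"),
                   row.names = FALSE)
  if (!is.null(report$table)) {
    utils::write.csv(report$table, file.path(dir, "interaction_table.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$coordinates)) {
    utils::write.csv(report$coordinates,
                     file.path(dir, "isobologram_coordinates.csv"),
                     row.names = FALSE)
  }
  json <- list(log = report$log, potencies = report$potencies,
               table = report$table,
               operands = lapply(report$details, `[[`, "operands"))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Bundled study fixtures
#'
#' Accessors for the packaged summary-mode fixtures: solo potencies, the
#' printed two- and three-drug mixture summaries, and the matching design
#' configuration. The borneol solo ED50 is not published; the bundled value
#' (250 mg/kg, flagged `inferred` in `solo_potency.csv`) is back-calculated
#' from its printed dose fraction, while the three-drug designs pool the
#' adjunct doses onto the coumarin's solo curve for the additive prediction,
#' mirroring the published additive values.
#'
#' @return `isop_study_solo()` and `isop_study_summary()` return data frames;
#'   `isop_study_designs()` the design list; `isop_study_config()` a ready
#'   [study_config] for the bundled study.
#' @export
isop_study_solo <- function() {
  utils::read.csv(system.file("extdata", "solo_potency.csv",
                              package = "quantiso"))
}

#' @rdname isop_study_solo
#' @export
isop_study_summary <- function() {
  utils::read.csv(system.file("extdata", "table1_table2_summary.csv",
                              package = "quantiso"),
                  check.names = TRUE)
}

#' @rdname isop_study_solo
#' @export
isop_study_designs <- function() {
  read_design_config(system.file("extdata", "study_designs.json",
                                 package = "quantiso"))
}

#' @rdname isop_study_solo
#' @export
isop_study_config <- function() {
  cfg <- isop_study_designs()
  study_config(mode = "summary", solo = isop_study_solo(),
               mixtures = isop_study_summary(), designs = cfg$designs,
               alpha = if (is.null(cfg$alpha)) 0.05 else cfg$alpha)
}
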