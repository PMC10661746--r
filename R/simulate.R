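#' Protection probability under the log-probit model
#'
#' `p(d) = pnorm(slope * (log10(d) - log10(ed50)))`: the probability that an
#' animal given dose `d` is protected, for a curve with the given median
#' effective dose and probit slope.
#'
#' @param dose Dose(s), mg/kg (> 0).
#' @param ed50 True median effective dose, mg/kg.
#' @param slope Probit slope, probits per log10(dose) (> 0).
#' @return Protection probabilities in (0, 1).
#' @export
protection_probability <- function(dose, ed50, slope) {
  stopifnot(all(dose > 0), ed50 > 0, slope > 0)
  stats::pnorm(slope * (log10(dose) - log10(ed50)))
}

#' Configure a quantal simulation
#'
#' Ground-truth settings for synthetic maximal-electroshock-style quantal
#' experiments: a log-probit protection curve sampled at the given doses with
#' binomial group outcomes. Group size defaults to 8 animals, the usual size
#' in this assay. For mixtures, `adjuncts` holds the fixed co-administered
#' doses with their solo ED50s, and `interaction_factor` multiplies the
#' Loewe-equivalent dose: 1 is exact additivity, > 1 synergy, < 1 antagonism.
#'
#' @param ed50_true True ED50 of the varied drug, mg/kg.
#' @param slope_true True probit slope (> 0), probits per log10(dose).
#' @param doses Dose grid for the varied drug, mg/kg.
#' @param n_per_group Animals per dose group (default 8).
#' @param seed Integer seed; a dataset is deterministic given the full config.
#' @param interaction_factor Potency multiplier on the equivalent dose
#'   (default 1 = additive).
#' @param adjuncts Optional data frame with columns `dose` and `ed50` (and
#'   optionally `drug`) describing fixed-dose adjuncts.
#' @param drug Label for the simulated drug or mixture.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(ed50_true, slope_true, doses, n_per_group = 8,
                              seed = 20231011, interaction_factor = 1,
                              adjuncts = NULL, drug = "sim") {
  stopifnot(ed50_true > 0, slope_true > 0, all(doses > 0),
            n_per_group >= 1, interaction_factor > 0)
  if (!is.null(adjuncts)) {
    adjuncts <- as.data.frame(adjuncts)
    stopifnot(all(c("dose", "ed50") %in% names(adjuncts)),
              all(adjuncts$dose >= 0), all(adjuncts$ed50 > 0))
  }
  structure(list(ed50_true = ed50_true, slope_true = slope_true,
                 doses = as.numeric(doses),
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed),
                 interaction_factor = interaction_factor,
                 adjuncts = adjuncts, drug = drug),
            class = "simulation_config")
}

#' Simulate a single-drug quantal dose-response experiment
#'
#' Draws `n_protected ~ Binomial(n_per_group, p(d))` at each dose, with
#' `p(d)` from [protection_probability] at the configured ground truth.
#' Deterministic given the config (including its seed); the caller's RNG
#' state is untouched.
#'
#' @param config A [simulation_config] without adjuncts.
#' @return A [quantal_data] dataset; ground truth is attached as attribute
#'   `truth`.
#' @examples
#' cfg <- simulation_config(250, 3, c(100, 180, 250, 400, 600), seed = 7)
#' simulate_quantal(cfg)
#' @export
simulate_quantal <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$adjuncts)) {
    stop("config has adjuncts; use simulate_mixture()", call. = FALSE)
  }
  p <- protection_probability(config$doses, config$ed50_true,
                              config$slope_true)
  draw_quantal(config, p)
}

#' Simulate a fixed-dose mixture quantal experiment
#'
#' Each varied-drug dose `d` is converted to its Loewe-equivalent solo dose
#' `d_eq = d + sum_i ed50_true * dose_i / ed50_i` (adjunct doses expressed in
#' varied-drug units through the ratio of solo ED50s), and protection follows
#' the solo curve at `interaction_factor * d_eq`. With factor 1 the mixture
#' is exactly additive by construction; factors above 1 make the mixture more
#' potent than additivity predicts (synergy), below 1 less (antagonism).
#'
#' @param config A [simulation_config] with `adjuncts`; the adjunct
#'   ED50-fraction sum must be below 1.
#' @return A [quantal_data] dataset with attribute `truth`.
#' @export
simulate_mixture <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  adj <- config$adjuncts
  if (is.null(adj)) stop("config has no adjuncts", call. = FALSE)
  if (sum(adj$dose / adj$ed50) >= 1) {
    stop("adjunct ED50-fractions sum to >= 1", call. = FALSE)
  }
  d_eq <- config$doses + sum(config$ed50_true * adj$dose / adj$ed50)
  p <- stats::pnorm(config$slope_true *
                    (log10(config$interaction_factor * d_eq) -
                     log10(config$ed50_true)))
  draw_quantal(config, p)
}

draw_quantal <- function(config, p) {
  n_prot <- with_local_seed(config$seed,
                            stats::rbinom(length(p), config$n_per_group, p))
  out <- quantal_data(config$doses, n_prot,
                      rep(config$n_per_group, length(p)), drug = config$drug)
  attr(out, "truth") <- config
  out
}

#' Write a quantal dataset (or several) to raw-mode CSV
#'
#' Emits the canonical header `drug,dose_mg_kg,n_protected,n_total`. When a
#' dataset carries simulation ground truth, a JSON sidecar
#' (`<path>.truth.json`) records the generating parameters.
#'
#' @param data A [quantal_data] object or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_quantal_csv <- function(data, path) {
  if (inherits(data, "quantal_data")) data <- list(data)
  rows <- do.call(rbind, lapply(data, function(d) {
    data.frame(drug = attr(d, "drug"), dose_mg_kg = d$dose,
               n_protected = d$n_protected, n_total = d$n_total)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  truths <- Filter(Negate(is.null), lapply(data, attr, "truth"))
  if (length(truths) > 0) {
    sidecar <- lapply(truths, function(tr) {
      tr <- unclass(tr)
      tr$adjuncts <- if (is.null(tr$adjuncts)) NULL else as.list(tr$adjuncts)
      tr
    })
    names(sidecar) <- vapply(truths, function(tr) tr$drug, character(1))
    jsonlite::write_json(sidecar, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
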