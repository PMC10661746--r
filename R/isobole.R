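# Round half away from zero; stats::round() rounds half to even, which does
# not reproduce published 2-decimal fraction arithmetic.
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Define a fixed-dose mixture design
#'
#' One drug's dose varies while the co-administered adjuncts are held at
#' constant doses (a fixed-dose "ray" design). Each component carries its
#' solo ED50 so that doses can be expressed as fractions of solo potency
#' (Loewe dose equivalence).
#'
#' @param varied A [potency_estimate] for the varied drug alone.
#' @param adjuncts Data frame with columns `drug`, `dose` (fixed dose, mg/kg),
#'   `ed50` (that drug's solo ED50), and optionally `sem` and `n`.
#' @param pool_adjuncts_on Optional drug label: when set, the additive
#'   prediction treats the total adjunct dose as a single adjunct acting on
#'   that drug's solo curve (its `ed50`/`sem`/`n` row), while per-drug
#'   fractions still use each adjunct's own solo ED50. Used when adjuncts are
#'   assumed dose-equivalent to one reference component.
#' @param id Design label; defaults to "varied + adj1 (dose1) + ...".
#' @return A `mixture_design` object.
#' @examples
#' cbz <- potency_estimate(9.52, drug = "CBZ")
#' mixture_design(cbz, data.frame(drug = "ISOP", dose = 25, ed50 = 235.7))
#' @export
mixture_design <- function(varied, adjuncts, pool_adjuncts_on = NULL,
                           id = NULL) {
  stopifnot(inherits(varied, "potency_estimate"))
  adjuncts <- as.data.frame(adjuncts)
  stopifnot(all(c("drug", "dose", "ed50") %in% names(adjuncts)))
  if (!"sem" %in% names(adjuncts)) {
    adjuncts$sem <- rep(NA_real_, nrow(adjuncts))
  }
  if (!"n" %in% names(adjuncts)) adjuncts$n <- rep(NA_integer_, nrow(adjuncts))
  if (nrow(adjuncts) > 0 &&
      (any(adjuncts$dose <= 0) || any(adjuncts$ed50 <= 0))) {
    stop("adjunct doses and solo ED50s must be positive", call. = FALSE)
  }
  if (sum(adjuncts$dose / adjuncts$ed50) >= 1) {
    stop("adjunct ED50-fractions sum to >= 1: the fixed doses alone reach ",
         "the additive ED50", call. = FALSE)
  }
  if (!is.null(pool_adjuncts_on) &&
      !pool_adjuncts_on %in% adjuncts$drug) {
    stop("pool_adjuncts_on must name one of the adjunct drugs", call. = FALSE)
  }
  if (is.null(id)) {
    id <- paste(c(varied$drug,
                  sprintf("%s (%g)", adjuncts$drug, adjuncts$dose)),
                collapse = " + ")
  }
  structure(list(varied = varied, adjuncts = adjuncts,
                 pool_adjuncts_on = pool_adjuncts_on, id = id),
            class = "mixture_design")
}

# Adjunct table actually used for the additive prediction: either the per-drug
# rows, or the total dose pooled onto one reference component's solo curve.
additive_adjuncts <- function(design) {
  adj <- design$adjuncts
  if (is.null(design$pool_adjuncts_on) || nrow(adj) < 2) return(adj)
  ref <- adj[match(design$pool_adjuncts_on, adj$drug), ]
  data.frame(drug = paste(adj$drug, collapse = "+"),
             dose = sum(adj$dose), ed50 = ref$ed50, sem = ref$sem, n = ref$n)
}

#' Theoretical additive ED50 of a fixed-dose mixture
#'
#' Loewe dose equivalence with fixed adjunct doses: the varied drug's
#' additive-component ED50 is its solo ED50 scaled by the potency fraction the
#' adjuncts leave unused, `ED50_varied * (1 - sum_i dose_i / ED50_i)`, and the
#' additive total is that component plus all fixed doses. The prediction's SEM
#' is propagated by the delta method,
#' `Var_add = (1 - sum f_i)^2 Var(ED50_varied) +
#'  sum_i (ED50_varied dose_i / ED50_i^2)^2 Var(ED50_i)`
#' (terms with unknown component SEMs drop to `NA`), and `n_add` is the sum of
#' probit-window counts over the solo curves entering the calculation.
#'
#' @param design A [mixture_design].
#' @return An `additive_prediction` with fields `ed50_add_total`,
#'   `ed50_add_varied`, `sem_add`, `n_add`.
#' @examples
#' cbz <- potency_estimate(9.52, drug = "CBZ")
#' d <- mixture_design(cbz, data.frame(drug = "ISOP", dose = 25, ed50 = 235.7))
#' additive_ed50(d)   # total 33.51 mg/kg
#' @export
additive_ed50 <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  adj <- additive_adjuncts(design)
  ed50_v <- design$varied$ed50
  frac <- if (nrow(adj) > 0) adj$dose / adj$ed50 else numeric(0)
  fsum <- sum(frac)
  ed50_add_varied <- ed50_v * (1 - fsum)
  ed50_add_total <- ed50_add_varied + sum(adj$dose)
  var_v <- design$varied$sem^2
  var_adj <- if (nrow(adj) > 0) {
    sum((ed50_v * adj$dose / adj$ed50^2)^2 * adj$sem^2)
  } else 0
  sem_add <- sqrt((1 - fsum)^2 * ifelse(is.finite(var_v), var_v, NA_real_) +
                  var_adj)
  n_add <- design$varied$n_probit + sum(adj$n)
  structure(list(ed50_add_total = ed50_add_total,
                 ed50_add_varied = ed50_add_varied,
                 sem_add = sem_add, n_add = as.integer(n_add),
                 design_id = design$id),
            class = "additive_prediction")
}

#' @export
print.additive_prediction <- function(x, ...) {
  cat(sprintf("Additive ED50 [%s]: total %.2f mg/kg (varied component %.2f)",
              x$design_id, x$ed50_add_total, x$ed50_add_varied))
  if (is.finite(x$sem_add)) cat(sprintf(" +/- %.2f", x$sem_add))
  if (!is.na(x$n_add)) cat(sprintf(", n = %d", x$n_add))
  cat("\n")
  invisible(x)
}

#' Experimental total-mixture ED50
#'
#' Converts the varied drug's ED50, refit in the presence of the fixed-dose
#' adjuncts, to the total-mixture scale by adding the fixed doses. Fixed doses
#' carry no variance, so the SEM is that of the mixture fit unchanged.
#'
#' @param varied_in_mixture [potency_estimate] of the varied drug fitted with
#'   the adjuncts co-administered.
#' @param fixed_doses Numeric vector of the fixed adjunct doses, mg/kg.
#' @return An `experimental_mixture` with `ed50_exp_total`, `ed50_exp_varied`,
#'   `sem_exp`, `n_exp`.
#' @examples
#' pb_mix <- potency_estimate(26.17, sem = 2.07, n = 16, drug = "PB")
#' experimental_mixture_ed50(pb_mix, 25)   # total 51.17 mg/kg
#' @export
experimental_mixture_ed50 <- function(varied_in_mixture, fixed_doses = numeric(0)) {
  stopifnot(inherits(varied_in_mixture, "potency_estimate"))
  if (any(fixed_doses < 0)) stop("fixed doses must be >= 0", call. = FALSE)
  structure(list(ed50_exp_total = varied_in_mixture$ed50 + sum(fixed_doses),
                 ed50_exp_varied = varied_in_mixture$ed50,
                 sem_exp = varied_in_mixture$sem,
                 n_exp = varied_in_mixture$n_probit,
                 fixed_doses = fixed_doses),
            class = "experimental_mixture")
}

#' @export
print.experimental_mixture <- function(x, ...) {
  cat(sprintf("Experimental mixture ED50: total %.2f mg/kg (varied %.2f)",
              x$ed50_exp_total, x$ed50_exp_varied))
  if (is.finite(x$sem_exp)) cat(sprintf(" +/- %.2f", x$sem_exp))
  if (!is.na(x$n_exp)) cat(sprintf(", n = %d", x$n_exp))
  cat("\n")
  invisible(x)
}

#' Per-drug ED50 fractions and the fraction (interaction) index
#'
#' Expresses each component's dose at the mixture ED50 as a fraction of its
#' solo ED50: `ed50_exp_varied / ED50_varied` for the varied drug and
#' `dose_i / ED50_i` for each fixed adjunct. Fractions are rounded to two
#' decimals (half away from zero) before summing, matching how published
#' "sum of fractions" columns are assembled; the sum near 1 indicates
#' additivity, below 1 synergy, above 1 antagonism.
#'
#' @param mix An `experimental_mixture` (see [experimental_mixture_ed50]).
#' @param design The [mixture_design] holding the solo potencies.
#' @param digits Rounding for the printed fractions (default 2).
#' @return A `fraction_breakdown`: data frame `fractions` (`drug`, `fraction`,
#'   unrounded `fraction_raw`) plus `fraction_index` (sum of rounded
#'   fractions) and `fraction_index_raw`.
#' @export
fraction_breakdown <- function(mix, design, digits = 2) {
  stopifnot(inherits(mix, "experimental_mixture"),
            inherits(design, "mixture_design"))
  if (design$varied$ed50 <= 0 || any(design$adjuncts$ed50 <= 0)) {
    stop("solo ED50s must be positive", call. = FALSE)
  }
  raw <- c(mix$ed50_exp_varied / design$varied$ed50,
           design$adjuncts$dose / design$adjuncts$ed50)
  drugs <- c(design$varied$drug, design$adjuncts$drug)
  rounded <- round_half_away(raw, digits)
  structure(list(fractions = data.frame(drug = drugs, fraction = rounded,
                                        fraction_raw = raw),
                 fraction_index = sum(rounded),
                 fraction_index_raw = sum(raw),
                 design_id = design$id),
            class = "fraction_breakdown")
}

#' @export
print.fraction_breakdown <- function(x, ...) {
  cat(sprintf("Fraction index [%s]: %s = %.2f\n", x$design_id,
              paste(sprintf("%.2f", x$fractions$fraction), collapse = " + "),
              x$fraction_index))
  invisible(x)
}

#' Signed percent change of an ED50 versus control
#'
#' `round((control - treated) / control * 100)` to the nearest integer (half
#' away from zero); positive values are reductions in the ED50, i.e. a gain
#' in anticonvulsant potency.
#'
#' @param ed50_control Control ED50, mg/kg (> 0).
#' @param ed50_treated Treated ED50, mg/kg.
#' @return Integer signed percent.
#' @examples
#' percent_change(9.52, 7.32)   # 23
#' @export
percent_change <- function(ed50_control, ed50_treated) {
  if (any(!is.finite(ed50_control)) || any(ed50_control <= 0)) {
    stop("ed50_control must be positive", call. = FALSE)
  }
  as.integer(round_half_away((ed50_control - ed50_treated) /
                             ed50_control * 100))
}

#' Isobologram plotting coordinates
#'
#' Coordinates for the standard fixed-dose isobologram: the additivity line
#' joining the two solo ED50s, the vertical fixed-dose line, the theoretical
#' point of additivity A on that line, and the experimental point E. For a
#' single-adjunct (two-drug) design the X-axis is the adjunct dose; designs
#' with several adjuncts are collapsed onto one pooled-adjunct axis (total
#' fixed dose; pooled solo ED50 = total dose / sum of adjunct fractions), and
#' the returned object notes the pooling.
#'
#' @param design A [mixture_design].
#' @param add The [additive_ed50] prediction for that design.
#' @param exp The [experimental_mixture_ed50] result for that design.
#' @return Data frame with columns `series` (`additivity_line`,
#'   `fixed_dose_line`, `point_A`, `point_E`), `x` (adjunct dose, mg/kg) and
#'   `y` (varied-drug dose, mg/kg); attribute `pooling_note` when adjuncts
#'   were pooled.
#' @export
isobologram_coordinates <- function(design, add, exp) {
  stopifnot(inherits(design, "mixture_design"),
            inherits(add, "additive_prediction"),
            inherits(exp, "experimental_mixture"))
  adj <- design$adjuncts
  ed50_v <- design$varied$ed50
  note <- NULL
  if (nrow(adj) == 0) {
    x_dose <- 0
    x_ed50 <- 0
  } else if (nrow(adj) == 1) {
    x_dose <- adj$dose
    x_ed50 <- adj$ed50
  } else {
    x_dose <- sum(adj$dose)
    x_ed50 <- x_dose / sum(adj$dose / adj$ed50)
    note <- sprintf("adjuncts %s pooled onto one axis (total dose %g mg/kg, pooled solo ED50 %.4g mg/kg)",
                    paste(adj$drug, collapse = " + "), x_dose, x_ed50)
  }
  out <- rbind(
    data.frame(series = "additivity_line", x = c(0, x_ed50), y = c(ed50_v, 0)),
    data.frame(series = "fixed_dose_line", x = c(x_dose, x_dose),
               y = c(0, ed50_v)),
    data.frame(series = "point_A", x = x_dose, y = add$ed50_add_varied),
    data.frame(series = "point_E", x = x_dose, y = exp$ed50_exp_varied))
  attr(out, "pooling_note") <- note
  out
}
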