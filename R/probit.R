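#' Probit transform of a response proportion
#'
#' Maps a proportion to the classical probit scale: the standard-normal
#' quantile plus 5, so that a 50% response sits at the 5th probit and the
#' "4th--6th probit" window spans the 15.87--84.13% response range.
#'
#' @param p Numeric vector of proportions, each strictly inside (0, 1).
#' @return Numeric vector of probit values (`qnorm(p) + 5`).
#' @examples
#' probit_transform(0.5)            # 5
#' probit_transform(pnorm(1))       # 6
#' @export
probit_transform <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("'p' must be strictly inside (0, 1)", call. = FALSE)
  }
  stats::qnorm(p) + 5
}

#' Construct a quantal dose-response dataset
#'
#' One row per dose group: dose administered, animals protected (quantal
#' "success"), animals tested. Doses are mg/kg throughout.
#'
#' @param dose Positive numeric vector of doses (mg/kg).
#' @param n_protected Non-negative integer vector, animals protected.
#' @param n_total Positive integer vector, animals tested per group.
#' @param drug Single character label for the drug or mixture.
#' @param pretreatment_min Optional pretreatment time in minutes (metadata).
#' @return A `quantal_data` data frame with columns `dose`, `n_protected`,
#'   `n_total` and attributes `drug` and `pretreatment_min`.
#' @examples
#' quantal_data(c(6, 16), c(2, 6), c(8, 8), drug = "CBZ")
#' @export
quantal_data <- function(dose, n_protected, n_total, drug = "drug",
                         pretreatment_min = NULL) {
  stopifnot(length(dose) == length(n_protected),
            length(dose) == length(n_total))
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    stop("all doses must be positive and finite", call. = FALSE)
  }
  if (any(n_total < 1) || any(n_protected < 0) || any(n_protected > n_total)) {
    stop("counts must satisfy 0 <= n_protected <= n_total, n_total >= 1",
         call. = FALSE)
  }
  out <- data.frame(dose = as.numeric(dose),
                    n_protected = as.integer(n_protected),
                    n_total = as.integer(n_total))
  out <- out[order(out$dose), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drug") <- as.character(drug)[1]
  attr(out, "pretreatment_min") <- pretreatment_min
  class(out) <- c("quantal_data", "data.frame")
  out
}

#' @export
print.quantal_data <- function(x, ...) {
  cat("Quantal dose-response data:", attr(x, "drug"), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

# Collapse duplicate doses by summing counts; duplicate rows are never an error.
aggregate_doses <- function(data) {
  if (anyDuplicated(data$dose)) {
    agg <- stats::aggregate(cbind(n_protected, n_total) ~ dose,
                            data = as.data.frame(data), FUN = sum)
    data <- quantal_data(agg$dose, agg$n_protected, agg$n_total,
                         drug = attr(data, "drug"),
                         pretreatment_min = attr(data, "pretreatment_min"))
  }
  data
}

#' Read quantal dose-group data from CSV
#'
#' Expects the exact header `drug,dose_mg_kg,n_protected,n_total`, UTF-8,
#' one row per dose group. Returns one `quantal_data` object per drug.
#'
#' @param path Path to the CSV file.
#' @return Named list of [quantal_data] objects, one per drug label.
#' @export
read_quantal_csv <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  expected <- c("drug", "dose_mg_kg", "n_protected", "n_total")
  if (!identical(header, expected)) {
    stop("invalid CSV header: expected '", paste(expected, collapse = ","),
         "' but found '", paste(header, collapse = ","), "'", call. = FALSE)
  }
  raw <- utils::read.csv(path, fileEncoding = "UTF-8")
  split_rows <- split(raw, raw$drug)
  lapply(split_rows, function(d) {
    quantal_data(d$dose_mg_kg, d$n_protected, d$n_total, drug = d$drug[1])
  })
}

#' Construct a potency estimate (ED50 with dispersion)
#'
#' Container for a median effective dose with its SEM, 95% confidence limits,
#' probit-regression slope and the probit-window animal count. Used both for
#' fitted curves (see [fit_log_probit]) and for ingesting published summary
#' values, in which case only `ed50`, `sem` and `n` need be supplied.
#'
#' @param ed50 Median effective dose, mg/kg (> 0).
#' @param sem Standard error of the ED50, mg/kg (>= 0, or `NA` if unknown).
#' @param n Animal count in the 4th--6th probit window (`n_probit`).
#' @param cl95_lower,cl95_upper Optional 95% confidence limits, mg/kg.
#' @param slope Optional probit-regression slope, probits per log10(dose).
#' @param converged Logical fit-convergence flag.
#' @param se_log10 Optional standard error of log10(ED50); derived from `sem`
#'   when absent.
#' @param drug Drug label.
#' @return An object of class `potency_estimate`.
#' @examples
#' potency_estimate(235.7, sem = 23.5, n = 24, drug = "ISOP")
#' @export
potency_estimate <- function(ed50, sem = NA_real_, n = NA_integer_,
                             cl95_lower = NA_real_, cl95_upper = NA_real_,
                             slope = NA_real_, converged = TRUE,
                             se_log10 = NULL, drug = "drug") {
  ed50 <- unname(ed50); sem <- unname(sem); n <- unname(n)
  cl95_lower <- unname(cl95_lower); cl95_upper <- unname(cl95_upper)
  slope <- unname(slope)
  if (!is.finite(ed50) || ed50 <= 0) stop("ed50 must be positive", call. = FALSE)
  if (is.finite(sem) && sem < 0) stop("sem must be >= 0", call. = FALSE)
  if (is.finite(cl95_lower) && is.finite(cl95_upper) &&
      !(cl95_lower <= ed50 && ed50 <= cl95_upper)) {
    stop("confidence limits must bracket the ED50", call. = FALSE)
  }
  if (is.null(se_log10)) {
    se_log10 <- if (is.finite(sem)) sem / (ed50 * log(10)) else NA_real_
  }
  structure(list(drug = drug, ed50 = ed50, sem = sem,
                 cl95_lower = cl95_lower, cl95_upper = cl95_upper,
                 slope = slope, n_probit = as.integer(n),
                 converged = isTRUE(converged), se_log10 = se_log10),
            class = "potency_estimate")
}

#' @export
print.potency_estimate <- function(x, ...) {
  cat(sprintf("ED50 [%s] = %.4g mg/kg", x$drug, x$ed50))
  if (is.finite(x$sem)) cat(sprintf(" +/- %.4g (SEM)", x$sem))
  if (is.finite(x$cl95_lower)) {
    cat(sprintf(", 95%% CL [%.4g, %.4g]", x$cl95_lower, x$cl95_upper))
  }
  if (!is.na(x$n_probit)) cat(sprintf(", n = %d", x$n_probit))
  if (!x$converged) cat("  [NOT CONVERGED]")
  cat("\n")
  invisible(x)
}

# TRUE when a dose threshold perfectly splits all-0% from all-100% groups,
# which sends the ML slope to infinity.
is_completely_separated <- function(data) {
  f <- data$n_protected / data$n_total
  m <- nrow(data)
  for (k in seq_len(m - 1)) {
    if (all(f[seq_len(k)] == 0) && all(f[(k + 1):m] == 1)) return(TRUE)
  }
  FALSE
}

#' Fit a log-probit dose-response curve
#'
#' Maximum-likelihood probit regression of the protected fraction on
#' log10(dose) (iteratively reweighted least squares, convergence tolerance
#' 1e-10, at most 100 iterations). The ED50 is the dose at which the fitted
#' line crosses the 5th probit (50% response); its standard error comes from
#' the delta method on the log10 scale via [MASS::dose.p], so
#' `sem = ed50 * ln(10) * SE(log10 ED50)` and the 95% confidence limits are
#' `ed50 * 10^(+/- 1.96 SE(log10 ED50))`. Groups at 0% or 100% protection are
#' retained in the likelihood; duplicate doses are aggregated first.
#'
#' @param data A [quantal_data] object with at least two distinct doses.
#' @return A [potency_estimate]. When a dose threshold perfectly separates
#'   all-0% from all-100% groups the estimate is flagged `converged = FALSE`
#'   with `slope = Inf` and `NA` dispersion (ED50 set to the geometric
#'   midpoint of the two doses flanking the split), and a warning is issued.
#' @examples
#' d <- quantal_data(c(6, 16), c(2, 6), c(8, 8), drug = "CBZ")
#' fit_log_probit(d)   # ED50 = sqrt(6 * 16) = 9.798 mg/kg
#' @seealso [count_probit_window_n], [sem_from_cl]
#' @export
fit_log_probit <- function(data) {
  stopifnot(inherits(data, "quantal_data"))
  data <- aggregate_doses(data)
  if (nrow(data) < 2) {
    stop("need at least 2 distinct doses to fit", call. = FALSE)
  }
  f <- data$n_protected / data$n_total
  if (all(f == 0) || all(f == 1)) {
    stop("non-estimable: all groups at ", if (all(f == 0)) "0%" else "100%",
         " protection", call. = FALSE)
  }
  nwin <- count_probit_window_n(data)
  if (is_completely_separated(data)) {
    k <- max(which(f == 0))
    mid <- sqrt(data$dose[k] * data$dose[k + 1])
    warning("complete separation: a dose threshold perfectly splits 0% from ",
            "100% groups; slope is infinite and the ED50 is not identified ",
            "beyond the interval (", data$dose[k], ", ", data$dose[k + 1], ")",
            call. = FALSE)
    return(potency_estimate(mid, sem = NA_real_, n = nwin, slope = Inf,
                            converged = FALSE, drug = attr(data, "drug")))
  }
  x <- log10(data$dose)
  fit <- suppressWarnings(stats::glm(
    cbind(n_protected, n_total - n_protected) ~ x,
    family = stats::binomial(link = "probit"),
    data = cbind(as.data.frame(data), x = x),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  dp <- MASS::dose.p(fit, p = 0.5)
  log10_ed50 <- as.numeric(dp)
  se_log10 <- as.numeric(attr(dp, "SE"))
  ed50 <- 10^log10_ed50
  sem <- ed50 * log(10) * se_log10
  potency_estimate(ed50, sem = sem, n = nwin,
                   cl95_lower = ed50 * 10^(-1.96 * se_log10),
                   cl95_upper = ed50 * 10^(+1.96 * se_log10),
                   slope = unname(stats::coef(fit)[2]),
                   converged = fit$converged, se_log10 = se_log10,
                   drug = attr(data, "drug"))
}

#' Animal count within the 4th--6th probit window
#'
#' Sums `n_total` over the dose groups whose observed protected fraction lies
#' in the 4th--6th probit window, i.e. between `pnorm(-1)` and `pnorm(1)`
#' (15.87%--84.13%, inclusive). This is the `n` reported alongside ED50s in
#' the study tables.
#'
#' @param data A [quantal_data] object.
#' @return Integer animal count (0 when no group falls in the window).
#' @export
count_probit_window_n <- function(data) {
  stopifnot(inherits(data, "quantal_data"))
  f <- data$n_protected / data$n_total
  tol <- 1e-9
  inside <- f >= stats::pnorm(-1) - tol & f <= stats::pnorm(1) + tol
  as.integer(sum(data$n_total[inside]))
}

#' SEM from 95% confidence limits
#'
#' The published transformation of a 95% confidence interval into a standard
#' error of the mean: `sem = (upper - lower) / (2 * 1.96)`, used to attach a
#' SEM to literature ED50s reported only with confidence limits.
#'
#' @param cl95_lower,cl95_upper Confidence limits, mg/kg,
#'   `0 <= cl95_lower <= cl95_upper`.
#' @return SEM in mg/kg.
#' @examples
#' sem_from_cl(200, 278.4)   # 20
#' @export
sem_from_cl <- function(cl95_lower, cl95_upper) {
  if (any(cl95_lower < 0) || any(cl95_upper < cl95_lower)) {
    stop("require 0 <= cl95_lower <= cl95_upper", call. = FALSE)
  }
  (cl95_upper - cl95_lower) / (2 * 1.96)
}

#' Export potency estimates as a data frame
#'
#' @param estimates A list of [potency_estimate] objects.
#' @return Data frame with one row per drug: `drug`, `ed50`, `sem`,
#'   `cl95_lower`, `cl95_upper`, `slope`, `n_probit`, `converged`.
#' @export
potency_table <- function(estimates) {
  if (inherits(estimates, "potency_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(drug = e$drug, ed50 = e$ed50, sem = e$sem,
               cl95_lower = e$cl95_lower, cl95_upper = e$cl95_upper,
               slope = e$slope, n_probit = e$n_probit, converged = e$converged)
  }))
}
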