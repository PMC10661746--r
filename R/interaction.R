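#' Welch's t-test for two independent estimates
#'
#' Unequal-variance comparison of two summary estimates given as value, SEM
#' and animal count: `t = |v1 - v2| / sqrt(sem1^2 + sem2^2)` with
#' Welch--Satterthwaite degrees of freedom
#' `(sem1^2 + sem2^2)^2 / (sem1^4/(n1-1) + sem2^4/(n2-1))` rounded to the
#' nearest integer, and a two-sided p-value from the t distribution on that
#' integer df. The statistic is reported as an absolute value.
#'
#' @param value1,sem1,n1 First estimate: value, SEM (>= 0) and count (>= 2).
#' @param value2,sem2,n2 Second estimate.
#' @return A `welch_test` list: `t`, `df` (integer), `df_raw`, `p`.
#' @examples
#' welch_t(218.9, 13.15, 24, 280.0, 8.19, 52)   # t = 3.944, df = 41
#' @export
welch_t <- function(value1, sem1, n1, value2, sem2, n2) {
  if (n1 < 2 || n2 < 2) stop("both counts must be >= 2", call. = FALSE)
  if (sem1 < 0 || sem2 < 0) stop("SEMs must be >= 0", call. = FALSE)
  v1 <- sem1^2
  v2 <- sem2^2
  if (v1 + v2 == 0) {
    if (value1 != value2) {
      stop("both SEMs are zero but the values differ: t is infinite",
           call. = FALSE)
    }
    return(structure(list(t = 0, df = as.integer(n1 + n2 - 2),
                          df_raw = n1 + n2 - 2, p = 1),
                     class = "welch_test"))
  }
  t_stat <- abs(value1 - value2) / sqrt(v1 + v2)
  df_raw <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  df <- as.integer(round(df_raw))
  structure(list(t = t_stat, df = df, df_raw = df_raw,
                 p = 2 * stats::pt(-t_stat, df)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t(%d) = %.3f, p = %.4g\n", x$df, x$t, x$p))
  invisible(x)
}

#' Classify a drug-mixture interaction
#'
#' Compares the experimental and additive total-mixture ED50s with [welch_t].
#' A significant difference (p < alpha, strict) with the experimental ED50
#' below the additive prediction is synergy (supra-additivity); above it,
#' antagonism (sub-additivity); otherwise the interaction is additive.
#'
#' @param exp An `experimental_mixture` (or list with `ed50_exp_total`,
#'   `sem_exp`, `n_exp`).
#' @param add An `additive_prediction` (or list with `ed50_add_total`,
#'   `sem_add`, `n_add`).
#' @param alpha Two-sided significance level (default 0.05).
#' @return An `interaction_result`: `t_statistic`, `df`, `p_value`,
#'   `classification` (one of `"synergistic"`, `"additive"`,
#'   `"antagonistic"`), `alpha`.
#' @examples
#' exp <- list(ed50_exp_total = 313.8, sem_exp = 10.15, n_exp = 32)
#' add <- list(ed50_add_total = 280.0, sem_add = 8.19, n_add = 52)
#' classify_interaction(exp, add)   # antagonistic
#' @export
classify_interaction <- function(exp, add, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  w <- welch_t(exp$ed50_exp_total, exp$sem_exp, exp$n_exp,
               add$ed50_add_total, add$sem_add, add$n_add)
  classification <- if (w$p < alpha) {
    if (exp$ed50_exp_total < add$ed50_add_total) "synergistic" else "antagonistic"
  } else "additive"
  structure(list(t_statistic = w$t, df = w$df, df_raw = w$df_raw,
                 p_value = w$p, classification = classification,
                 alpha = alpha),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("Interaction: %s (t(%d) = %.3f, p = %.4g, alpha = %g)\n",
              x$classification, x$df, x$t_statistic, x$p_value, x$alpha))
  invisible(x)
}

# Run body with a local RNG state; the caller's .Random.seed is untouched.
with_local_seed <- function(seed, body) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  body
}

#' Dunnett-style many-to-one comparison of potency estimates
#'
#' Compares each treatment ED50 against a shared control using the normal
#' statistic `z_i = |ed50_control - ed50_i| / sqrt(sem_control^2 + sem_i^2)`,
#' with family-wise adjustment by Monte-Carlo sampling of the joint null: the
#' comparisons share the control term, so null draws of
#' `(x_0, x_1, ..., x_k)` with the given SEMs give the distribution of the
#' maximum absolute statistic, and each adjusted p is the tail probability of
#' that maximum beyond the observed `z_i`. This approximates the classical
#' ANOVA-plus-Dunnett procedure for the case where only summary estimates
#' (value, SEM, n) are available, not raw replicates.
#'
#' @param control A [potency_estimate] (or list with `ed50` and `sem`).
#' @param treatments List of treatment estimates in the same form.
#' @param alpha Family-wise significance level (default 0.05).
#' @param draws Monte-Carlo draws for the joint null (default 1e5).
#' @param seed Seed for the Monte-Carlo sampler (default 1); the global RNG
#'   state is left untouched.
#' @return Data frame with one row per treatment: `drug`, `z`, `p_adjusted`,
#'   `significant`.
#' @export
dunnett_compare <- function(control, treatments, alpha = 0.05,
                            draws = 1e5, seed = 1) {
  if (inherits(treatments, "potency_estimate")) treatments <- list(treatments)
  if (length(treatments) < 1) {
    stop("at least one treatment is required", call. = FALSE)
  }
  sems <- vapply(treatments, function(e) e$sem, numeric(1))
  if (!is.finite(control$sem) || control$sem <= 0 ||
      any(!is.finite(sems)) || any(sems <= 0)) {
    stop("all SEMs must be positive for the Dunnett-style comparison",
         call. = FALSE)
  }
  vals <- vapply(treatments, function(e) e$ed50, numeric(1))
  denom <- sqrt(control$sem^2 + sems^2)
  z <- abs(control$ed50 - vals) / denom
  k <- length(z)
  max_t <- with_local_seed(seed, {
    x0 <- stats::rnorm(draws, sd = control$sem)
    tmat <- vapply(seq_len(k), function(i) {
      abs(x0 - stats::rnorm(draws, sd = sems[i])) / denom[i]
    }, numeric(draws))
    if (k == 1) as.numeric(tmat) else do.call(pmax, as.data.frame(tmat))
  })
  p_adj <- vapply(z, function(zi) mean(max_t >= zi), numeric(1))
  labels <- vapply(treatments, function(e) {
    if (!is.null(e$drug)) as.character(e$drug) else NA_character_
  }, character(1))
  data.frame(drug = labels, z = z, p_adjusted = p_adj,
             significant = p_adj < alpha)
}
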