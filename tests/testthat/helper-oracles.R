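# Independent brute-force oracle for the log-probit ML fit: profile the
# binomial log-likelihood over a (log10 ED50, slope) grid, refining twice.
# Never calls the package's fitting path.
brute_force_probit <- function(dose, n_protected, n_total,
                               log10_ed50_range = range(log10(dose)) + c(-1, 1),
                               slope_range = c(0.05, 30)) {
  loglik <- function(mu, b) {
    p <- pnorm(b * (log10(dose) - mu))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(n_protected * log(p) + (n_total - n_protected) * log(1 - p))
  }
  mu_grid <- seq(log10_ed50_range[1], log10_ed50_range[2], length.out = 201)
  b_grid <- seq(slope_range[1], slope_range[2], length.out = 201)
  for (pass in 1:3) {
    ll <- outer(mu_grid, b_grid, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    mu_step <- diff(mu_grid[1:2])
    b_step <- diff(b_grid[1:2])
    mu_best <- mu_grid[best[1]]
    b_best <- b_grid[best[2]]
    mu_grid <- seq(mu_best - 2 * mu_step, mu_best + 2 * mu_step,
                   length.out = 81)
    b_grid <- seq(max(b_best - 2 * b_step, 1e-3), b_best + 2 * b_step,
                  length.out = 81)
  }
  list(log10_ed50 = mu_best, ed50 = 10^mu_best, slope = b_best)
}

# Printed summary rows of the study's two interaction tables, frozen here
# independently of the packaged fixture files: experimental and additive
# total-mixture ED50s (mg/kg +/- SEM) with probit-window counts, the
# published Welch statistics, and the published per-drug fraction sums.
printed_interaction_rows <- function() {
  read.csv(text = 'combination,varied,isop_dose,bor_dose,ed50_exp,sem_exp,n_exp,ed50_add,sem_add,n_add,t,df,p,fractions,sum_frac
CBZ + ISOP (25),CBZ,25,0,33.44,0.84,16,33.51,2.33,44,0.028,52,0.978,0.86 + 0.11,0.97
CBZ + ISOP (50),CBZ,50,0,57.32,0.97,24,57.50,3.54,44,0.049,49,0.961,0.77 + 0.21,0.98
PHT + ISOP (25),PHT,25,0,32.27,0.72,16,32.79,2.42,44,0.206,50,0.838,0.83 + 0.11,0.94
PHT + ISOP (50),PHT,50,0,56.13,0.67,24,56.86,3.61,44,0.199,46,0.843,0.70 + 0.21,0.91
PB + ISOP (25),PB,25,0,51.17,2.07,16,50.79,2.84,44,0.108,56,0.914,0.91 + 0.11,1.02
PB + ISOP (50),PB,50,0,74.67,2.16,24,72.73,3.99,44,0.428,62,0.670,0.86 + 0.21,1.07
VPA + ISOP (25),VPA,25,0,311.13,11.73,24,286.00,7.62,52,1.797,43,0.079,0.98 + 0.11,1.09
VPA + ISOP (50),VPA,50,0,313.8,10.15,32,280.0,8.19,52,2.589,67,0.012,0.90 + 0.21,1.11
CBZ + ISOP (25) + BOR (25),CBZ,25,25,55.73,0.89,24,57.50,3.54,44,0.485,48,0.630,0.60 + 0.11 + 0.10,0.81
PHT + ISOP (25) + BOR (25),PHT,25,25,55.54,0.82,24,56.86,3.61,44,0.357,47,0.723,0.64 + 0.11 + 0.10,0.85
PB + ISOP (25) + BOR (25),PB,25,25,62.25,2.52,24,72.73,3.99,44,2.221,65,0.030,0.42 + 0.11 + 0.10,0.63
VPA + ISOP (25) + BOR (25),VPA,25,25,218.9,13.15,24,280.0,8.19,52,3.944,41,0.0003,0.58 + 0.11 + 0.10,0.79',
           check.names = TRUE)
}

# Published solo ED50s (mg/kg) used throughout the tests.
printed_solo_ed50 <- c(CBZ = 9.52, PHT = 8.71, PB = 28.85, VPA = 292,
                       ISOP = 235.7)

log_spaced <- function(from, to, n) 10^seq(log10(from), log10(to),
                                           length.out = n)

# One end-to-end replicate of the simulated pipeline: fit solo curves for the
# varied drug and the adjunct, fit the mixture curve, form the additive
# prediction and classify. Returns the classification or NA when a replicate
# is non-estimable (e.g. complete separation at small group sizes).
simulate_and_classify <- function(seed, interaction_factor = 1,
                                  n_per_group = 8) {
  tryCatch({
    fv <- fit_log_probit(simulate_quantal(simulation_config(
      250, 3, log_spaced(100, 600, 6), n_per_group = n_per_group,
      seed = seed * 4 + 1, drug = "varied")))
    fa <- fit_log_probit(simulate_quantal(simulation_config(
      500, 3, log_spaced(200, 1250, 6), n_per_group = n_per_group,
      seed = seed * 4 + 2, drug = "adjunct")))
    fm <- fit_log_probit(simulate_mixture(simulation_config(
      250, 3, log_spaced(30, 500, 6), n_per_group = n_per_group,
      seed = seed * 4 + 3, drug = "mixture",
      interaction_factor = interaction_factor,
      adjuncts = data.frame(dose = 100, ed50 = 500))))
    design <- mixture_design(fv, data.frame(drug = "adjunct", dose = 100,
                                            ed50 = fa$ed50, sem = fa$sem,
                                            n = fa$n_probit))
    classify_interaction(experimental_mixture_ed50(fm, 100),
                         additive_ed50(design))$classification
  }, error = function(e) NA_character_, warning = function(w) NA_character_)
}
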