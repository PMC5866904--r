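# Profile builders and closed-form oracles shared across test files.
# Oracles here are independent of the NCA implementation: closed-form
# integrals of mono-/biexponential curves and adaptive quadrature.

# geometric time grid, dense enough that trapezoidal error is far below the
# tolerances asserted against the analytic oracles
dense_grid <- function(t_min, t_max, n = 20000) {
  exp(seq(log(t_min), log(t_max), length.out = n))
}

mono_profile <- function(C0 = 300, lambda = 0.05, dose = 30,
                         times = dense_grid(1e-3 / lambda, 40 / lambda),
                         id = "mono", group = "control") {
  conc_time_profile(id, group, dose = dose, times = times,
                    concentrations = C0 * exp(-lambda * times))
}

biexp_curve <- function(A, alpha, B, beta) {
  function(t) A * exp(-alpha * t) + B * exp(-beta * t)
}

biexp_profile <- function(A, alpha, B, beta, dose = 30,
                          times = dense_grid(1e-3 / alpha, 15 / beta),
                          id = "biexp", group = "control") {
  conc_time_profile(id, group, dose = dose, times = times,
                    concentrations = biexp_curve(A, alpha, B, beta)(times))
}

# closed forms for the biexponential (A, alpha, B, beta)
biexp_auc_to <- function(A, alpha, B, beta, T) {
  A * (1 - exp(-alpha * T)) / alpha + B * (1 - exp(-beta * T)) / beta
}
# int_0^T t C(t) dt for one exponential term a*exp(-k t):
# a * (1 - exp(-k T) (1 + k T)) / k^2
biexp_aumc_to <- function(A, alpha, B, beta, T) {
  term <- function(a, k) a * (1 - exp(-k * T) * (1 + k * T)) / k^2
  term(A, alpha) + term(B, beta)
}
biexp_mrt <- function(A, alpha, B, beta) {
  (A / alpha^2 + B / beta^2) / (A / alpha + B / beta)
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)

# small fixed-design profile on the study's 8-point schedule
schedule_times <- c(1, 3, 5, 10, 20, 30, 60, 90)
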