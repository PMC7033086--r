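# Shared fixtures, built once per test run.  All noiseless objects are
# deterministic; noisy objects always take explicit seeds in the tests.

# canonical bi-exponential input used across module tests
canonical_input <- function() {
  list(A1 = 50, lambda1 = 0.5, A2 = 10, lambda2 = 0.02, rise_min = 0.75)
}

# noiseless default study and its fitted input function
.noiseless_env <- new.env()
noiseless_study <- function() {
  if (is.null(.noiseless_env$study)) {
    .noiseless_env$study <- make_study_fixture(sim_config(noise_cv = 0))
    .noiseless_env$input <- fit_input_function(.noiseless_env$study$blood)
  }
  list(study = .noiseless_env$study, input = .noiseless_env$input)
}

# blood samples drawn exactly from a bi-exponential (no bolus ramp), with
# a zero background row; handy for input-function tests
biexp_blood <- function(p, times = c(0.5, 1, 3, 5, 10, 20, 30, 50),
                        noise_cv = 0, seed = NULL) {
  y <- p$A1 * exp(-p$lambda1 * times) + p$A2 * exp(-p$lambda2 * times)
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y * pmax(0, 1 + noise_cv * rnorm(length(y)))
  }
  blood_samples(time = c(0, times), whole_blood = c(0, y / 1.31),
                plasma = c(0, y))
}

# a study_config whose metabolite fraction is zero (correction disabled)
no_metabolite_config <- function() {
  study_config(metabolite_fractions = cbind(time = 20, fraction = 0))
}

# tissue activities constructed so that the package's own discretized
# Logan relation  int C = V * int Cp + b * C(T)  holds exactly on every
# frame; on such data Logan and MA1 are algebraically identical.
exact_equilibrium_tac <- function(input, V = 0.8, b = -5,
                                  schedule = default_schedule()) {
  mid <- frame_midpoints(schedule)
  X <- plasma_integral(input, mid)
  du <- schedule$duration
  st <- schedule$start
  n <- length(mid)
  C <- numeric(n)
  C[1] <- V * X[1] / (st[1] + du[1] / 2 - b)
  for (i in seq_len(n)[-1]) {
    gap <- st[i] - (st[i - 1] + du[i - 1])
    a <- du[i - 1] / 2 + gap / 2
    cc <- gap / 2 + du[i] / 2
    C[i] <- (V * (X[i - 1] - X[i]) + C[i - 1] * (b + a)) / (b - cc)
  }
  tissue_tac("equilibrium", schedule, C)
}
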