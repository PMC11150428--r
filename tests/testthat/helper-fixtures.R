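# Shared fixtures: a small, fast-breeding species for simulator unit tests,
# and builders for hand-constructed sample sets used by the likelihood and
# estimator oracles.

toy_species <- function(phi = NULL) {
  species_config(
    name = "toy", a_max = 6, alpha_f = 2, alpha_m = 2,
    litter_sizes = 2L, gestation_years = 0L,
    vbgf = vbgf_params(100, 0.4, -1), sigma_l = 2, phi = phi)
}

toy_gestating_species <- function(phi = NULL) {
  species_config(
    name = "toy-gest", a_max = 9, alpha_f = 3, alpha_m = 2,
    litter_sizes = 2:4, gestation_years = 1L,
    vbgf = vbgf_params(100, 0.4, -1), sigma_l = 2, phi = phi)
}

# A sample tibble from explicit vectors; records numbered 1..n.
make_samples <- function(sex, capture_year, length, id = seq_along(sex),
                         true_age = NA_integer_) {
  tibble::tibble(record = seq_along(sex), id = id,
                 capture_year = capture_year, sex = sex,
                 true_age = true_age, length = as.integer(length))
}

# Random small sample set (n records over two capture years) plus a random
# subset of pairs marked as POPs; used for aggregation-equivalence oracles.
random_fixture <- function(n = 30, n_pop = 5, seed = 1,
                           species = species_simple()) {
  set.seed(seed)
  ages <- sample(0:species$a_max, n, replace = TRUE)
  cy <- sample(c(99L, 100L), n, replace = TRUE)
  len <- as.integer(round(vbgf_length(ages, species$vbgf) +
                            rnorm(n, 0, species$sigma_l)))
  samples <- make_samples(sample(c("F", "M"), n, TRUE), cy, len,
                          true_age = ages)
  prs <- t(utils::combn(n, 2))
  pick <- prs[sample(nrow(prs), n_pop), , drop = FALSE]
  pops <- tibble::tibble(record_i = pick[, 1L], record_j = pick[, 2L])
  list(samples = samples, pops = pops)
}

# Naive O(n^2 (a_max+1)^2) pseudo-log-likelihood: loops over every record
# pair and every age combination with no deduplication or caching. The
# independent oracle for the aggregated fast path.
naive_log_likelihood <- function(N_f, N_m, samples, pops, model, species) {
  n <- nrow(samples)
  is_pop <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(pops))) {
    i <- pops$record_i[k]; j <- pops$record_j[k]
    is_pop[i, j] <- is_pop[j, i] <- TRUE
  }
  post <- age_posterior(samples$length, model)
  ages <- 0:model$a_max
  ll <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      A <- B <- 0
      for (ai in ages) {
        for (aj in ages) {
          w <- post[ai + 1, i] * post[aj + 1, j]
          if (w == 0) next
          A <- A + w * kinship_coefficient(
            samples$capture_year[i] - ai, samples$capture_year[i],
            samples$capture_year[j] - aj, samples$sex[i], species, model$phi)
          B <- B + w * kinship_coefficient(
            samples$capture_year[j] - aj, samples$capture_year[j],
            samples$capture_year[i] - ai, samples$sex[j], species, model$phi)
        }
      }
      P <- A / (if (samples$sex[i] == "F") N_f else N_m) +
        B / (if (samples$sex[j] == "F") N_f else N_m)
      ll <- ll + if (is_pop[i, j]) log(P) else log1p(-P)
    }
  }
  ll
}

# Known-age fixture: sigma so small that every posterior is a point mass at
# the true age, mothers captured after every offspring's birth, so each
# mother-offspring comparison has pair probability exactly 1/N_f (and
# father-offspring 1/N_m). The closed-form MLE is then
# N_hat = (#comparisons) / (#POPs) per sex.
known_age_fixture <- function(n_mothers = 6, n_fathers = 6, n_juv = 40,
                              n_pop_f = 4, n_pop_m = 3, seed = 2) {
  set.seed(seed)
  sp <- species_simple()
  # parent age 15, juvenile age 1, both captured in year 100
  sex <- c(rep("F", n_mothers), rep("M", n_fathers), rep("M", n_juv))
  age <- c(rep(15L, n_mothers + n_fathers), rep(1L, n_juv))
  len <- as.integer(round(vbgf_length(age, sp$vbgf)))
  samples <- make_samples(sex, rep(100L, length(sex)), len, true_age = age)
  pops <- tibble::tibble(
    record_i = c(seq_len(n_pop_f), n_mothers + seq_len(n_pop_m)),
    record_j = n_mothers + n_fathers + seq_len(n_pop_f + n_pop_m))
  model <- age_model(sp$vbgf, 0.05, sp$phi, sp$a_max)
  list(samples = samples, pops = pops, model = model, species = sp,
       n_mothers = n_mothers, n_fathers = n_fathers, n_juv = n_juv,
       n_pop_f = n_pop_f, n_pop_m = n_pop_m)
}
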