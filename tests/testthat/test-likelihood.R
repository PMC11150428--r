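test_that("kinship kernels reproduce the worked gestation example exactly", {
  cx <- species_complex()
  phi <- cx$phi
  # mother born year 9, captured year 45 aged 36; offspring born year 47:
  # mature by the mating year, survives capture -> birth, gestation factor
  # phi^-1: multiplier phi^2 * phi^-1 = phi, i.e. probability phi / N_f
  expect_equal(kinship_coefficient(9, 45, 47, "F", cx), phi)
  # father only needs to be alive at mating (year 46): phi^(46-45)
  expect_equal(kinship_coefficient(9, 45, 47, "M", cx), phi)
  # father captured in or after the mating year needs no extra survival
  expect_equal(kinship_coefficient(20, 46, 47, "M", cx), 1)
  expect_equal(kinship_coefficient(20, 47, 47, "F", cx), 1 / phi)
  # maturity indicator: complex mothers must mature by the mating year
  expect_equal(kinship_coefficient(28, 47, 47, "F", cx), 0)  # age 18 at mating
  expect_equal(kinship_coefficient(27, 47, 47, "F", cx), 1 / phi)
})

test_that("kinship kernels handle the annual breeder cases", {
  sp <- species_simple()
  phi <- sp$phi
  # parent captured after the offspring's birth, mature in time
  expect_equal(kinship_coefficient(80, 100, 95, "F", sp), 1)
  expect_equal(kinship_coefficient(80, 99, 95, "M", sp), 1)
  # captured before the birth: survival to the birth year
  expect_equal(kinship_coefficient(80, 99, 100, "F", sp), phi)
  expect_equal(kinship_coefficient(80, 95, 100, "M", sp), phi^5)
  # too young to be a parent
  expect_equal(kinship_coefficient(91, 100, 100, "F", sp), 0)
  expect_equal(kinship_coefficient(90, 100, 100, "F", sp), 1)
  # multipliers are bounded by 1/phi over a grid of year combinations
  grid <- expand.grid(y_i = 60:100, y_j = 80:100, c_i = c(99, 100))
  m <- with(grid, kinship_coefficient(y_i, c_i, y_j, "F", sp))
  expect_true(all(m >= 0 & m <= 1 / phi + 1e-12))
})

test_that("complex mother and father kernels agree when both captured before mating", {
  # for capture c_i < y_j - 1, mother: phi^(y_j - c_i - 1),
  # father: phi^(y_j - 1 - c_i) -- identical once both mature in time
  cx <- species_complex()
  for (y_i in c(10, 20, 30)) {
    for (y_j in c(95, 100)) {
      for (c_i in 90:(y_j - 2)) {
        if (y_i + cx$alpha_f <= y_j - 1) {
          expect_equal(kinship_coefficient(y_i, c_i, y_j, "F", cx),
                       kinship_coefficient(y_i, c_i, y_j, "M", cx))
        }
      }
    }
  }
})

test_that("pair coefficients match a brute-force double loop over ages", {
  fx <- random_fixture(n = 10, n_pop = 2, seed = 4)
  sp <- species_simple()
  model <- age_model(sp$vbgf, sp$sigma_l, sp$phi, sp$a_max)
  post <- age_posterior(fx$samples$length, model)
  set.seed(9)
  for (k in 1:5) {
    ij <- sample(10, 2)
    ri <- fx$samples[ij[1], ]; rj <- fx$samples[ij[2], ]
    got <- pair_coefficients(ri, rj, model, sp)
    A <- B <- 0
    for (ai in 0:19) {
      for (aj in 0:19) {
        w <- post[ai + 1, ij[1]] * post[aj + 1, ij[2]]
        A <- A + w * kinship_coefficient(ri$capture_year - ai,
                                         ri$capture_year,
                                         rj$capture_year - aj, ri$sex, sp)
        B <- B + w * kinship_coefficient(rj$capture_year - aj,
                                         rj$capture_year,
                                         ri$capture_year - ai, rj$sex, sp)
      }
    }
    expect_equal(got, c(A = A, B = B), tolerance = 1e-12)
  }
})

test_that("identical records give exchangeable coefficients", {
  sp <- species_simple()
  model <- age_model(sp$vbgf, sp$sigma_l, sp$phi, sp$a_max)
  r <- list(sex = "F", capture_year = 99L, length = 110L)
  ab <- pair_coefficients(r, r, model, sp)
  expect_equal(ab[["A"]], ab[["B"]])
})

test_that("comparison counts cover every unordered record pair exactly once", {
  fx <- random_fixture(n = 30, n_pop = 5, seed = 1)
  counts <- comparison_counts(fx$samples, fx$pops)
  expect_equal(sum(counts$n_pairs), 30 * 29 / 2)
  expect_equal(sum(counts$n_pop), 5)
  expect_true(all(counts$n_pop <= counts$n_pairs))
  # deduplication: far fewer keys than pairs on a bounded length grid
  sim <- simulate_population(species_simple(), seed = 3)
  big <- comparison_counts(sim$samples, sim$pops)
  expect_equal(sum(big$n_pairs), 750 * 749 / 2)
  expect_lt(nrow(big), 750 * 749 / 2 / 5)
})

test_that("aggregated likelihood equals the naive pair-by-pair evaluation", {
  sp <- species_simple()
  model <- age_model(sp$vbgf, sp$sigma_l, sp$phi, sp$a_max)
  fx <- random_fixture(n = 30, n_pop = 5, seed = 1)
  agg <- aggregate_comparisons(fx$samples, fx$pops, model, sp)
  for (N in list(c(800, 800), c(500, 1500), c(2000, 900))) {
    expect_equal(pseudo_log_likelihood(N[1], N[2], agg),
                 naive_log_likelihood(N[1], N[2], fx$samples, fx$pops,
                                      model, sp),
        tolerance = 1e-10)
  }
})

test_that("coefficients do not depend on the abundance parameters", {
  # the aggregated table is built once; likelihood evaluations at different
  # abundances must reuse identical coefficients
  sp <- species_simple()
  model <- age_model(sp$vbgf, sp$sigma_l, sp$phi, sp$a_max)
  fx <- random_fixture(n = 20, n_pop = 3, seed = 6)
  a1 <- aggregate_comparisons(fx$samples, fx$pops, model, sp)
  a2 <- aggregate_comparisons(fx$samples, fx$pops, model, sp)
  expect_identical(a1$A, a2$A)
  expect_identical(a1$B, a2$B)
})

test_that("a data set with no POPs has likelihood increasing in abundance", {
  sp <- species_simple()
  model <- age_model(sp$vbgf, sp$sigma_l, sp$phi, sp$a_max)
  fx <- random_fixture(n = 15, n_pop = 1, seed = 2)
  agg <- aggregate_comparisons(fx$samples, fx$pops[0, ], model, sp,
                               counts = comparison_counts(fx$samples,
                                                          fx$pops[0, ]))
  Ns <- c(500, 1000, 2000, 4000, 8000)
  ll <- vapply(Ns, function(N) pseudo_log_likelihood(N, N, agg), numeric(1))
  expect_true(all(diff(ll) > 0))
})

test_that("true POPs have positive probability under correct specification", {
  sp <- species_simple()
  sim <- simulate_population(sp, seed = 17)
  model <- age_model(sp$vbgf, sp$sigma_l, sp$phi, sp$a_max)
  agg <- aggregate_comparisons(sim$samples, sim$pops, model, sp)
  fin <- sim$truth[sim$truth$year == 100, ]
  N <- c(F = fin$N_f_adult, M = fin$N_m_adult)
  P <- agg$A / N[agg$sex_i] + agg$B / N[agg$sex_j]
  expect_true(all(P[agg$n_pop > 0] > 0))
  expect_true(is.finite(pseudo_log_likelihood(N[1], N[2], agg)))
})
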