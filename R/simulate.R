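#' @importFrom rlang %||% .data
#' @importFrom stats rbinom runif rnorm median sd qnorm pnorm optim setNames
#' @importFrom utils head
NULL

# sample() treats a length-one vector as 1:x; this wrapper never does.
sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# Internal mutable population state. Individuals live in flat, preallocated
# vectors indexed by id; `alive` holds the ids currently alive. Gestation
# state (complex species) is carried per female as the year her litter is
# due and the id of the father sampled at mating.
new_population_state <- function(capacity) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$female <- logical(capacity)
  env$birth_year <- integer(capacity)
  env$mother <- integer(capacity)
  env$father <- integer(capacity)
  env$due_year <- integer(capacity)   # NA when not gestating
  env$due_father <- integer(capacity)
  env$alive <- integer(0)
  env
}

pop_grow <- function(env, need) {
  cap <- length(env$female)
  if (env$n + need <= cap) return(invisible(env))
  new_cap <- max(2L * cap, env$n + need)
  for (f in c("female", "birth_year", "mother", "father", "due_year",
              "due_father")) {
    length(env[[f]]) <- new_cap
  }
  invisible(env)
}

pop_add <- function(env, female, birth_year, mother, father) {
  k <- length(female)
  pop_grow(env, k)
  idx <- env$n + seq_len(k)
  env$female[idx] <- female
  env$birth_year[idx] <- birth_year
  env$mother[idx] <- mother
  env$father[idx] <- father
  env$due_year[idx] <- NA_integer_
  env$due_father[idx] <- NA_integer_
  env$n <- env$n + k
  env$alive <- c(env$alive, idx)
  idx
}

#' Initialize a founding population
#'
#' Creates `n0` founders with a 50:50 expected sex ratio and ages drawn
#' from the stationary age structure at the point in the yearly cycle where
#' the simulation starts: just before the birth event, where a stationary
#' population holds survivorship-weighted ages `1..a_max` (that year's
#' age-0 cohort has not been born yet; it appears at the first birth
#' event). Seeding this census with the stationary structure keeps the
#' expected population level flat from year one, so the post-birth census
#' -- where sampling happens and abundance is reported -- settles at its
#' long-run level rather than relaxing through a transient. For a gestating
#' species, mature founder females are placed on the stationary alternating
#' breeding schedule: a female is carrying a litter due this year exactly
#' when her current age is one of her breeding ages, so annual birth totals
#' are balanced from the start instead of pulsing every other year.
#' Founders have no recorded parents.
#'
#' @param n0 Number of founders.
#' @param species A `ckmr_species` object.
#' @param year Simulation year at which founders are censused (ages are
#'   ages at this year's birth event).
#' @return An internal population state environment.
#' @keywords internal
initialize_population <- function(n0, species, year = 1L) {
  env <- new_population_state(max(2L * n0, 1000L))
  if (n0 == 0L) return(env)
  ages <- sample(1:species$a_max, n0, replace = TRUE,
                 prob = founder_age_pmf(species$phi, species$a_max))
  female <- runif(n0) < 0.5
  pop_add(env, female, year - ages, NA_integer_, NA_integer_)
  if (species$gestation_years == 1L) {
    due_now <- which(female & ages %in% birth_ages(species))
    males <- which(!female & ages >= species$alpha_m)
    if (length(due_now) > 0 && length(males) > 0) {
      env$due_year[due_now] <- year
      env$due_father[due_now] <- sample_vec(males, length(due_now), replace = TRUE)
    }
  }
  env
}

#' Truncated-geometric stable age distribution
#'
#' Probability mass of age `a` in a stationary population with constant
#' annual survival `phi` and a hard maximum age:
#' \deqn{f(a) = \phi^a (1-\phi) / (1 - \phi^{a_{max}+1}), \quad 0 \le a \le a_{max}}
#'
#' @param phi Annual survival probability.
#' @param a_max Maximum age.
#' @return Numeric vector of length `a_max + 1` summing to one.
#' @export
stable_age_pmf <- function(phi, a_max) {
  stopifnot(phi > 0, phi < 1, a_max >= 0)
  a <- 0:a_max
  phi^a * (1 - phi) / (1 - phi^(a_max + 1))
}

#' Stationary pre-recruitment age distribution
#'
#' Age frequencies of a stationary population censused just before the
#' birth event, when the current year's cohort does not exist yet:
#' survivorship-weighted ages `1..a_max`,
#' \deqn{f(a) = \phi^a (1-\phi) / (\phi - \phi^{a_{max}+1}), \quad 1 \le a \le a_{max}.}
#' This is [stable_age_pmf()] conditioned on age at least one, and is the
#' distribution founders are drawn from.
#'
#' @inheritParams stable_age_pmf
#' @return Numeric vector of length `a_max` (ages `1..a_max`) summing to 1.
#' @export
founder_age_pmf <- function(phi, a_max) {
  stopifnot(phi > 0, phi < 1, a_max >= 1)
  a <- 1:a_max
  phi^a / sum(phi^a)
}

#' Advance a population by one yearly cycle
#'
#' Executes, in order: (1) birth/mating -- gestating females whose litter is
#' due give birth (litter size drawn from the species' litter distribution)
#' and then all mature, non-gestating females that did not just give birth
#' mate with a uniformly chosen mature male (males can father several
#' litters); for annual breeders every mature female produces a litter
#' outright; (2) sampling -- if requested, a uniform random subset of the
#' living population (all ages, without replacement) is measured; (3)
#' survival -- every living individual survives with probability `phi`, and
#' any individual that has reached the maximum age dies; (4) ageing (age is
#' derived as year minus birth year). The pre-survival census taken at the
#' sampling stage is returned alongside any sample records.
#'
#' @param env Internal population state (modified in place).
#' @param t Current simulation year.
#' @param species A `ckmr_species` object.
#' @param sample_n Number of individuals to sample this year (0 for none).
#' @return List with `samples` (list of record vectors or `NULL`) and
#'   `census` (named vector: adult females, adult males, total alive).
#' @keywords internal
step_year <- function(env, t, species, sample_n = 0L) {
  alive <- env$alive
  age <- t - env$birth_year[alive]
  is_f <- env$female[alive]

  # --- stage 1: birth, then mating --------------------------------------
  due <- integer(0)
  if (species$gestation_years == 1L) {
    due <- alive[is_f & !is.na(env$due_year[alive]) & env$due_year[alive] == t]
    if (length(due) > 0) {
      litters <- sample_vec(species$litter_sizes, length(due), replace = TRUE,
                        prob = species$litter_probs)
      nb <- sum(litters)
      pop_add(env, runif(nb) < 0.5, rep.int(t, nb),
              rep.int(due, litters), rep.int(env$due_father[due], litters))
      env$due_year[due] <- NA_integer_
      env$due_father[due] <- NA_integer_
    }
    candidates <- setdiff(
      alive[is_f & age >= species$alpha_f & is.na(env$due_year[alive])], due)
    males <- alive[!is_f & age >= species$alpha_m]
    if (length(candidates) > 0 && length(males) > 0) {
      env$due_year[candidates] <- t + 1L
      env$due_father[candidates] <- sample_vec(males, length(candidates),
                                           replace = TRUE)
    }
  } else {
    mothers <- alive[is_f & age >= species$alpha_f]
    males <- alive[!is_f & age >= species$alpha_m]
    if (length(mothers) > 0 && length(males) > 0) {
      litters <- sample_vec(species$litter_sizes, length(mothers), replace = TRUE,
                        prob = species$litter_probs)
      nb <- sum(litters)
      pop_add(env, runif(nb) < 0.5, rep.int(t, nb), rep.int(mothers, litters),
              rep.int(sample_vec(males, length(mothers), replace = TRUE), litters))
    }
  }

  # --- census at the sampling stage (post-birth, pre-survival) ----------
  alive_now <- env$alive
  age_now <- t - env$birth_year[alive_now]
  f_now <- env$female[alive_now]
  census <- c(
    N_f_adult = sum(f_now & age_now >= species$alpha_f),
    N_m_adult = sum(!f_now & age_now >= species$alpha_m),
    N_total = length(alive_now))

  # --- stage 2: sampling ------------------------------------------------
  samples <- NULL
  if (sample_n > 0L) {
    if (sample_n > length(alive_now)) {
      stop("sampling count exceeds the living population: degenerate run")
    }
    ids <- sort(sample_vec(alive_now, sample_n))
    a <- t - env$birth_year[ids]
    true_len <- vbgf_length(a, species$vbgf)
    meas <- floor(true_len + rnorm(sample_n, 0, species$sigma_l) + 0.5)
    samples <- list(id = ids, capture_year = rep.int(t, sample_n),
                    sex = ifelse(env$female[ids], "F", "M"),
                    true_age = a, length = as.integer(meas))
  }

  # --- stages 3-4: survival, deterministic death at a_max, ageing -------
  keep <- runif(length(alive_now)) < species$phi & age_now < species$a_max
  env$alive <- alive_now[keep]

  list(samples = samples, census = census)
}

#' Simulate one population with pedigree tracking
#'
#' Runs the yearly cycle (birth/mating, sampling, survival, ageing) for
#' `years` years starting from `n0` founders, sampling `n_per_year` living
#' individuals uniformly (all ages, without replacement within a year) in
#' each of `sample_years`. Measured lengths are the VBGF expectation at the
#' individual's true age plus Gaussian measurement error, rounded to the
#' nearest integer centimetre (half away from zero). The full pedigree is
#' retained, so the true parent-offspring pairs among the sampled records
#' are known exactly.
#'
#' @param species A `ckmr_species` object.
#' @param years Number of simulated years; must exceed `a_max` so that all
#'   founders (whose parents are unrecorded) are dead before sampling.
#' @param sample_years Years in which sampling occurs.
#' @param n_per_year Individuals sampled per sampling year.
#' @param n0 Founding population size.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return An object of class `ckmr_sim`: a list with
#' \describe{
#'   \item{samples}{tibble of capture records: `record`, `id`,
#'     `capture_year`, `sex`, `true_age` (latent, kept for diagnostics),
#'     `length` (measured, integer cm).}
#'   \item{pops}{tibble of true parent-offspring record pairs
#'     (`record_i`, `record_j`).}
#'   \item{truth}{tibble of yearly abundance at the post-birth census:
#'     `year`, `N_f_adult`, `N_m_adult`, `N_total`.}
#'   \item{growth_rate}{realized geometric-mean annual growth of total
#'     abundance.}
#'   \item{n_recaptured}{number of individuals sampled in more than one
#'     year.}
#'   \item{species}{the species configuration used (including `phi`).}
#'   \item{seed}{the seed, if one was given.}
#' }
#' @examples
#' \donttest{
#' sim <- simulate_population(species_simple(), seed = 1)
#' sim$truth[sim$truth$year == 100, ]
#' nrow(sim$pops) # true POPs among the samples
#' }
#' @export
simulate_population <- function(species, years = 100L,
                                sample_years = c(99L, 100L),
                                n_per_year = 375L, n0 = 8500L, seed = NULL) {
  stopifnot(inherits(species, "ckmr_species"), years > species$a_max,
            all(sample_years >= 1L), all(sample_years <= years))
  if (!is.null(seed)) set.seed(seed)

  env <- initialize_population(n0, species, year = 1L)
  truth <- matrix(0L, nrow = years, ncol = 3L,
                  dimnames = list(NULL, c("N_f_adult", "N_m_adult", "N_total")))
  recs <- list()

  for (t in seq_len(years)) {
    want <- if (t %in% sample_years && n_per_year > 0L) n_per_year else 0L
    out <- step_year(env, t, species, sample_n = want)
    truth[t, ] <- out$census
    if (!is.null(out$samples)) recs[[length(recs) + 1L]] <- out$samples
    if (length(env$alive) == 0L && t < max(sample_years)) {
      stop("population went extinct before sampling: failed replicate")
    }
  }

  samples <- if (length(recs) > 0) {
    tibble::as_tibble(purrr::map(purrr::transpose(recs), ~ unlist(.x, use.names = FALSE)))
  } else {
    tibble::tibble(id = integer(), capture_year = integer(),
                   sex = character(), true_age = integer(), length = integer())
  }
  samples <- dplyr::mutate(samples, record = dplyr::row_number(),
                           .before = 1L)

  pedigree <- tibble::tibble(
    id = seq_len(env$n),
    mother = env$mother[seq_len(env$n)],
    father = env$father[seq_len(env$n)])
  pops <- identify_kinship(samples, pedigree)

  truth_tbl <- tibble::tibble(year = seq_len(years),
                              N_f_adult = truth[, "N_f_adult"],
                              N_m_adult = truth[, "N_m_adult"],
                              N_total = truth[, "N_total"])
  growth <- (truth[years, "N_total"] / truth[1L, "N_total"])^(1 / (years - 1))

  structure(
    list(samples = samples, pops = pops, truth = truth_tbl,
         growth_rate = unname(growth),
         n_recaptured = sum(duplicated(unique(samples[c("id", "capture_year")])$id)),
         species = species, seed = seed),
    class = "ckmr_sim")
}

#' @export
print.ckmr_sim <- function(x, ...) {
  fin <- x$truth[nrow(x$truth), ]
  cat(sprintf("CKMR simulation of the '%s' species (%d years)\n",
              x$species$name, nrow(x$truth)))
  cat(sprintf("  %d sample records, %d true POPs, %d recaptured individuals\n",
              nrow(x$samples), nrow(x$pops), x$n_recaptured))
  cat(sprintf("  final-year adult abundance: %d F / %d M; realized growth %.4f\n",
              fin$N_f_adult, fin$N_m_adult, x$growth_rate))
  invisible(x)
}

#' Find true parent-offspring pairs among sample records
#'
#' A pair of sample records is a parent-offspring pair (POP) exactly when
#' one record's individual is the recorded mother or father of the other's.
#' Every other relationship -- half-siblings, grandparent-grandchild, two
#' captures of the same individual, unrelated -- counts as "not a POP".
#'
#' @param samples Tibble of sample records with columns `record` and `id`.
#' @param pedigree Tibble with columns `id`, `mother`, `father` covering all
#'   sampled individuals.
#' @return Tibble with columns `record_i` (the parent's record) and
#'   `record_j` (the offspring's record), one row per POP record pair.
#' @export
identify_kinship <- function(samples, pedigree) {
  if (nrow(samples) < 2L) {
    return(tibble::tibble(record_i = integer(), record_j = integer()))
  }
  ped <- pedigree[match(samples$id, pedigree$id), ]
  link <- function(parent_ids) {
    # rows: every (offspring record, parent record) with matching ids
    hits <- purrr::map(parent_ids, function(pid) {
      if (is.na(pid)) integer(0) else which(samples$id == pid)
    })
    tibble::tibble(
      record_j = rep.int(samples$record, lengths(hits)),
      record_i = samples$record[unlist(hits, use.names = FALSE)] %||% integer(0))
  }
  out <- dplyr::bind_rows(link(ped$mother), link(ped$father))
  out <- out[out$record_i != out$record_j, c("record_i", "record_j")]
  dplyr::distinct(out)
}
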