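#' Von Bertalanffy growth parameters
#'
#' Bundle the three parameters of a von Bertalanffy growth function (VBGF),
#' the standard length-at-age model for fish and elasmobranchs:
#' \deqn{\ell(a) = \ell_\infty \left(1 - e^{-k (a - a_0)}\right)}
#'
#' @param l_inf Asymptotic length (cm), the length approached at old age.
#' @param k Growth coefficient (1/year), the rate at which `l_inf` is
#'   approached.
#' @param a0 Theoretical age at length zero (years); typically negative so
#'   that age-0 animals already have positive length.
#'
#' @return An object of class `vbgf_params` (a named list).
#' @examples
#' vb <- vbgf_params(l_inf = 163, k = 0.0554, a0 = -8.27)
#' vbgf_length(0:10, vb)
#' @export
vbgf_params <- function(l_inf, k, a0) {
  stopifnot(is.numeric(l_inf), length(l_inf) == 1L, l_inf > 0,
            is.numeric(k), length(k) == 1L, k > 0,
            is.numeric(a0), length(a0) == 1L)
  structure(list(l_inf = l_inf, k = k, a0 = a0), class = "vbgf_params")
}

#' @export
print.vbgf_params <- function(x, ...) {
  cat(sprintf("von Bertalanffy growth curve: l_inf = %g cm, k = %g /yr, a0 = %g yr\n",
              x$l_inf, x$k, x$a0))
  invisible(x)
}

#' Expected length at age
#'
#' Evaluates the von Bertalanffy growth function at one or more ages.
#'
#' @param age Numeric vector of ages in years; must be non-negative.
#' @param params A [vbgf_params()] object.
#'
#' @return Numeric vector of expected lengths (cm), real-valued.
#' @examples
#' vbgf_length(0, vbgf_params(163, 0.0554, -8.27)) # ~59.91 cm at birth
#' @export
vbgf_length <- function(age, params) {
  stopifnot(inherits(params, "vbgf_params"), is.numeric(age))
  if (any(age < 0)) stop("`age` must be non-negative")
  params$l_inf * (1 - exp(-params$k * (age - params$a0)))
}

#' Shift a growth curve up or down by a fixed percentage
#'
#' Produces a misspecified growth curve whose expected length-at-age equals
#' `(1 + shift)` times the original at every age. Because the VBGF is linear
#' in `l_inf`, this is implemented by scaling the asymptotic length while
#' leaving `k` and `a0` untouched.
#'
#' @param params A [vbgf_params()] object.
#' @param shift Fractional shift, e.g. `-0.05` for a curve 5% below truth.
#'
#' @return A new `vbgf_params` object.
#' @export
vbgf_shift <- function(params, shift) {
  stopifnot(inherits(params, "vbgf_params"), is.numeric(shift),
            length(shift) == 1L, shift > -1)
  vbgf_params(params$l_inf * (1 + shift), params$k, params$a0)
}

#' Species life-history configuration
#'
#' Describes one simulated species: demography (maturity, litter size,
#' gestation, survival, maximum age) and the observation process (growth
#' curve and length measurement error). Two ready-made configurations,
#' [species_simple()] and [species_complex()], cover the standard study
#' designs; `species_config()` is the general constructor.
#'
#' @param name Label for the species.
#' @param a_max Maximum age in years. Animals breed through age `a_max` and
#'   die deterministically at that year's survival event.
#' @param alpha_f,alpha_m Female / male age at maturity (knife-edge).
#' @param litter_sizes Integer vector of possible litter sizes.
#' @param litter_probs Probabilities for `litter_sizes`; must sum to 1.
#' @param gestation_years 0 for annual breeders (mating and birth in the
#'   same yearly cycle) or 1 for a one-year gestation, which forces females
#'   onto an every-other-year breeding schedule.
#' @param vbgf A [vbgf_params()] growth curve.
#' @param sigma_l True standard deviation (cm) of length measurement error.
#' @param phi Annual survival probability; if `NULL` it is calibrated with
#'   [calibrate_survival()] so the long-run population growth rate is 1.
#'
#' @return An object of class `ckmr_species`.
#' @seealso [calibrate_survival()], [simulate_population()]
#' @export
species_config <- function(name, a_max, alpha_f, alpha_m,
                           litter_sizes, litter_probs = NULL,
                           gestation_years, vbgf, sigma_l, phi = NULL) {
  if (is.null(litter_probs)) {
    litter_probs <- rep(1 / length(litter_sizes), length(litter_sizes))
  }
  stopifnot(
    length(litter_sizes) == length(litter_probs),
    abs(sum(litter_probs) - 1) < 1e-9,
    all(litter_sizes >= 1),
    gestation_years %in% c(0L, 1L),
    alpha_f > 0, alpha_f <= a_max,
    alpha_m > 0, alpha_m <= a_max,
    inherits(vbgf, "vbgf_params"),
    sigma_l > 0
  )
  sp <- structure(
    list(name = name, a_max = as.integer(a_max),
         alpha_f = as.integer(alpha_f), alpha_m = as.integer(alpha_m),
         litter_sizes = as.integer(litter_sizes), litter_probs = litter_probs,
         gestation_years = as.integer(gestation_years),
         vbgf = vbgf, sigma_l = sigma_l, phi = phi),
    class = "ckmr_species")
  if (is.null(phi)) sp$phi <- calibrate_survival(sp)
  stopifnot(sp$phi > 0, sp$phi < 1)
  sp
}

#' @export
print.ckmr_species <- function(x, ...) {
  cat(sprintf("Species '%s': a_max = %d, maturity F %d / M %d, gestation %d yr\n",
              x$name, x$a_max, x$alpha_f, x$alpha_m, x$gestation_years))
  cat(sprintf("  litter sizes {%s}, annual survival phi = %.6f\n",
              paste(x$litter_sizes, collapse = ","), x$phi))
  print(x$vbgf)
  cat(sprintf("  length measurement error SD = %g cm\n", x$sigma_l))
  invisible(x)
}

#' Simple study species
#'
#' Annual breeder with a fixed litter of two, both sexes maturing at 10 and
#' a maximum age of 19. Length-at-age follows the grey-reef-shark growth
#' curve (l_inf = 163 cm, k = 0.0554, a0 = -8.27) with measurement error
#' SD 2.89 cm. Survival is calibrated for a stationary population.
#'
#' @param phi Optional pre-calibrated survival; calibrated if `NULL`.
#' @return A `ckmr_species` object.
#' @export
species_simple <- function(phi = NULL) {
  species_config(
    name = "simple", a_max = 19, alpha_f = 10, alpha_m = 10,
    litter_sizes = 2L, gestation_years = 0L,
    vbgf = vbgf_params(163, 0.0554, -8.27), sigma_l = 2.89, phi = phi)
}

#' Complex study species
#'
#' Life history patterned on the grey reef shark: litters of 3-6 pups with
#' equal probability, a one-year gestation (so females breed every other
#' year), males maturing at 17, females at 19, and a maximum age of 63.
#' Growth curve and measurement error as in [species_simple()].
#'
#' @inheritParams species_simple
#' @return A `ckmr_species` object.
#' @export
species_complex <- function(phi = NULL) {
  species_config(
    name = "complex", a_max = 63, alpha_f = 19, alpha_m = 17,
    litter_sizes = 3:6, gestation_years = 1L,
    vbgf = vbgf_params(163, 0.0554, -8.27), sigma_l = 2.89, phi = phi)
}

#' Ages at which a female gives birth
#'
#' For annual breeders this is every age from `alpha_f` through `a_max`.
#' With a one-year gestation a female first mates at `alpha_f`, gives birth
#' the following year, and cannot mate again in a birth year, so births fall
#' at ages `alpha_f + 1, alpha_f + 3, ...` up to `a_max`.
#'
#' @param species A `ckmr_species` object.
#' @return Integer vector of breeding ages.
#' @keywords internal
birth_ages <- function(species) {
  if (species$gestation_years == 0L) {
    seq.int(species$alpha_f, species$a_max)
  } else {
    seq.int(species$alpha_f + 1L, species$a_max, by = 2L)
  }
}

#' Female Leslie projection matrix
#'
#' Builds the female-only Leslie matrix for a species at a given annual
#' survival, with the census taken immediately after the birth event. Age
#' classes are 0..a_max; newborns are exposed to survival in their birth
#' year and animals of age `a_max` die deterministically at the survival
#' event (after breeding). Fecundity is expected daughters per litter
#' (mean litter size / 2) at each breeding age.
#'
#' @param species A `ckmr_species` object (its `phi` field is ignored).
#' @param phi Annual survival probability to use.
#' @return A dense `(a_max + 1) x (a_max + 1)` matrix.
#' @export
leslie_matrix <- function(species, phi) {
  n <- species$a_max + 1L
  A <- matrix(0, n, n)
  # survival subdiagonal: age a -> a + 1; age a_max has no survivors
  for (a in 0:(species$a_max - 1L)) A[a + 2L, a + 1L] <- phi
  daughters <- sum(species$litter_sizes * species$litter_probs) / 2
  # a census-age-a female breeds next year at age a + 1 if that is a birth age
  breed_next <- intersect(birth_ages(species) - 1L, 0:(species$a_max - 1L))
  A[1L, breed_next + 1L] <- A[1L, breed_next + 1L] + daughters * phi
  A
}

#' Long-run population growth rate at a given survival
#'
#' Dominant eigenvalue of the female Leslie matrix.
#'
#' @inheritParams leslie_matrix
#' @return The asymptotic yearly growth rate lambda.
#' @export
leslie_growth_rate <- function(species, phi) {
  max(Mod(eigen(leslie_matrix(species, phi), only.values = TRUE)$values))
}

#' Calibrate annual survival for a stationary population
#'
#' Finds the annual survival probability at which the species' long-run
#' growth rate equals one, so simulated populations neither grow nor
#' shrink on average. The growth rate is the dominant eigenvalue of the
#' female Leslie matrix (census right after birth, newborns exposed to
#' survival in their birth year, deterministic death after the maximum
#' age), and is strictly increasing in survival, so a root bracketed in
#' (0, 1) is unique.
#'
#' @param species A `ckmr_species` object; its current `phi` is ignored.
#' @param tol Tolerance on `|lambda - 1|` at the returned root.
#' @return The calibrated survival probability.
#' @examples
#' sp <- species_simple()
#' leslie_growth_rate(sp, sp$phi) # ~1
#' @export
calibrate_survival <- function(species, tol = 1e-6) {
  f <- function(phi) leslie_growth_rate(species, phi) - 1
  lo <- 0.05; hi <- 0.999
  if (f(lo) > 0 || f(hi) < 0) {
    stop("no survival probability in (0, 1) yields a stationary population; ",
         "the life history is inconsistent")
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (abs(f(root)) > tol) stop("survival calibration did not reach tolerance")
  root
}

#' Read species and scenario settings from a YAML or JSON config file
#'
#' The file may define a `species` block (fields matching
#' [species_config()]'s arguments, with `vbgf` as a list `l_inf`, `k`,
#' `a0`) and optional `me_factors` / `gc_shifts` vectors for the scenario
#' grid. Calibrated survival is filled in when `phi` is absent.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `species` (a `ckmr_species`) and
#'   `scenarios` (a tibble from [scenario_grid()]).
#' @export
read_species_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  spc <- cfg$species
  stopifnot(!is.null(spc))
  species <- species_config(
    name = spc$name %||% "custom",
    a_max = spc$a_max, alpha_f = spc$alpha_f, alpha_m = spc$alpha_m,
    litter_sizes = spc$litter_sizes,
    litter_probs = spc$litter_probs,
    gestation_years = spc$gestation_years,
    vbgf = vbgf_params(spc$vbgf$l_inf, spc$vbgf$k, spc$vbgf$a0),
    sigma_l = spc$sigma_l, phi = spc$phi)
  scen <- scenario_grid(
    me_factors = cfg$me_factors %||% c(0.33, 0.67, 1, 1.33, 1.67),
    gc_shifts = cfg$gc_shifts %||% c(-0.10, -0.05, 0, 0.05, 0.10))
  list(species = species, scenarios = scen)
}
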