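#' Kinship kernel: scaled probability that one animal is another's parent
#'
#' Given known birth years, the probability that individual *i* (a
#' potential parent of known sex, captured in year `c_i`) is the parent of
#' an animal born in year `y_j` has the form `m / N_s`, where `N_s` is the
#' adult abundance of the parent's sex and `m` is the multiplier returned
#' here. The multiplier combines a knife-edge maturity indicator, survival
#' of the parent from capture to the year it had to be alive to reproduce,
#' and -- for species with a one-year gestation -- a gestation-survival
#' adjustment:
#'
#' * annual breeders (either sex, maturity `alpha`):
#'   `m = I(y_i + alpha <= y_j) * phi^max(y_j - c_i, 0)`
#' * gestating species, mother: she must have matured by the mating year
#'   `y_j - 1` and survived to the birth itself, and her expected relative
#'   reproductive output is taken among mating females that survive
#'   gestation, contributing a factor `1 / phi`:
#'   `m = I(y_i + alpha_f <= y_j - 1) * phi^{-1} * phi^max(y_j - c_i, 0)`
#' * gestating species, father: he only needs to have been alive (and
#'   mature) in the mating year:
#'   `m = I(y_i + alpha_m <= y_j - 1) * phi^max(y_j - 1 - c_i, 0)`
#'
#' @param y_i Parent's birth year (integer, vectorized).
#' @param c_i Parent's capture year.
#' @param y_j Offspring's birth year.
#' @param parent_sex `"F"` or `"M"` (scalar).
#' @param species A `ckmr_species` object.
#' @param phi Annual survival; defaults to the species' value.
#' @return Numeric vector of multipliers `m >= 0` (at most `1/phi`).
#' @examples
#' sp <- species_complex()
#' # mother born year 9, captured year 45; offspring born year 47:
#' kinship_coefficient(9, 45, 47, "F", sp) # equals phi
#' @export
kinship_coefficient <- function(y_i, c_i, y_j, parent_sex, species,
                                phi = species$phi) {
  stopifnot(parent_sex %in% c("F", "M"))
  alpha <- if (parent_sex == "F") species$alpha_f else species$alpha_m
  if (species$gestation_years == 0L) {
    ind <- (y_i + alpha) <= y_j
    ind * phi^pmax(y_j - c_i, 0)
  } else if (parent_sex == "F") {
    ind <- (y_i + alpha) <= (y_j - 1)
    ind * phi^(pmax(y_j - c_i, 0) - 1)
  } else {
    ind <- (y_i + alpha) <= (y_j - 1)
    ind * phi^pmax(y_j - 1 - c_i, 0)
  }
}

#' Deduplicate pairwise comparisons between sample records
#'
#' Every unordered pair of distinct sample records enters the
#' pseudo-likelihood as one Bernoulli comparison, but two pairs whose
#' records agree on (sex, capture year, measured length) make identical
#' probabilistic statements. This groups records into types on those three
#' observables and counts, for each unordered type pair, the number of
#' record pairs (`n_pairs`) and how many of them are true parent-offspring
#' pairs (`n_pop`). Pairs formed by two captures of the same individual are
#' ordinary non-POP comparisons and are included.
#'
#' @param samples Tibble of sample records (`record`, `id`, `capture_year`,
#'   `sex`, `length`).
#' @param pops Tibble of true POP record pairs (`record_i`, `record_j`),
#'   e.g. from [identify_kinship()].
#' @return A tibble with columns `sex_i`, `c_i`, `len_i`, `sex_j`, `c_j`,
#'   `len_j`, `n_pairs`, `n_pop`; the total of `n_pairs` is
#'   `n (n - 1) / 2`. Attribute `n_records` stores `n`.
#' @export
comparison_counts <- function(samples, pops) {
  stopifnot(nrow(samples) >= 2L)
  types <- dplyr::arrange(
    dplyr::distinct(samples[c("sex", "capture_year", "length")]),
    .data$sex, .data$capture_year, .data$length)
  tcode <- match(
    paste(samples$sex, samples$capture_year, samples$length),
    paste(types$sex, types$capture_year, types$length))
  nt <- nrow(types)
  counts <- tabulate(tcode, nt)

  pair_mat <- tcrossprod(counts)           # n_u * n_v
  diag(pair_mat) <- counts * (counts - 1) / 2
  keep <- upper.tri(pair_mat, diag = TRUE) & pair_mat > 0

  pop_mat <- matrix(0, nt, nt)
  if (nrow(pops) > 0) {
    ti <- tcode[match(pops$record_i, samples$record)]
    tj <- tcode[match(pops$record_j, samples$record)]
    lo <- pmin(ti, tj); hi <- pmax(ti, tj)
    for (k in seq_along(lo)) pop_mat[lo[k], hi[k]] <- pop_mat[lo[k], hi[k]] + 1
  }

  idx <- which(keep, arr.ind = TRUE)
  out <- tibble::tibble(
    sex_i = types$sex[idx[, 1L]],
    c_i = types$capture_year[idx[, 1L]],
    len_i = types$length[idx[, 1L]],
    sex_j = types$sex[idx[, 2L]],
    c_j = types$capture_year[idx[, 2L]],
    len_j = types$length[idx[, 2L]],
    n_pairs = pair_mat[keep],
    n_pop = pop_mat[keep])
  attr(out, "n_records") <- nrow(samples)
  out
}

# Age-marginalized coefficient lookup. For each (parent sex, parent capture
# year, offspring capture year) builds a matrix indexed [offspring length,
# parent length] of
#   A = sum_{a_i, a_j} f(a_i | l_i) f(a_j | l_j) m(c_i - a_i, c_i, c_j - a_j)
# via two small matrix products: the parent-side sum is folded into
# G = t(M) P over a grid of offspring birth years, then the offspring-side
# posterior contracts G over ages.
coefficient_tables <- function(lengths, capture_years, model, species) {
  post <- age_posterior(lengths, model)
  bad <- attr(post, "incompatible")
  post_ok <- post
  post_ok[, bad] <- 0 # incompatible lengths carry no mass; flagged upstream
  ages <- 0:model$a_max
  yj_grid <- (min(capture_years) - model$a_max):max(capture_years)

  tables <- list()
  for (s in c("F", "M")) {
    for (ci in capture_years) {
      M <- outer(ages, yj_grid, function(a, yj)
        kinship_coefficient(ci - a, ci, yj, s, species, model$phi))
      G <- crossprod(M, post_ok)            # [y_j, parent length]
      for (cj in capture_years) {
        rows <- match(cj - ages, yj_grid)
        tables[[paste(s, ci, cj)]] <- crossprod(post_ok, G[rows, , drop = FALSE])
      }
    }
  }
  list(tables = tables, lengths = lengths, incompatible = bad)
}

#' Age-marginalized pair coefficients for one record pair
#'
#' For two sample records, computes the coefficients `(A, B)` such that the
#' probability that the pair is parent-offspring (in either direction) is
#' `A / N_{sex_i} + B / N_{sex_j}`: `A` marginalizes "record i is the
#' parent of record j" over both unknown ages weighted by their length-based
#' posteriors, and `B` the reverse direction.
#'
#' @param record_i,record_j One-row data frames (or named lists) with
#'   fields `sex`, `capture_year`, `length`.
#' @param model A [age_model()] object.
#' @param species A `ckmr_species` object.
#' @return Named numeric vector `c(A = , B = )`.
#' @export
pair_coefficients <- function(record_i, record_j, model, species) {
  lens <- sort(unique(c(record_i$length, record_j$length)))
  cys <- sort(unique(c(record_i$capture_year, record_j$capture_year)))
  ct <- coefficient_tables(lens, cys, model, species)
  li <- match(record_i$length, lens); lj <- match(record_j$length, lens)
  A <- ct$tables[[paste(record_i$sex, record_i$capture_year,
                        record_j$capture_year)]][lj, li]
  B <- ct$tables[[paste(record_j$sex, record_j$capture_year,
                        record_i$capture_year)]][li, lj]
  c(A = unname(A), B = unname(B))
}

#' Aggregated comparison table with precomputed coefficients
#'
#' Combines [comparison_counts()] with the age-marginalized coefficients of
#' every type pair under an assumed observation model. The result is all the
#' estimator needs: the pseudo-log-likelihood is a function of `(N_f, N_m)`
#' only, with the coefficients independent of abundance.
#'
#' @inheritParams comparison_counts
#' @param model A [age_model()] object (the assumed, possibly misspecified,
#'   observation model).
#' @param species A `ckmr_species` object (maturity, gestation and survival
#'   used by the kinship kernels).
#' @param counts Optional precomputed [comparison_counts()] table, to avoid
#'   re-deduplicating when fitting many scenarios to one data set.
#' @return A tibble of class `ckmr_comparisons`: the columns of
#'   [comparison_counts()] plus `A` and `B`. Attributes: `n_records`,
#'   `species` name, `infeasible_lengths` (TRUE when some observed length
#'   has zero marginal probability under `model`).
#' @export
aggregate_comparisons <- function(samples, pops, model, species,
                                  counts = NULL) {
  counts <- counts %||% comparison_counts(samples, pops)
  lens <- sort(unique(c(counts$len_i, counts$len_j)))
  cys <- sort(unique(c(counts$c_i, counts$c_j)))
  ct <- coefficient_tables(lens, cys, model, species)

  li <- match(counts$len_i, lens)
  lj <- match(counts$len_j, lens)
  nr <- nrow(counts)
  A <- B <- numeric(nr)
  key_a <- paste(counts$sex_i, counts$c_i, counts$c_j)
  key_b <- paste(counts$sex_j, counts$c_j, counts$c_i)
  for (k in unique(c(key_a, key_b))) {
    tab <- ct$tables[[k]]
    sel <- key_a == k
    if (any(sel)) A[sel] <- tab[cbind(lj[sel], li[sel])]
    sel <- key_b == k
    if (any(sel)) B[sel] <- tab[cbind(li[sel], lj[sel])]
  }
  out <- dplyr::mutate(counts, A = A, B = B)
  # type pairs with zero coefficients and no observed POP contribute exactly
  # zero to the likelihood at any abundance; drop them but keep the totals
  keep <- out$A > 0 | out$B > 0 | out$n_pop > 0
  total_pairs <- sum(out$n_pairs)
  out <- out[keep, ]
  attr(out, "n_records") <- attr(counts, "n_records")
  attr(out, "n_pairs_total") <- total_pairs
  attr(out, "species") <- species$name
  attr(out, "infeasible_lengths") <- any(ct$incompatible)
  class(out) <- c("ckmr_comparisons", class(out))
  out
}

#' Parent-offspring pseudo-log-likelihood
#'
#' Sum over deduplicated comparisons of independent-Bernoulli log
#' probabilities: each unordered record pair is a POP with probability
#' `P = A / N_{sex_i} + B / N_{sex_j}` (the two directed parent-offspring
#' probabilities are mutually exclusive given the age constraints, so they
#' add). Comparisons are treated as independent even though they are not,
#' hence *pseudo*-likelihood; with sparse sampling this does not affect
#' point estimation.
#'
#' Returns `-Inf` when some observed POP has probability zero under the
#' assumed model (an infeasible likelihood). Proposed abundances so small
#' that some `P >= 1` have the offending probabilities clipped just below
#' one; such excursions can occur during optimization and are harmless away
#' from the optimum.
#'
#' @param N_f,N_m Candidate female / male adult abundance (> 0).
#' @param comparisons A [aggregate_comparisons()] table.
#' @return The pseudo-log-likelihood value (scalar).
#' @export
pseudo_log_likelihood <- function(N_f, N_m, comparisons) {
  stopifnot(N_f > 0, N_m > 0)
  N <- c(F = unname(N_f), M = unname(N_m))
  P <- comparisons$A / N[comparisons$sex_i] +
    comparisons$B / N[comparisons$sex_j]
  w <- comparisons$n_pop
  if (any(w > 0 & P <= 0)) return(-Inf)
  P <- pmin(P, 1 - 1e-9)
  pos <- P > 0
  sum(w[pos] * log(P[pos])) +
    sum((comparisons$n_pairs - comparisons$n_pop) * log1p(-P))
}
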