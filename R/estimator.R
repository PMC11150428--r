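#' 95% log-normal confidence interval
#'
#' The standard log-normal interval for a positive parameter:
#' \deqn{C = \exp\left(z_{1-(1-level)/2} \sqrt{\ln(1 + (se/\hat N)^2)}\right)}
#' with bounds \eqn{(\hat N / C, \hat N \times C)}. The interval is
#' multiplicatively symmetric about the point estimate and collapses to the
#' point as the standard error goes to zero.
#'
#' @param point Point estimate(s), > 0.
#' @param se Standard error(s) on the same scale, >= 0.
#' @param level Coverage level (default 0.95).
#' @return A tibble with columns `lower` and `upper`.
#' @examples
#' lognormal_ci(1000, 200)
#' @export
lognormal_ci <- function(point, se, level = 0.95) {
  stopifnot(all(point > 0), all(se >= 0), level > 0, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  C <- exp(z * sqrt(log1p((se / point)^2)))
  tibble::tibble(lower = point / C, upper = point * C)
}

# Central finite-difference Hessian of `fn` at `x` (step on the log scale).
fd_hessian <- function(fn, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h)
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h^2
    if (i < p) {
      for (j in (i + 1):p) {
        ej <- replace(numeric(p), j, h)
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

failed_fit <- function(reason, comparisons) {
  structure(
    list(estimate = c(N_f = NA_real_, N_m = NA_real_),
         se = c(N_f = NA_real_, N_m = NA_real_),
         ci = tibble::tibble(sex = c("F", "M"), lower = NA_real_,
                             upper = NA_real_),
         loglik = NA_real_, converged = FALSE, failure_reason = reason,
         n_pop = sum(comparisons$n_pop),
         n_pairs = total_pair_count(comparisons)),
    class = "ckmr_fit")
}

total_pair_count <- function(comparisons) {
  attr(comparisons, "n_pairs_total") %||% sum(comparisons$n_pairs)
}

#' Fit the parent-offspring CKMR model
#'
#' Maximizes the pseudo-log-likelihood over `(log N_f, log N_m)` by
#' quasi-Newton (BFGS) iteration, with a short ladder of alternative
#' starting values before declaring failure. Standard errors come from the
#' inverse of the negative Hessian (central finite differences on the log
#' scale) transformed to the abundance scale by the delta method
#' (`Var(N) = N^2 Var(log N)`); 95% intervals are log-normal.
#'
#' The fit is declared non-converged -- recorded, never raised -- when the
#' likelihood is infeasible (an observed length impossible under the
#' assumed model, or a true POP with zero pair probability, or no POP
#' information for one sex), when the optimizer fails or runs away to
#' unbounded abundance, or when the Hessian at the optimum is not positive
#' definite.
#'
#' @param comparisons A [aggregate_comparisons()] table.
#' @param start Optional starting abundances `c(N_f, N_m)`; defaults to
#'   twice the number of sample records for each sex.
#' @param level Confidence level for the intervals.
#' @return An object of class `ckmr_fit` with elements `estimate`, `se`,
#'   `ci`, `loglik`, `converged`, `failure_reason`, `n_pop`, `n_pairs`.
#'   Use [generics::tidy()] / [generics::glance()] for tibble views.
#' @export
fit_ckmr <- function(comparisons, start = NULL, level = 0.95) {
  stopifnot(inherits(comparisons, "ckmr_comparisons"))

  if (isTRUE(attr(comparisons, "infeasible_lengths"))) {
    return(failed_fit("infeasible_likelihood", comparisons))
  }
  w <- comparisons$n_pop
  if (any(w > 0 & comparisons$A + comparisons$B <= 0)) {
    return(failed_fit("infeasible_likelihood", comparisons))
  }
  has_f <- any(w > 0 & ((comparisons$sex_i == "F" & comparisons$A > 0) |
                          (comparisons$sex_j == "F" & comparisons$B > 0)))
  has_m <- any(w > 0 & ((comparisons$sex_i == "M" & comparisons$A > 0) |
                          (comparisons$sex_j == "M" & comparisons$B > 0)))
  if (!has_f || !has_m) {
    return(failed_fit("infeasible_likelihood", comparisons))
  }

  # fast objective on plain vectors; the exported pseudo_log_likelihood()
  # computes the same quantity and the suite checks them against each other
  A <- as.numeric(comparisons$A); B <- as.numeric(comparisons$B)
  Af <- A * (comparisons$sex_i == "F"); Am <- A - Af
  Bf <- B * (comparisons$sex_j == "F"); Bm <- B - Bf
  n_pairs <- as.numeric(comparisons$n_pairs)
  w_pop <- as.numeric(comparisons$n_pop)
  idx_w <- which(w_pop > 0)
  non_pop <- n_pairs - w_pop
  cache <- new.env(parent = emptyenv()); cache$theta <- c(NA_real_, NA_real_)
  eval_parts <- function(theta) {
    if (identical(theta, cache$theta)) return(invisible(NULL))
    inv_f <- exp(-theta[1L]); inv_m <- exp(-theta[2L])
    Pf <- Af * inv_f + Bf * inv_f
    Pm <- Am * inv_m + Bm * inv_m
    P <- pmin(Pf + Pm, 1 - 1e-9)
    cache$theta <- theta; cache$Pf <- Pf; cache$Pm <- Pm; cache$P <- P
    invisible(NULL)
  }
  nll <- function(theta) {
    eval_parts(theta)
    P <- cache$P
    if (any(P[idx_w] <= 0)) return(1e12)
    v <- -(sum(w_pop[idx_w] * log(P[idx_w])) + sum(non_pop * log1p(-P)))
    if (!is.finite(v)) 1e12 else v
  }
  # analytic gradient: dP/dlog N_s = -(share of P carried by N_s), so
  # dl/dlog N_s = sum [w/P - (n-w)/(1-P)] * P_s
  ngr <- function(theta) {
    eval_parts(theta)
    P <- cache$P
    core <- -non_pop / (1 - P)
    core[idx_w] <- core[idx_w] + w_pop[idx_w] / pmax(P[idx_w], 1e-300)
    c(sum(core * cache$Pf), sum(core * cache$Pm))
  }
  n0 <- start %||% rep(2 * attr(comparisons, "n_records"), 2L)
  starts <- lapply(c(1, 5, 0.2, 25), function(f) log(n0 * f))

  opt <- NULL
  for (th0 in starts) {
    cand <- tryCatch(
      optim(th0, nll, gr = ngr, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    ok <- !is.null(cand) && cand$convergence == 0 &&
      is.finite(cand$value) && cand$value < 1e11 &&
      all(cand$par < log(1e8))
    if (ok) { opt <- cand; break }
  }
  if (is.null(opt)) return(failed_fit("optimizer_failure", comparisons))

  H <- fd_hessian(nll, opt$par)
  ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  if (any(!is.finite(ev)) || any(ev <= 0)) {
    return(failed_fit("optimizer_failure", comparisons))
  }
  V <- solve(H)
  se_log <- sqrt(diag(V))
  N_hat <- exp(opt$par)
  se <- N_hat * se_log
  ci <- lognormal_ci(N_hat, se, level)

  structure(
    list(estimate = c(N_f = N_hat[1L], N_m = N_hat[2L]),
         se = c(N_f = se[1L], N_m = se[2L]),
         ci = tibble::tibble(sex = c("F", "M"), lower = ci$lower,
                             upper = ci$upper),
         loglik = -opt$value, converged = TRUE, failure_reason = "none",
         n_pop = sum(comparisons$n_pop),
         n_pairs = total_pair_count(comparisons)),
    class = "ckmr_fit")
}

#' @export
print.ckmr_fit <- function(x, ...) {
  cat("CKMR parent-offspring pair fit\n")
  if (!x$converged) {
    cat(sprintf("  did not converge (%s); %d POPs among %d comparisons\n",
                x$failure_reason, x$n_pop, x$n_pairs))
    return(invisible(x))
  }
  cat(sprintf("  N_f = %.1f (SE %.1f, 95%% CI %.1f-%.1f)\n",
              x$estimate["N_f"], x$se["N_f"], x$ci$lower[1L], x$ci$upper[1L]))
  cat(sprintf("  N_m = %.1f (SE %.1f, 95%% CI %.1f-%.1f)\n",
              x$estimate["N_m"], x$se["N_m"], x$ci$lower[2L], x$ci$upper[2L]))
  cat(sprintf("  log-likelihood %.2f; %d POPs among %d comparisons\n",
              x$loglik, x$n_pop, x$n_pairs))
  invisible(x)
}

#' Tidy a CKMR fit
#'
#' @param x A `ckmr_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`N_f`, `N_m`): `term`,
#'   `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.ckmr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("N_f", "N_m"),
    estimate = unname(x$estimate),
    std.error = unname(x$se),
    conf.low = x$ci$lower,
    conf.high = x$ci$upper)
}

#' One-row summary of a CKMR fit
#'
#' @param x A `ckmr_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `logLik`, `converged`, `failure_reason`,
#'   `n_pop`, `n_pairs`.
#' @export
glance.ckmr_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 failure_reason = x$failure_reason,
                 n_pop = x$n_pop, n_pairs = x$n_pairs)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
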