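#' Write a simulation to plain-text files
#'
#' Writes `samples.csv` (one capture record per row), `pops.csv` (true
#' parent-offspring record pairs), `truth.csv` (yearly abundance), and
#' `manifest.json` recording the seed and the full species configuration --
#' including the calibrated survival probability -- so every downstream
#' artifact can be traced to its generating parameters.
#'
#' @param sim A `ckmr_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "ckmr_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$pops, file.path(dir, "pops.csv"), row.names = FALSE)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  sp <- sim$species
  manifest <- list(
    seed = sim$seed, species = sp$name, a_max = sp$a_max,
    alpha_f = sp$alpha_f, alpha_m = sp$alpha_m,
    litter_sizes = sp$litter_sizes, litter_probs = sp$litter_probs,
    gestation_years = sp$gestation_years, phi = sp$phi,
    vbgf = list(l_inf = sp$vbgf$l_inf, k = sp$vbgf$k, a0 = sp$vbgf$a0),
    sigma_l = sp$sigma_l, growth_rate = sim$growth_rate,
    n_recaptured = sim$n_recaptured)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulation written by [write_sim_output()]
#'
#' Reconstructs the sample, POP-pair and truth tables plus the species
#' configuration from a directory of plain-text outputs. The individual
#' pedigree itself is not stored, so the returned object supports fitting
#' (which only needs samples, POP pairs and truth) but not re-running
#' kinship identification.
#'
#' @param dir Directory containing the four files.
#' @return A `ckmr_sim` object.
#' @export
read_sim_output <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  species <- species_config(
    name = man$species, a_max = man$a_max, alpha_f = man$alpha_f,
    alpha_m = man$alpha_m, litter_sizes = man$litter_sizes,
    litter_probs = man$litter_probs, gestation_years = man$gestation_years,
    vbgf = vbgf_params(man$vbgf$l_inf, man$vbgf$k, man$vbgf$a0),
    sigma_l = man$sigma_l, phi = man$phi)
  samples <- tibble::as_tibble(utils::read.csv(file.path(dir, "samples.csv")))
  structure(
    list(samples = samples,
         pops = tibble::as_tibble(utils::read.csv(file.path(dir, "pops.csv"))),
         truth = tibble::as_tibble(utils::read.csv(file.path(dir, "truth.csv"))),
         growth_rate = man$growth_rate, n_recaptured = man$n_recaptured,
         species = species, seed = man$seed),
    class = "ckmr_sim")
}
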