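## Default ligand panels and population sets. The original figure panels are
## shown only graphically, so these are representative panels spanning the
## relevant regimes (affinity decades for the monomeric model; bound-fraction
## deciles for the homodimer; occupancy extremes for the heterodimer), chosen
## from the model structure rather than fitted to any output. Rationale in
## the methods vignette.

#' Monomeric affinity panel
#'
#' Five ligands at unit concentration with affinities log-spaced over four
#' decades. In the monomeric model they differ in mean occupancy but induce
#' identical response heterogeneity.
#'
#' @param n Panel size.
#' @param range Affinity range (per ACU).
#' @return List of [ligand_params()].
#' @export
al_affinity_panel <- function(n = 5, range = c(1e-2, 1e2)) {
  ks <- log_space(range[1], range[2], n)
  lapply(seq_len(n), function(i)
    ligand_params(conc = 1, K_P = ks[i], K_F = 1, id = paste0("L", i)))
}

#' Homodimer bound-fraction panel
#'
#' Ligands at the partial-binding EC50 (`K_P*C = 1`) whose full-complex
#' affinities are chosen so the bound fraction `2F/A0` at the reference cell
#' (`A0 = A0_ref`) hits the requested values: from `f`, free subunits are
#' `A = A0(1-f)/2`, so `K_F = 2f / (A0 (1-f)^2)`. The extremes `f = 0` and
#' `f = 1` are unattainable limits, so the default panel spans the symmetric
#' deciles 0.1--0.9.
#'
#' @param f Target bound fractions in (0, 1).
#' @param A0_ref Reference receptor total.
#' @return List of [ligand_params()].
#' @export
ala_bound_fraction_panel <- function(f = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                     A0_ref = 1) {
  stopifnot(all(f > 0), all(f < 1))
  lapply(seq_along(f), function(i)
    ligand_params(conc = 1, K_P = 1,
                  K_F = 2 * f[i] / (A0_ref * (1 - f[i])^2),
                  id = sprintf("f%02d", round(100 * f[i]))))
}

#' Heterodimer occupancy panel
#'
#' Three ligands spanning the sub-saturated, intermediate and saturated
#' occupancy regimes of the sequential heterodimer.
#'
#' @return List of [ligand_params()].
#' @export
alb_occupancy_panel <- function() {
  list(ligand_params(conc = 1, K_P = 0.01, K_F = 0.001, id = "weak"),
       ligand_params(conc = 1, K_P = 1, K_F = 1, id = "mid"),
       ligand_params(conc = 1, K_P = 100, K_F = 100, id = "saturating"))
}

#' Four-population heterodimer set
#'
#' Two-subunit gamma populations probing how subunit imbalance and
#' variability shape ligand-dependent heterogeneity:
#' \describe{
#'   \item{balanced}{A and B both mean 1, sd 0.5.}
#'   \item{abundant_tight}{B 100-fold more abundant but tightly expressed.}
#'   \item{both_variable}{B abundant and variable, A also variable.}
#'   \item{abundant_variable}{B abundant and highly variable, A tight ---
#'     the regime with the widest ligand-dependent CV spread.}
#' }
#'
#' @param n_cells Cells per population.
#' @param seed Base seed (populations use consecutive seeds).
#' @return Named list of [population_spec()]s.
#' @export
heterodimer_population_set <- function(n_cells = 1e5, seed = 101L) {
  list(
    balanced = population_spec(n_cells, mean = c(1, 1), sd = c(0.5, 0.5),
                               seed = seed),
    abundant_tight = population_spec(n_cells, mean = c(1, 100), sd = c(0.5, 5),
                                     seed = seed + 1L),
    both_variable = population_spec(n_cells, mean = c(1, 100), sd = c(0.5, 75),
                                    seed = seed + 2L),
    abundant_variable = population_spec(n_cells, mean = c(1, 100),
                                        sd = c(0.05, 75), seed = seed + 3L))
}
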