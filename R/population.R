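## Heterogeneous cell populations: receptor totals drawn per cell from a
## gamma distribution parameterized by mean and standard deviation (moment
## matching: shape = (mean/sd)^2, scale = sd^2/mean). Heterogeneity of the
## response is summarized by the coefficient of variation CV = sd/mean.

#' Population specification
#'
#' @param n_cells Number of cells (default 100,000, the size used for the
#'   main population experiments; smaller populations are configurable).
#' @param mean,sd Gamma mean and standard deviation per receptor subunit
#'   (ARU). Length 1 for single-subunit models, length 2 (`A`, `B`) for
#'   heterodimers. `sd = 0` gives a constant population.
#' @param seed Integer RNG seed; draws are reproducible given the seed.
#' @return An object of class `population_spec`.
#' @examples
#' population_spec(1e4, mean = 1, sd = 0.5, seed = 1)
#' @export
population_spec <- function(n_cells = 1e5, mean = 1, sd = 0.5, seed = 1L) {
  stopifnot(is.numeric(n_cells), length(n_cells) == 1L, n_cells >= 1,
            is.numeric(mean), length(mean) %in% 1:2, all(mean > 0),
            is.numeric(sd), length(sd) == length(mean), all(sd >= 0),
            is.numeric(seed), length(seed) == 1L)
  structure(list(n_cells = as.integer(n_cells), mean = mean, sd = sd,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Gamma parameters implied by a population spec
#'
#' Moment matching: `shape = (mean/sd)^2`, `scale = sd^2/mean`.
#'
#' @param mean,sd Positive mean, non-negative sd.
#' @return List with `shape` and `scale` (both `Inf`-safe: `sd = 0` is the
#'   degenerate point mass and is handled by the sampler, not here).
#' @export
gamma_moments <- function(mean, sd) {
  stopifnot(all(mean > 0), all(sd >= 0))
  list(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Draw per-cell receptor totals
#'
#' Independent gamma draws per subunit (no A/B correlation by default; an
#' optional Gaussian-copula correlation is exposed because subunit
#' covariance is not otherwise constrained).
#'
#' @param spec A [population_spec()].
#' @param correlation Optional rank correlation between A and B draws for
#'   two-subunit specs (Gaussian copula), in `(-1, 1)`. Default 0.
#' @return A data frame with column `A0` (and `B0` for two-subunit specs),
#'   one row per cell.
#' @export
sample_receptors <- function(spec, correlation = 0) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  ns <- length(spec$mean)
  draw <- function(q, m, s) {
    if (s == 0) return(rep(m, length(q)))
    gm <- gamma_moments(m, s)
    stats::qgamma(q, shape = gm$shape, scale = gm$scale)
  }
  if (ns == 1L) {
    q <- stats::runif(spec$n_cells)
    return(data.frame(A0 = draw(q, spec$mean[1L], spec$sd[1L])))
  }
  z1 <- stats::rnorm(spec$n_cells)
  z2 <- stats::rnorm(spec$n_cells)
  zb <- correlation * z1 + sqrt(1 - correlation^2) * z2
  data.frame(A0 = draw(stats::pnorm(z1), spec$mean[1L], spec$sd[1L]),
             B0 = draw(stats::pnorm(zb), spec$mean[2L], spec$sd[2L]))
}

population_stats <- function(E) {
  m <- base::mean(E)
  s <- stats::sd(E)
  list(mean = m, sd = s, cv = if (m > 0) s / m else NA_real_)
}

#' Simulate the response of a heterogeneous population
#'
#' All cells see the same ligand concentration (well-mixed medium); each
#' cell's equilibrium is solved at its own receptor totals and the response
#' `E = e * F^n` recorded.
#'
#' @param model Model kind with a closed-form solver (for competition use
#'   [simulate_population_competition()]).
#' @param ligand A [ligand_params()].
#' @param spec A [population_spec()].
#' @param n Response exponent.
#' @param cells Optional pre-drawn receptor data frame (from
#'   [sample_receptors()]); when supplied the spec's seed is not used, which
#'   lets several ligands share the same cells.
#' @return An object of class `population_response`: per-cell responses `E`,
#'   `mean`, `sd`, `cv` (`NA` with a flag when the response is identically
#'   zero, e.g. at `C = 0`), the ligand and spec echoes.
#' @export
simulate_population <- function(model, ligand, spec, n = 1, cells = NULL) {
  model <- model_kind(model)
  if (is.null(cells)) cells <- sample_receptors(spec)
  hetero <- is_heterodimeric(model)
  if (hetero && is.null(cells$B0))
    stop("heterodimeric models need a two-subunit population spec")
  FF <- complexes_for_cells(model, ligand, cells$A0,
                            if (hetero) cells$B0 else NULL)
  E <- ligand$activity * FF^n
  st <- population_stats(E)
  structure(list(E = E, mean = st$mean, sd = st$sd, cv = st$cv,
                 all_zero = all(E == 0), ligand = ligand, spec = spec,
                 model = model, n = n),
            class = "population_response")
}

#' @export
print.population_response <- function(x, ...) {
  cat(sprintf("population response (%s, %d cells): mean %.6g, sd %.6g, CV %s\n",
              x$model, length(x$E), x$mean, x$sd,
              if (is.na(x$cv)) "undefined (all-zero response)"
              else sprintf("%.6g", x$cv)))
  invisible(x)
}

#' Match a ligand's activity rate to a target population mean response
#'
#' Because the response is proportional to the activity rate, setting
#' `e = target / mean(F^n)` over the population makes the matched mean
#' exact. Used to compare heterogeneity across ligands at identical mean
#' activity.
#'
#' @inheritParams simulate_population
#' @param target_mean Desired population mean response, positive.
#' @return The ligand with its `activity` replaced by the matched rate.
#' @export
match_mean_activity <- function(model, ligand, spec, target_mean = 1, n = 1,
                                cells = NULL) {
  stopifnot(target_mean > 0)
  model <- model_kind(model)
  if (is.null(cells)) cells <- sample_receptors(spec)
  hetero <- is_heterodimeric(model)
  FF <- complexes_for_cells(model, ligand, cells$A0,
                            if (hetero) cells$B0 else NULL)
  mF <- base::mean(FF^n)
  if (mF <= 0)
    stop("cannot match the mean: no complexes form for ligand ",
         if (is.null(ligand$id)) "<unnamed>" else ligand$id)
  ligand$activity <- target_mean / mF
  ligand
}

#' Compare response heterogeneity across a ligand panel
#'
#' All ligands are applied to the same receptor sample (same seed), with
#' each activity rate matched so the population mean response equals
#' `target_mean`; this isolates ligand effects on heterogeneity from
#' sampling noise and from mean differences.
#'
#' @param model Model kind.
#' @param ligands List of [ligand_params()] (>= 2), ideally with `id`s.
#' @param spec A [population_spec()].
#' @param target_mean Common population mean response.
#' @param n Response exponent.
#' @return A data frame with one row per ligand: `ligand`, matched
#'   `activity`, `mean`, `sd`, `cv`, and `scaling_at_mean` (local scaling at
#'   the mean-receptor cell). The max/min CV ratio is attached as attribute
#'   `cv_ratio`.
#' @export
compare_ligands <- function(model, ligands, spec, target_mean = 1, n = 1) {
  stopifnot(length(ligands) >= 2L)
  model <- model_kind(model)
  cells <- sample_receptors(spec)
  hetero <- is_heterodimeric(model)
  mean_cell <- receptor_config(spec$mean[1L],
                               if (hetero) spec$mean[2L] else NA_real_)
  rows <- lapply(seq_along(ligands), function(i) {
    lig <- match_mean_activity(model, ligands[[i]], spec, target_mean,
                               n = n, cells = cells)
    pr <- simulate_population(model, lig, spec, n = n, cells = cells)
    S <- local_scaling(model, lig, mean_cell, "A", n = n)$S
    if (hetero) S <- S + local_scaling(model, lig, mean_cell, "B", n = n)$S
    data.frame(ligand = if (is.null(lig$id)) paste0("L", i) else lig$id,
               activity = lig$activity, mean = pr$mean, sd = pr$sd,
               cv = pr$cv, scaling_at_mean = S)
  })
  out <- do.call(rbind, rows)
  attr(out, "cv_ratio") <- max(out$cv) / min(out$cv)
  out
}

#' Heterodimer population experiment
#'
#' For each cell population (its own two-subunit gamma spec) and each
#' ligand, the activity rate is matched so the population mean response is
#' `target_mean`, and the response CV is recorded. The ligand-to-ligand CV
#' spread within a population is largest when the subunit means are
#' imbalanced and the abundant subunit is the more variable one.
#'
#' @param populations Named list of two-subunit [population_spec()]s.
#' @param ligands List of [ligand_params()] spanning occupancy regimes.
#' @param target_mean Common population mean response.
#' @param n Response exponent.
#' @return A data frame with columns `population`, `ligand`, `mean`, `sd`,
#'   `cv`; per-population max/min CV ratios are attached as attribute
#'   `cv_ratio` (named numeric vector).
#' @export
heterodimer_population_experiment <- function(populations, ligands,
                                              target_mean = 1, n = 1) {
  stopifnot(is.list(populations), length(populations) >= 1L,
            is.list(ligands), length(ligands) >= 1L)
  if (is.null(names(populations)))
    names(populations) <- paste0("pop", seq_along(populations))
  rows <- list()
  for (pn in names(populations)) {
    spec <- populations[[pn]]
    if (length(spec$mean) != 2L)
      stop("population '", pn, "' must specify both subunits")
    cells <- sample_receptors(spec)
    for (i in seq_along(ligands)) {
      lig <- match_mean_activity("ALB_SEQ", ligands[[i]], spec, target_mean,
                                 n = n, cells = cells)
      pr <- simulate_population("ALB_SEQ", lig, spec, n = n, cells = cells)
      rows[[length(rows) + 1L]] <- data.frame(
        population = pn,
        ligand = if (is.null(lig$id)) paste0("L", i) else lig$id,
        mean = pr$mean, sd = pr$sd, cv = pr$cv)
    }
  }
  out <- do.call(rbind, rows)
  ratios <- vapply(split(out$cv, out$population),
                   function(v) max(v) / min(v), numeric(1))
  attr(out, "cv_ratio") <- ratios[unique(out$population)]
  out
}

#' Population response under activator/inhibitor competition
#'
#' Per-cell equilibria of the competition network (activator + zero-activity
#' inhibitor sharing the A pool), solved with the vectorized network Newton
#' iteration. The response counts only the activator's full complexes.
#'
#' @inheritParams build_competition_network
#' @param spec A single-subunit [population_spec()].
#' @param n Response exponent.
#' @param cells Optional pre-drawn receptor sample.
#' @return A `population_response` for the activator's response
#'   `E = e_L * F_L^n`.
#' @export
simulate_population_competition <- function(activator, inhibitor, spec,
                                            n = 1, cells = NULL) {
  if (is.null(cells)) cells <- sample_receptors(spec)
  net <- build_competition_network(activator, inhibitor, receptor_config(1))
  amt <- solve_network_1d_many(net, cells$A0)
  E <- activator$activity * amt["F_L", ]^n
  st <- population_stats(E)
  structure(list(E = E, mean = st$mean, sd = st$sd, cv = st$cv,
                 all_zero = all(E == 0), ligand = activator, spec = spec,
                 model = "COMPETITION", n = n),
            class = "population_response")
}

#' Activator concentration holding the complex amount fixed
#'
#' Finds the activator concentration `C_L` at which the activator's
#' full-complex amount at the reference cell equals `target_F`, given the
#' inhibitor setting. Used to walk constant-complex paths along which the
#' inhibitor tunes heterogeneity.
#'
#' @inheritParams build_competition_network
#' @param target_F Desired `F_L` at the reference cell; must be attainable
#'   (below the saturation value `A0/2`).
#' @param interval Log10 search interval for `C_L`.
#' @return The matching concentration.
#' @export
hold_complex_constant <- function(activator, inhibitor, receptors, target_F,
                                  interval = c(-9, 9)) {
  FL_of <- function(log10C) {
    a <- activator; a$conc <- 10^log10C
    st <- solve_equilibrium(build_competition_network(a, inhibitor, receptors))
    st$species[["F_L"]]
  }
  # the dose-response is non-monotonic (hook effect), so both interval ends
  # can sit below the target; locate the peak and root on the rising branch,
  # where the bracket is guaranteed to change sign when the target is
  # attainable
  peak <- stats::optimize(FL_of, interval, maximum = TRUE, tol = 1e-6)
  if (peak$objective < target_F)
    stop("target_F = ", target_F, " is not attainable: the maximum complex ",
         "amount over the search interval is ", signif(peak$objective, 6))
  root <- stats::uniroot(function(x) FL_of(x) - target_F,
                         c(interval[1L], peak$maximum), tol = 1e-12)
  10^root$root
}

#' Constant-complex inhibitor path
#'
#' For each inhibitor concentration, adjusts the activator concentration so
#' the activator's complex amount at the mean-receptor cell stays at
#' `target_F`, then records the population CV and the local scaling at the
#' mean cell. On the inhibitor's rising-occupancy branch (below its own
#' hook-effect peak, `K_P * C_I` of order 1) the total bound fraction rises
#' with the inhibitor, so the scaling and the population heterogeneity
#' fall; beyond the peak, inhibitor partials displace its full complexes
#' and both recover part-way.
#'
#' @param activator Activator [ligand_params()] (its `conc` is overridden
#'   along the path).
#' @param inhibitor Inhibitor [ligand_params()]; its `conc` field is
#'   replaced by each value of `C_I`.
#' @param C_I Increasing vector of inhibitor concentrations.
#' @param spec Single-subunit [population_spec()].
#' @param target_F Complex amount held fixed at the mean cell.
#' @param n Response exponent.
#' @return Data frame with `C_I`, matched `C_L`, `S` (scaling at the mean
#'   cell) and population `cv`.
#' @export
inhibitor_tuning_path <- function(activator, inhibitor, C_I, spec,
                                  target_F, n = 1) {
  cells <- sample_receptors(spec)
  ref <- receptor_config(spec$mean[1L])
  rows <- lapply(C_I, function(ci) {
    inh <- inhibitor; inh$conc <- ci
    cl <- hold_complex_constant(activator, inh, ref, target_F)
    act <- activator; act$conc <- cl
    S <- competition_scaling(act, inh, ref, n = n)$S
    pr <- simulate_population_competition(act, inh, spec, n = n, cells = cells)
    data.frame(C_I = ci, C_L = cl, S = S, cv = pr$cv)
  })
  do.call(rbind, rows)
}
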