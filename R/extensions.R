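## Robustness extensions: ligand-dependent receptor turnover, finite
## (depletable) ligand pools, and power-law downstream responses.

#' Receptor turnover parameters
#'
#' Minimal production/first-order-degradation scheme: subunits are produced
#' at a constant rate and every species is degraded first-order, with
#' complexes (ligand-bound species) optionally removed faster than free
#' subunits. The receptor total becomes an emergent steady-state quantity
#' rather than a fixed conservation total.
#'
#' @param production Subunit production rate (ARU/time), non-negative. For
#'   heterodimers this is the A-subunit rate.
#' @param deg_free Degradation rate of free subunits (1/time), positive.
#' @param deg_complex Degradation rate of full complexes (1/time), positive.
#' @param production_B B-subunit production rate (heterodimers only).
#' @return An object of class `turnover_params`.
#' @export
turnover_params <- function(production, deg_free, deg_complex,
                            production_B = production) {
  stopifnot(production >= 0, deg_free > 0, deg_complex > 0, production_B >= 0)
  structure(list(production = production, deg_free = deg_free,
                 deg_complex = deg_complex, production_B = production_B),
            class = "turnover_params")
}

#' Steady state with ligand-dependent receptor turnover
#'
#' Binding/unbinding is fast relative to turnover, so species stay on the
#' binding equilibrium manifold while production balances degradation:
#' for single-subunit models
#' `production = deg_free*A + deg_P*P + 2*deg_complex*F` (each full complex
#' carries two subunits), which is a quadratic in free `A` of the same form
#' as the fixed-total models. With uniform degradation the model reduces
#' exactly to the fixed-total model with `A0 = production/deg`.
#'
#' @param model Model kind (closed-form architectures).
#' @param ligand A [ligand_params()].
#' @param turnover A [turnover_params()].
#' @param partial_rate Whether partial complexes degrade at the complex rate
#'   (default) or the free-subunit rate.
#' @return An `equilibrium_state`; the emergent receptor total(s) are
#'   attached as attribute `emergent_total`.
#' @export
solve_with_turnover <- function(model, ligand, turnover,
                                partial_rate = c("complex", "free")) {
  model <- model_kind(model)
  partial_rate <- match.arg(partial_rate)
  stopifnot(inherits(turnover, "turnover_params"))
  kpc <- ligand$K_P * ligand$conc
  df <- turnover$deg_free; dc <- turnover$deg_complex
  dp <- if (partial_rate == "complex") dc else df
  beta <- turnover$production

  st <- switch(model,
    AL = {
      # beta = df*A + dc*F, F = kpc*A
      A <- beta / (df + dc * kpc)
      FF <- kpc * A
      new_equilibrium_state(c(A = A, F = FF),
                            c(A = rel_residual(df * A + dc * FF, beta)), model)
    },
    ALA = ,
    LAAL = {
      phi <- if (model == "ALA") ligand$K_F * kpc else ligand$K_F * kpc^2
      # beta = A*(df + dp*kpc) + 2*dc*phi*A^2
      b <- df + dp * kpc
      A <- 2 * beta / (b + sqrt(b * b + 8 * dc * phi * beta))
      P <- kpc * A
      FF <- phi * A * A
      new_equilibrium_state(
        c(A = A, P = P, F = FF),
        c(A = rel_residual(df * A + dp * P + 2 * dc * FF, beta)), model)
    },
    ALB_SEQ = {
      betaB <- turnover$production_B
      # A*(df + dp*kpc) + dc*F = beta ; df*B + dc*F = betaB ; F = K_F*kpc*A*B
      # => G = dc*F solves G = alpha*(beta - G)*(betaB - G)
      alpha <- dc * ligand$K_F * kpc / ((df + dp * kpc) * df)
      G <- alb_complex_kernel(alpha, beta, betaB)
      FF <- G / dc
      A <- (beta - G) / (df + dp * kpc)
      B <- (betaB - G) / df
      P <- kpc * A
      new_equilibrium_state(
        c(A = A, B = B, P = P, F = FF),
        c(A = rel_residual((df + dp * kpc) * A + dc * FF, beta),
          B = rel_residual(df * B + dc * FF, betaB)), model)
    },
    stop("turnover model not implemented for ", model))
  totals <- switch(model,
    AL = sum(st$species[c("A", "F")]),
    ALB_SEQ = c(A = sum(st$species[c("A", "P", "F")]),
                B = sum(st$species[c("B", "F")])),
    st$species[["A"]] + st$species[["P"]] + 2 * st$species[["F"]])
  attr(st, "emergent_total") <- totals
  st
}

#' Scaling against the production rate under turnover
#'
#' With turnover, the cell-intrinsic quantity is the production rate, so the
#' scaling is the logarithmic derivative of the response with respect to it
#' (per subunit for heterodimers).
#'
#' @inheritParams solve_with_turnover
#' @param subunit `"A"`, `"B"` or `"both"` (heterodimers only beyond "A").
#' @param h Finite-difference step.
#' @param n Response exponent.
#' @return A `scaling_result`.
#' @export
local_scaling_turnover <- function(model, ligand, turnover,
                                   subunit = c("A", "B", "both"),
                                   partial_rate = c("complex", "free"),
                                   h = 1e-4, n = 1) {
  model <- model_kind(model)
  subunit <- match.arg(subunit)
  partial_rate <- match.arg(partial_rate)
  if (subunit != "A" && model != "ALB_SEQ")
    stop("subunit '", subunit, "' requires the heterodimeric model")
  f_at <- function(fac) {
    tp <- turnover
    if (subunit %in% c("A", "both")) tp$production <- tp$production * fac
    if (subunit %in% c("B", "both")) tp$production_B <- tp$production_B * fac
    solve_with_turnover(model, ligand, tp, partial_rate)$species[["F"]]
  }
  F0 <- f_at(1)
  if (F0 <= 0) stop("scaling is undefined: the response is zero at the evaluation point")
  S <- n * (log(f_at(exp(h))) - log(f_at(exp(-h)))) / (2 * h)
  structure(list(S = S, subunit = subunit, bound_fraction = NA_real_,
                 model = paste0(model, "+turnover"), ligand = ligand,
                 receptors = NULL, n = n),
            class = "scaling_result")
}

#' Finite ligand pool
#'
#' @param total Total ligand amount in the cell's reaction volume (ACU),
#'   conserved: free ligand plus ligand in complexes equals the total.
#' @return An object of class `ligand_pool`.
#' @export
ligand_pool <- function(total) {
  stopifnot(is.numeric(total), length(total) == 1L, total >= 0)
  structure(list(total = total), class = "ligand_pool")
}

#' Equilibrium with a depletable ligand pool
#'
#' The ligand becomes a conserved species of the per-cell reaction network
#' (its own conservation law replaces the constant-concentration
#' assumption); solved with the general network solver. As the pool grows
#' the constant-ligand solution is recovered.
#'
#' @param model Model kind (closed-form architectures).
#' @param ligand A [ligand_params()] (its `conc` field is ignored; the pool
#'   supplies the ligand budget).
#' @param receptors A [receptor_config()].
#' @param pool A [ligand_pool()].
#' @return An `equilibrium_state` including the free ligand `L`.
#' @export
solve_finite_ligand <- function(model, ligand, receptors, pool) {
  model <- model_kind(model)
  stopifnot(inherits(pool, "ligand_pool"))
  A0 <- receptors$A0
  net <- switch(model,
    AL = reaction_network(
      list(reaction(c("A", "L"), "F", ligand$K_P)),
      conservation = list(
        conservation_law(c(A = 1, F = 1), A0, "A"),
        conservation_law(c(L = 1, F = 1), pool$total, "L")),
      model = model),
    ALA = reaction_network(
      list(reaction(c("A", "L"), "P", ligand$K_P),
           reaction(c("P", "A"), "F", ligand$K_F)),
      conservation = list(
        conservation_law(c(A = 1, P = 1, F = 2), A0, "A"),
        conservation_law(c(L = 1, P = 1, F = 1), pool$total, "L")),
      model = model),
    LAAL = reaction_network(
      list(reaction(c("A", "L"), "P", ligand$K_P),
           reaction(c("P", "P"), "F", ligand$K_F)),
      conservation = list(
        conservation_law(c(A = 1, P = 1, F = 2), A0, "A"),
        conservation_law(c(L = 1, P = 1, F = 2), pool$total, "L")),
      model = model),
    ALB_SEQ = {
      if (is.na(receptors$B0)) stop("ALB requires B0")
      reaction_network(
        list(reaction(c("A", "L"), "P", ligand$K_P),
             reaction(c("P", "B"), "F", ligand$K_F)),
        conservation = list(
          conservation_law(c(A = 1, P = 1, F = 1), A0, "A"),
          conservation_law(c(B = 1, F = 1), receptors$B0, "B"),
          conservation_law(c(L = 1, P = 1, F = 1), pool$total, "L")),
        model = model)
    },
    stop("finite-ligand model not implemented for ", model))
  solve_equilibrium(net)
}

#' Scaling with a depletable ligand pool
#'
#' Numeric log-derivative of the response with respect to the receptor
#' total, with the per-cell ligand pool held fixed. Unlike the
#' constant-ligand monomeric model, depletion makes the scaling deviate
#' from 1.
#'
#' @inheritParams solve_finite_ligand
#' @param subunit Receptor subunit to perturb.
#' @param h Finite-difference step.
#' @param n Response exponent.
#' @return A `scaling_result`.
#' @export
local_scaling_finite_ligand <- function(model, ligand, receptors, pool,
                                        subunit = c("A", "B", "both"),
                                        h = 1e-4, n = 1) {
  model <- model_kind(model)
  subunit <- match.arg(subunit)
  f_at <- function(fac)
    solve_finite_ligand(model, ligand,
                        perturb_receptors(receptors, subunit, fac),
                        pool)$species[["F"]]
  F0 <- f_at(1)
  if (F0 <= 0) stop("scaling is undefined: the response is zero at the evaluation point")
  S <- n * (log(f_at(exp(h))) - log(f_at(exp(-h)))) / (2 * h)
  structure(list(S = S, subunit = subunit, bound_fraction = NA_real_,
                 model = paste0(model, "+finite_ligand"), ligand = ligand,
                 receptors = receptors, n = n),
            class = "scaling_result")
}

#' Scaling under a power-law downstream response
#'
#' With `E = e * F^n` the chain rule gives `S(n) = n * S(1)`; the scaling
#' shifts away from its linear-readout value but remains independent of the
#' activity rate. This is [local_scaling()] with the exponent made explicit.
#'
#' @inheritParams local_scaling
#' @return A `scaling_result`.
#' @export
scaling_with_nonlinearity <- function(model, ligand, receptors, n,
                                      subunit = "A", h = 1e-4,
                                      extra_affinities = NULL) {
  local_scaling(model, ligand, receptors, subunit = subunit, h = h, n = n,
                extra_affinities = extra_affinities)
}
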