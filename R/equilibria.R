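## Closed-form steady-state solvers under the constant-ligand assumption.
##
## All quadratics are solved with the cancellation-stable form
## x = 2c / (b + sqrt(b^2 + 4ac)) (for a x^2 + b x - c = 0 with a, b, c >= 0),
## which stays accurate when b >> 4ac (low-affinity regimes) and degrades
## gracefully to x = c/b when a = 0.

## Vectorized species kernels -------------------------------------------------
## These accept vector receptor totals so population simulations solve all
## cells at once. `phi` is the coefficient of the quadratic term in free A:
## ALA:  phi = K_F * K_P * C      (F = phi * A^2)
## LAAL: phi = K_F * (K_P * C)^2  (F = phi * A^2)

al_complex_kernel <- function(kc, A0) A0 * kc / (1 + kc)

homodimer_free_A <- function(kpc, phi, A0) {
  # 2*phi*A^2 + (1 + kpc)*A - A0 = 0, positive root
  b <- 1 + kpc
  2 * A0 / (b + sqrt(b * b + 8 * phi * A0))
}

alb_complex_kernel <- function(alpha, A0, B0) {
  # alpha*F^2 - (1 + alpha*(A0+B0))*F + alpha*A0*B0 = 0, smaller root
  b <- 1 + alpha * (A0 + B0)
  cc <- alpha * A0 * B0
  2 * cc / (b + sqrt(pmax(b * b - 4 * alpha * cc, 0)))
}

## Full complex amounts for a whole vector of cells, by architecture.
complexes_for_cells <- function(model, ligand, A0, B0 = NULL) {
  model <- model_kind(model)
  kpc <- ligand$K_P * ligand$conc
  switch(model,
    AL = al_complex_kernel(kpc, A0),
    ALA = {
      phi <- ligand$K_F * kpc
      phi * homodimer_free_A(kpc, phi, A0)^2
    },
    LAAL = {
      phi <- ligand$K_F * kpc^2
      phi * homodimer_free_A(kpc, phi, A0)^2
    },
    ALB_SEQ = {
      if (is.null(B0) || anyNA(B0)) stop("ALB models require B0")
      alpha <- ligand$K_F * kpc / (1 + kpc)
      alb_complex_kernel(alpha, A0, B0)
    },
    stop("no closed-form kernel for model ", model)
  )
}

## Equilibrium state container ------------------------------------------------

new_equilibrium_state <- function(species, residuals, model) {
  structure(list(species = species, residuals = residuals, model = model),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("equilibrium state (%s)\n", x$model))
  print(signif(x$species, 8))
  cat("max |relative residual|:", format(max(abs(x$residuals)), digits = 3), "\n")
  invisible(x)
}

check_domain <- function(ligand, receptors, need_B = FALSE) {
  stopifnot(inherits(ligand, "ligand_params"),
            inherits(receptors, "receptor_config"))
  if (need_B && is.na(receptors$B0))
    stop("this architecture requires a B0 receptor total")
}

rel_residual <- function(lhs, total) (lhs - total) / max(total, .Machine$double.xmin)

#' Monomeric (AL) receptor equilibrium
#'
#' One ligand molecule binds one receptor subunit to form the active complex
#' directly: `F = A0 * K_P*C / (1 + K_P*C)`, the Michaelis--Menten occupancy.
#'
#' @param ligand A [ligand_params()] object (only `conc` and `K_P` are used).
#' @param receptors A [receptor_config()] object; `B0` is ignored.
#' @return An `equilibrium_state` with species `A` (free subunit) and `F`
#'   (full complex), plus the relative conservation residual `A + F - A0`.
#' @examples
#' solve_al(ligand_params(1, 1), receptor_config(1))$species[["F"]] # 0.5
#' @export
solve_al <- function(ligand, receptors) {
  check_domain(ligand, receptors)
  A0 <- receptors$A0
  FF <- al_complex_kernel(ligand$K_P * ligand$conc, A0)
  A <- A0 - FF
  new_equilibrium_state(c(A = A, F = FF),
                        c(A = rel_residual(A + FF, A0)), "AL")
}

#' Homodimeric (ALA) receptor equilibrium
#'
#' A single ligand binds one subunit (partial complex `P = K_P*C*A`), then
#' the partial complex recruits a second identical subunit
#' (`F = K_F*A*P`). Subunit conservation `A + P + 2F = A0` yields a
#' quadratic in free `A`, solved with the cancellation-stable formula.
#'
#' @inheritParams solve_al
#' @return An `equilibrium_state` with species `A`, `P`, `F`.
#' @examples
#' st <- solve_ala(ligand_params(1, 1, K_F = 0.01), receptor_config(1))
#' st$species[["A"]] # ~0.49752
#' @export
solve_ala <- function(ligand, receptors) {
  check_domain(ligand, receptors)
  A0 <- receptors$A0
  kpc <- ligand$K_P * ligand$conc
  phi <- ligand$K_F * kpc
  A <- homodimer_free_A(kpc, phi, A0)
  P <- kpc * A
  FF <- phi * A * A
  new_equilibrium_state(c(A = A, P = P, F = FF),
                        c(A = rel_residual(A + P + 2 * FF, A0)), "ALA")
}

#' Homodimeric two-ligand (LAAL) receptor equilibrium
#'
#' Each partial complex is one ligand bound to one subunit
#' (`P = K_P*C*A`); two partial complexes pair into the full complex
#' (`F = K_F*P^2`). Conservation `A + P + 2F = A0`.
#'
#' @inheritParams solve_al
#' @return An `equilibrium_state` with species `A`, `P`, `F`.
#' @export
solve_laal <- function(ligand, receptors) {
  check_domain(ligand, receptors)
  A0 <- receptors$A0
  kpc <- ligand$K_P * ligand$conc
  phi <- ligand$K_F * kpc^2
  A <- homodimer_free_A(kpc, phi, A0)
  P <- kpc * A
  FF <- phi * A * A
  new_equilibrium_state(c(A = A, P = P, F = FF),
                        c(A = rel_residual(A + P + 2 * FF, A0)), "LAAL")
}

#' Sequential heterodimeric (ALB) receptor equilibrium
#'
#' The ligand binds subunit A first (`P = K_P*C*A`); the partial complex
#' then recruits subunit B (`F = K_F*P*B`). Conservation laws
#' `A(1 + K_P*C) + F = A0` and `B + F = B0` reduce to a quadratic in `F`
#' whose smaller root is the feasible equilibrium
#' (`0 <= F <= min(A0, B0)`).
#'
#' @inheritParams solve_al
#' @param receptors A [receptor_config()] with both `A0` and `B0`.
#' @return An `equilibrium_state` with species `A`, `B`, `P`, `F`.
#' @examples
#' st <- solve_alb_seq(ligand_params(1, 1, 1), receptor_config(1, 1))
#' st$species[["F"]] # 2 - sqrt(3)
#' @export
solve_alb_seq <- function(ligand, receptors) {
  check_domain(ligand, receptors, need_B = TRUE)
  A0 <- receptors$A0; B0 <- receptors$B0
  kpc <- ligand$K_P * ligand$conc
  alpha <- ligand$K_F * kpc / (1 + kpc)
  FF <- alb_complex_kernel(alpha, A0, B0)
  if (FF < 0 || FF > min(A0, B0) * (1 + 1e-12))
    stop("internal consistency error: ALB root outside the feasible box")
  A <- (A0 - FF) / (1 + kpc)
  P <- kpc * A
  B <- B0 - FF
  new_equilibrium_state(
    c(A = A, B = B, P = P, F = FF),
    c(A = rel_residual(A + P + FF, A0), B = rel_residual(B + FF, B0)),
    "ALB_SEQ")
}

#' Solve any closed-form architecture
#'
#' Dispatch on [model_kind()]. The non-sequential heterodimer has no closed
#' form; use [solve_alb_nonseq()].
#'
#' @param model Model kind (see [model_kind()]).
#' @inheritParams solve_alb_seq
#' @return An `equilibrium_state`.
#' @export
solve_model <- function(model, ligand, receptors) {
  switch(model_kind(model),
    AL = solve_al(ligand, receptors),
    ALA = solve_ala(ligand, receptors),
    LAAL = solve_laal(ligand, receptors),
    ALB_SEQ = solve_alb_seq(ligand, receptors),
    ALB_NONSEQ = stop("ALB_NONSEQ has no closed form; use solve_alb_nonseq()"))
}

#' Downstream response of a solved state
#'
#' The response is `E = e * F^n`: full complexes drive target-gene
#' expression at the ligand's activity rate, optionally through a power-law
#' nonlinearity of exponent `n` (cooperative downstream steps).
#'
#' @param state An `equilibrium_state`.
#' @param ligand The [ligand_params()] supplying the activity rate `e`.
#' @param n Response exponent, strictly positive (default 1, the linear
#'   readout used by the core models).
#' @return Non-negative response value.
#' @examples
#' st <- solve_al(ligand_params(1, 1), receptor_config(1))
#' response(st, ligand_params(1, 1, activity = 2)) # 1.0
#' @export
response <- function(state, ligand, n = 1) {
  stopifnot(inherits(state, "equilibrium_state"))
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stop("response exponent n must be a positive scalar")
  ligand$activity * state$species[["F"]]^n
}

#' Fraction of receptor subunits sequestered in full complexes
#'
#' `2F/A0` for homodimers (each full complex holds two subunits),
#' `F/min(A0, B0)` for heterodimers (reported against the less abundant
#' subunit).
#'
#' @param state An `equilibrium_state`.
#' @param receptors The [receptor_config()] the state was solved at.
#' @return Value in `[0, 1]`.
#' @export
bound_fraction <- function(state, receptors) {
  FF <- state$species[["F"]]
  if (is_heterodimeric(state$model)) FF / min(receptors$A0, receptors$B0)
  else if (state$model == "AL") FF / receptors$A0
  else 2 * FF / receptors$A0
}
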