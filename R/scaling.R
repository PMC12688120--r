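## Local scaling: the logarithmic derivative of the response with respect to
## total receptor abundance, S = d ln E / d ln A0. S is the local power-law
## exponent E ~ A0^S, so for small receptor variability the response CV is
## approximately S times the receptor CV.
##
## The numeric central difference (relative step h in log space) is the
## ground-truth method; the closed forms below were derived from the
## conservation laws and are validated against it in the test suite. Since
## E = e * F^n, d ln E / d ln A0 = n * d ln F / d ln A0: the derivative is
## taken on ln F and multiplied by n, so S is exactly independent of the
## activity rate e.

perturb_receptors <- function(receptors, subunit, factor) {
  r <- receptors
  if (subunit %in% c("A", "both")) r$A0 <- r$A0 * factor
  if (subunit %in% c("B", "both")) r$B0 <- r$B0 * factor
  r
}

#' Local scaling of the response with receptor totals
#'
#' Central finite difference of `ln F` with respect to `ln(total)` at
#' relative step `h`, multiplied by the response exponent `n`. For
#' heterodimeric models the derivative can be taken with respect to `A0`,
#' `B0`, or both jointly (`subunit = "both"`).
#'
#' @param model Model kind (see [model_kind()]); `ALB_NONSEQ` requires
#'   `extra_affinities`.
#' @param ligand A [ligand_params()].
#' @param receptors A [receptor_config()].
#' @param subunit One of `"A"`, `"B"`, `"both"`; `"B"`/`"both"` only for
#'   heterodimeric models.
#' @param h Relative log-space step of the central difference.
#' @param n Response exponent (see [response()]).
#' @param extra_affinities For `ALB_NONSEQ`: list with `K_PB`, `K_FB`.
#' @return An object of class `scaling_result`: list with `S`, `subunit`,
#'   `bound_fraction`, `model` and a parameter echo.
#' @examples
#' local_scaling("AL", ligand_params(1, 1), receptor_config(1))$S  # 1
#' @export
local_scaling <- function(model, ligand, receptors,
                          subunit = c("A", "B", "both"),
                          h = 1e-4, n = 1, extra_affinities = NULL) {
  model <- model_kind(model)
  subunit <- match.arg(subunit)
  if (subunit != "A" && !is_heterodimeric(model))
    stop("subunit '", subunit, "' is only meaningful for heterodimeric models")
  solve_fn <- if (model == "ALB_NONSEQ") {
    if (is.null(extra_affinities)) stop("ALB_NONSEQ requires extra_affinities")
    function(r) solve_alb_nonseq(ligand, extra_affinities, r)
  } else function(r) solve_model(model, ligand, r)

  st <- solve_fn(receptors)
  if (st$species[["F"]] <= 0)
    stop("scaling is undefined: the response is zero at the evaluation point")
  up <- solve_fn(perturb_receptors(receptors, subunit, exp(h)))
  dn <- solve_fn(perturb_receptors(receptors, subunit, exp(-h)))
  S <- n * (log(up$species[["F"]]) - log(dn$species[["F"]])) / (2 * h)
  structure(list(S = S, subunit = subunit,
                 bound_fraction = bound_fraction(st, receptors),
                 model = model, ligand = ligand, receptors = receptors, n = n),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("local scaling (%s, subunit %s): S = %.6g (bound fraction %.4g)\n",
              x$model, x$subunit, x$S, x$bound_fraction))
  invisible(x)
}

#' Homodimer scaling from the bound fraction
#'
#' For the single-ligand homodimeric (ALA) model the scaling collapses onto
#' the fraction of subunits held in full complexes, `f = 2F/A0`:
#' `S = 2/(1 + f)`. Derived by differentiating the conservation law
#' `A(1 + K_P C) + 2 K_F K_P C A^2 = A0`, which gives
#' `S = 2 A0 / (A0 + 2F)`; validated against the numeric derivative in the
#' test suite.
#'
#' @param f Bound fraction in `[0, 1]`.
#' @return Scaling value in `[1, 2]`.
#' @export
scaling_from_bound_fraction_ala <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("bound fraction must lie in [0, 1]")
  2 / (1 + f)
}

#' Heterodimer per-subunit scaling from the full-complex amount
#'
#' For the sequential heterodimer (`F = alpha (A0 - F)(B0 - F)`) implicit
#' differentiation gives
#' `S_A = A0 (B0 - F) / (A0 B0 - F^2)` and the A/B-symmetric `S_B`.
#' Both lie in `[0, 1]`; the scaling with the abundant subunit vanishes as
#' that subunit saturates. Validated against the numeric derivative in the
#' test suite.
#'
#' @param receptors A [receptor_config()] with both totals.
#' @param F Full-complex amount from a solved `ALB_SEQ` state; must satisfy
#'   `F < min(A0, B0)`.
#' @return Named numeric vector `c(S_A, S_B)`.
#' @export
scaling_alb_closed <- function(receptors, F) {
  stopifnot(inherits(receptors, "receptor_config"))
  A0 <- receptors$A0; B0 <- receptors$B0
  if (is.na(B0)) stop("heterodimer scaling requires B0")
  if (F >= min(A0, B0)) stop("F must be strictly below min(A0, B0)")
  den <- A0 * B0 - F^2
  c(S_A = A0 * (B0 - F) / den, S_B = B0 * (A0 - F) / den)
}

#' Scan the scaling over a dimensionless parameter grid
#'
#' Sweeps the dimensionless groups `K_P*C` and `K_F*X0` on a log grid
#' (where `X0` is `A0` for single-subunit models and `A0 + B0` for
#' heterodimers) and records the local scaling and bound fraction at each
#' grid point. Per-cell solver failures are recorded as `NA` rows.
#'
#' @param model Model kind.
#' @param kpc,kfx Numeric vectors of grid values for `K_P*C` and `K_F*X0`
#'   (default 41 log-spaced points over `[1e-4, 1e4]`).
#' @param ratio `A0/B0` for heterodimeric models (the scan fixes
#'   `A0 + B0 = 2`); ignored otherwise.
#' @param n Response exponent.
#' @param h Finite-difference step.
#' @return A data frame with one row per grid point: `model`, `kpc`, `kfx`,
#'   `ratio`, `S` (joint for heterodimers), `S_A`, `S_B`, `bound_fraction`.
#' @export
scan_scaling <- function(model, kpc = log_space(1e-4, 1e4, 41),
                         kfx = log_space(1e-4, 1e4, 41),
                         ratio = NA_real_, n = 1, h = 1e-4) {
  model <- model_kind(model)
  if (!length(kpc) || !length(kfx)) stop("empty scan grid")
  hetero <- is_heterodimeric(model)
  if (hetero && is.na(ratio)) stop("heterodimeric scans require a ratio A0/B0")
  if (hetero) {
    B0 <- 2 / (1 + ratio); A0 <- 2 - B0
  } else {
    A0 <- 1; B0 <- NA_real_
  }
  receptors <- receptor_config(A0, B0)
  X0 <- if (hetero) A0 + B0 else A0
  grid <- expand.grid(kpc = kpc, kfx = kfx, KEEP.OUT.ATTRS = FALSE)
  one <- function(kpc_i, kfx_i) {
    lig <- ligand_params(conc = 1, K_P = kpc_i, K_F = kfx_i / X0)
    tryCatch({
      if (hetero) {
        sa <- local_scaling(model, lig, receptors, "A", h = h, n = n)
        sb <- local_scaling(model, lig, receptors, "B", h = h, n = n)
        c(S = sa$S + sb$S, S_A = sa$S, S_B = sb$S, bf = sa$bound_fraction)
      } else {
        s <- local_scaling(model, lig, receptors, "A", h = h, n = n)
        c(S = s$S, S_A = NA_real_, S_B = NA_real_, bf = s$bound_fraction)
      }
    }, error = function(e) c(S = NA_real_, S_A = NA_real_, S_B = NA_real_,
                             bf = NA_real_))
  }
  vals <- t(mapply(one, grid$kpc, grid$kfx))
  data.frame(model = model, kpc = grid$kpc, kfx = grid$kfx, ratio = ratio,
             S = vals[, "S"], S_A = vals[, "S_A"], S_B = vals[, "S_B"],
             bound_fraction = vals[, "bf"], row.names = NULL)
}

#' Scaling of the activating ligand in the presence of an inhibitor
#'
#' Numeric log-derivative of the activator's full-complex amount `F_L` with
#' respect to the shared receptor total `A0`, with both ligands at
#' equilibrium (solved through the general network solver).
#'
#' @inheritParams build_competition_network
#' @param h Finite-difference step.
#' @param n Response exponent.
#' @return A `scaling_result`; `bound_fraction` is the activator's
#'   `2 F_L / A0`.
#' @export
competition_scaling <- function(activator, inhibitor, receptors,
                                h = 1e-4, n = 1) {
  f_at <- function(A0) {
    st <- solve_equilibrium(build_competition_network(
      activator, inhibitor, receptor_config(A0)))
    st$species[["F_L"]]
  }
  F0 <- f_at(receptors$A0)
  if (F0 <= 0) stop("scaling is undefined: the response is zero at the evaluation point")
  S <- n * (log(f_at(receptors$A0 * exp(h))) -
              log(f_at(receptors$A0 * exp(-h)))) / (2 * h)
  structure(list(S = S, subunit = "A", bound_fraction = 2 * F0 / receptors$A0,
                 model = "COMPETITION", ligand = activator,
                 receptors = receptors, n = n),
            class = "scaling_result")
}
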