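## General coupled-binding equilibrium solver.
##
## Every species in an association network is a monomial in the free base
## species: amount_s = k_s * prod_j x_j^(n_sj), where the prefactor k_s
## absorbs association constants and constant-species amounts. Conservation
## laws are therefore posynomials in the base amounts, and a damped Newton
## iteration on log-amounts is globally well behaved and keeps all amounts
## positive without clipping.

#' Association reaction
#'
#' One reversible association written in the direction of complex
#' formation: `product = K * prod(reactants)` at equilibrium.
#'
#' @param reactants Character vector of reactant species names; repeat a
#'   name for multiplicity (e.g. `c("P", "P")`).
#' @param product Single product species name.
#' @param K Association constant, strictly positive.
#' @return An object of class `reaction`.
#' @export
reaction <- function(reactants, product, K) {
  stopifnot(is.character(reactants), length(reactants) >= 1L,
            is.character(product), length(product) == 1L,
            is.numeric(K), length(K) == 1L, K > 0, is.finite(K))
  structure(list(reactants = reactants, product = product, K = K),
            class = "reaction")
}

#' Conservation law
#'
#' @param coef Named numeric vector of stoichiometric coefficients (how many
#'   copies of the conserved unit each species carries).
#' @param total Conserved total amount, non-negative.
#' @param name Law label (defaults to the first species name).
#' @return An object of class `conservation_law`.
#' @export
conservation_law <- function(coef, total, name = names(coef)[1L]) {
  stopifnot(is.numeric(coef), !is.null(names(coef)), all(coef > 0),
            is.numeric(total), length(total) == 1L, total >= 0)
  structure(list(coef = coef, total = total, name = name),
            class = "conservation_law")
}

#' Reaction network
#'
#' @param reactions List of [reaction()] objects.
#' @param constants Named numeric vector of species held at fixed amounts
#'   (e.g. a ligand under the unlimited-pool assumption).
#' @param conservation List of [conservation_law()] objects covering every
#'   non-constant species.
#' @param model Optional label attached to solutions.
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(reactions, constants = numeric(), conservation,
                             model = "network") {
  stopifnot(is.list(reactions), all(vapply(reactions, inherits, TRUE, "reaction")),
            is.list(conservation),
            all(vapply(conservation, inherits, TRUE, "conservation_law")))
  if (length(constants) && (is.null(names(constants)) || any(constants < 0)))
    stop("constants must be a named non-negative numeric vector")
  net <- structure(list(reactions = reactions, constants = constants,
                        conservation = conservation, model = model),
                   class = "reaction_network")
  compile_network(net)  # validates eagerly
  net
}

## Resolve every species to (log prefactor, exponent vector over free base
## species). Products defined by more than one route must agree (detailed
## balance around the cycle) to relative 1e-6 on the constant product.
compile_network <- function(net, db_tol = 1e-6) {
  products <- vapply(net$reactions, `[[`, "", "product")
  all_reactants <- unique(unlist(lapply(net$reactions, `[[`, "reactants")))
  species <- unique(c(names(net$constants), all_reactants, products))
  const_names <- names(net$constants)
  base <- setdiff(species, c(const_names, products))
  if (!length(base)) stop("network has no free base species")

  nb <- length(base)
  logk <- stats::setNames(rep(NA_real_, length(species)), species)
  expo <- matrix(0, length(species), nb, dimnames = list(species, base))
  zerok <- stats::setNames(rep(FALSE, length(species)), species)

  logk[base] <- 0
  for (j in seq_along(base)) expo[base[j], j] <- 1
  for (cn in const_names) {
    v <- net$constants[[cn]]
    zerok[cn] <- v == 0
    logk[cn] <- if (v > 0) log(v) else -Inf
  }

  pending <- net$reactions
  repeat {
    progressed <- FALSE
    keep <- logical(length(pending))
    for (i in seq_along(pending)) {
      rx <- pending[[i]]
      if (any(is.na(logk[rx$reactants]))) { keep[i] <- TRUE; next }
      lk <- log(rx$K) + sum(logk[rx$reactants])
      ex <- colSums(expo[rx$reactants, , drop = FALSE])
      zk <- any(zerok[rx$reactants])
      p <- rx$product
      if (is.na(logk[p])) {
        logk[p] <- lk; expo[p, ] <- ex; zerok[p] <- zk
      } else {
        # second route to the same complex: thermodynamic cycle check
        if (!isTRUE(all.equal(expo[p, ], ex, tolerance = 1e-12)) ||
            (!zk && !zerok[p] && abs(lk - logk[p]) > db_tol))
          stop("detailed-balance violation: species '", p,
               "' is produced by routes with inconsistent effective constants")
      }
      progressed <- TRUE
    }
    pending <- pending[keep]
    if (!length(pending)) break
    if (!progressed)
      stop("reaction network cannot be resolved: cyclic definitions among ",
           paste(vapply(pending, `[[`, "", "product"), collapse = ", "))
  }

  law_species <- lapply(net$conservation, function(l) names(l$coef))
  covered <- unique(unlist(law_species))
  uncovered <- setdiff(setdiff(species, const_names), covered)
  if (length(uncovered))
    stop("non-constant species not covered by any conservation law: ",
         paste(uncovered, collapse = ", "))
  unknown <- setdiff(covered, species)
  if (length(unknown))
    stop("conservation law references unknown species: ",
         paste(unknown, collapse = ", "))

  nl <- length(net$conservation)
  C <- matrix(0, nl, length(species), dimnames =
                list(vapply(net$conservation, `[[`, "", "name"), species))
  totals <- numeric(nl)
  for (i in seq_len(nl)) {
    l <- net$conservation[[i]]
    C[i, names(l$coef)] <- l$coef
    totals[i] <- l$total
  }
  list(species = species, base = base, const_names = const_names,
       logk = logk, expo = expo, zerok = zerok,
       C = C, totals = totals, model = net$model)
}

species_amounts <- function(cmp, u) {
  # u: log-amounts of base species (may contain -Inf for forced-zero)
  a <- exp(cmp$logk + drop(cmp$expo %*% ifelse(is.finite(u), u, 0)))
  dead <- cmp$zerok | (cmp$expo %*% !is.finite(u)) > 0
  a[dead] <- 0
  a
}

#' Solve a mass-action network to equilibrium
#'
#' Damped Newton iteration on the log-amounts of the free base species;
#' positivity is automatic in log space. For one-dimensional problems a
#' bisection fallback guards against pathological steps.
#'
#' @param network A [reaction_network()].
#' @param tol Convergence tolerance on the conservation residuals, relative
#'   to each law's total.
#' @param maxit Maximum Newton iterations.
#' @return An `equilibrium_state` with all non-constant species amounts and
#'   per-law relative residuals.
#' @examples
#' net <- reaction_network(
#'   reactions = list(reaction(c("A", "L"), "P", K = 1)),
#'   constants = c(L = 1),
#'   conservation = list(conservation_law(c(A = 1, P = 1), total = 1)))
#' solve_equilibrium(net)$species  # A = P = 0.5
#' @export
solve_equilibrium <- function(network, tol = 1e-12, maxit = 200) {
  cmp <- compile_network(network)
  nb <- length(cmp$base)
  scale <- pmax(cmp$totals, .Machine$double.xmin)

  # base species confined to a zero-total law are identically zero
  forced0 <- rep(FALSE, nb)
  for (i in seq_along(cmp$totals)) {
    if (cmp$totals[i] == 0)
      forced0 <- forced0 | (cmp$C[i, cmp$base] > 0)
  }
  u <- rep(-Inf, nb)
  active <- which(!forced0)

  if (length(active)) {
    for (j in active) {
      laws <- which(cmp$C[, cmp$base[j], drop = TRUE] > 0 & cmp$totals > 0)
      u[j] <- log(min(cmp$totals[laws] / cmp$C[laws, cmp$base[j]]) / 2)
    }
    live <- cmp$totals > 0
    resid <- function(u) drop(cmp$C %*% species_amounts(cmp, u)) - cmp$totals
    r <- resid(u)
    for (it in seq_len(maxit)) {
      if (max(abs(r[live]) / scale[live]) < tol) break
      amt <- species_amounts(cmp, u)
      J <- (cmp$C[live, , drop = FALSE] * rep(amt, each = sum(live))) %*%
        cmp$expo[, active, drop = FALSE]
      du <- tryCatch(solve(J, -r[live]), error = function(e) NULL)
      if (is.null(du)) du <- -r[live] / pmax(diag(as.matrix(J)), .Machine$double.xmin)
      du <- pmin(pmax(du, -30), 30)
      step <- 1; accepted <- FALSE
      for (k in 1:60) {
        u_try <- u; u_try[active] <- u[active] + step * du
        r_try <- resid(u_try)
        if (sum((r_try[live] / scale[live])^2) < sum((r[live] / scale[live])^2)) {
          u <- u_try; r <- r_try; accepted <- TRUE; break
        }
        step <- step / 2
      }
      if (!accepted) {
        if (length(active) == 1L) {
          u[active] <- bisect_1d(function(v) {
            uu <- u; uu[active] <- v; resid(uu)[which(live)[1L]]
          }, u[active])
          r <- resid(u)
        } else break
      }
    }
    if (max(abs(r[live]) / scale[live]) > 1e-9)
      stop(sprintf("equilibrium solver did not converge (max relative residual %.3g)",
                   max(abs(r[live]) / scale[live])))
  }

  amt <- species_amounts(cmp, u)
  report <- setdiff(cmp$species, cmp$const_names)
  res <- (drop(cmp$C %*% amt) - cmp$totals) / scale
  names(res) <- rownames(cmp$C)
  new_equilibrium_state(amt[report], res, cmp$model)
}

## Scalar bisection on a monotone-increasing residual in log-amount.
bisect_1d <- function(g, u0, tol = 1e-14, maxit = 400) {
  lo <- u0; hi <- u0
  while (g(lo) > 0) lo <- lo - 5
  while (g(hi) < 0) hi <- hi + 5
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

## Vectorized Newton for networks that reduce to a single free base species
## and a single conservation law (e.g. the competition model across a cell
## population). The residual is convex and increasing in the log-amount, so
## undamped Newton with a step clamp converges monotonically.
solve_network_1d_many <- function(network, totals, tol = 1e-12, maxit = 300) {
  cmp <- compile_network(network)
  if (length(cmp$base) != 1L || nrow(cmp$C) != 1L)
    stop("solve_network_1d_many requires one free base species and one conservation law")
  coef <- cmp$C[1L, ]
  k <- exp(cmp$logk); k[cmp$zerok] <- 0
  p <- cmp$expo[, 1L]
  live <- totals > 0
  u <- log(pmax(totals, .Machine$double.xmin) / (2 * max(coef)))
  sc <- pmax(totals, .Machine$double.xmin)
  idx <- which(live)
  for (it in seq_len(maxit)) {
    eu <- exp(outer(p, u[idx]))          # species x cells
    amt <- k * eu
    r <- colSums(coef * amt) - totals[idx]
    bad <- abs(r) / sc[idx] >= tol
    if (!any(bad)) break
    J <- colSums(coef * amt * p)[bad]
    du <- pmin(pmax(-r[bad] / J, -10), 10)
    u[idx[bad]] <- u[idx[bad]] + du
    idx <- idx[bad]
    if (it == maxit) stop("vectorized 1-D equilibrium solve did not converge")
  }
  out <- k * exp(outer(p, ifelse(live, u, -Inf)))
  out[, !live] <- 0
  rownames(out) <- cmp$species
  out[setdiff(cmp$species, cmp$const_names), , drop = FALSE]
}

#' Competition network: activator plus inhibitor on a homodimeric receptor
#'
#' Both ligands follow the ALA architecture and compete for the same pool
#' of A subunits. The inhibitor is typically a zero-activity ligand
#' (`activity = 0`): it sequesters receptors without signaling.
#'
#' @param activator,inhibitor [ligand_params()] for the two ligands.
#' @param receptors [receptor_config()]; only `A0` is used.
#' @return A [reaction_network()] with species `A`, `P_L`, `F_L`, `P_I`,
#'   `F_I` and the conservation law `A + P_L + 2 F_L + P_I + 2 F_I = A0`.
#' @export
build_competition_network <- function(activator, inhibitor, receptors) {
  stopifnot(inherits(activator, "ligand_params"),
            inherits(inhibitor, "ligand_params"),
            inherits(receptors, "receptor_config"))
  reaction_network(
    reactions = list(
      reaction(c("A", "L"), "P_L", activator$K_P),
      reaction(c("P_L", "A"), "F_L", activator$K_F),
      reaction(c("A", "I"), "P_I", inhibitor$K_P),
      reaction(c("P_I", "A"), "F_I", inhibitor$K_F)),
    constants = c(L = activator$conc, I = inhibitor$conc),
    conservation = list(conservation_law(
      c(A = 1, P_L = 1, F_L = 2, P_I = 1, F_I = 2),
      total = receptors$A0, name = "A")),
    model = "COMPETITION")
}

#' Non-sequential heterodimer network
#'
#' The ligand may bind subunit A first (partial complex `P_A`, constant
#' `K_P`) or subunit B first (`P_B`, constant `K_PB`); each partial then
#' recruits the other subunit to form the same full complex `F`. The two
#' routes to `F` must satisfy the detailed-balance cycle constraint
#' `K_P * K_F = K_PB * K_FB`.
#'
#' @param ligand [ligand_params()] supplying `conc`, `K_P` (A-first partial)
#'   and `K_F` (P_A + B step).
#' @param extra_affinities List with `K_PB` (B-first partial) and `K_FB`
#'   (P_B + A step).
#' @param receptors [receptor_config()] with both subunit totals.
#' @return A [reaction_network()] with species `A`, `B`, `P_A`, `P_B`, `F`.
#' @export
build_alb_nonseq_network <- function(ligand, extra_affinities, receptors) {
  stopifnot(inherits(ligand, "ligand_params"),
            inherits(receptors, "receptor_config"),
            is.list(extra_affinities),
            all(c("K_PB", "K_FB") %in% names(extra_affinities)))
  if (is.na(receptors$B0)) stop("non-sequential heterodimer requires B0")
  reaction_network(
    reactions = list(
      reaction(c("A", "L"), "P_A", ligand$K_P),
      reaction(c("B", "L"), "P_B", extra_affinities$K_PB),
      reaction(c("P_A", "B"), "F", ligand$K_F),
      reaction(c("P_B", "A"), "F", extra_affinities$K_FB)),
    constants = c(L = ligand$conc),
    conservation = list(
      conservation_law(c(A = 1, P_A = 1, F = 1), total = receptors$A0, name = "A"),
      conservation_law(c(B = 1, P_B = 1, F = 1), total = receptors$B0, name = "B")),
    model = "ALB_NONSEQ")
}

#' Solve the non-sequential heterodimer model
#'
#' @inheritParams build_alb_nonseq_network
#' @param ... Passed to [solve_equilibrium()].
#' @return An `equilibrium_state` (model `ALB_NONSEQ`).
#' @export
solve_alb_nonseq <- function(ligand, extra_affinities, receptors, ...) {
  solve_equilibrium(build_alb_nonseq_network(ligand, extra_affinities, receptors), ...)
}

#' Serialize a reaction network to JSON
#'
#' @param network A [reaction_network()].
#' @param path Output file path.
#' @export
write_network_json <- function(network, path) {
  doc <- list(
    model = network$model,
    constants = as.list(network$constants),
    reactions = lapply(network$reactions, function(r)
      list(reactants = r$reactants, product = r$product, K = r$K)),
    conservation = lapply(network$conservation, function(l)
      list(name = l$name, coef = as.list(l$coef), total = l$total)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reaction network from JSON
#'
#' @param path File written by [write_network_json()].
#' @return A [reaction_network()].
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path)
  reaction_network(
    reactions = lapply(doc$reactions, function(r)
      reaction(unlist(r$reactants), r$product, as.numeric(r$K))),
    constants = unlist(lapply(doc$constants, as.numeric)) %||% numeric(),
    conservation = lapply(doc$conservation, function(l)
      conservation_law(unlist(lapply(l$coef, as.numeric)), as.numeric(l$total),
                       name = l$name)),
    model = doc$model %||% "network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
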