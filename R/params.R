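#' Ligand parameter set
#'
#' Bundles the biochemical identity of one ligand: its environmental
#' concentration, the association constant for forming the partial complex
#' (ligand + first receptor subunit), the association constant for forming
#' the full signaling complex, and the activity rate with which a full
#' complex drives the downstream response.
#'
#' All affinities are association constants, so at equilibrium the partial
#' complex satisfies `P = K_P * C * A` and the full complex the analogous
#' relation for each architecture. Concentrations are in arbitrary
#' concentration units (ACU) and receptor amounts in arbitrary receptor
#' units (ARU); the models carry no absolute scale.
#'
#' @param conc Ligand concentration `C` (ACU), non-negative.
#' @param K_P Association constant of the first binding step (per ACU),
#'   strictly positive.
#' @param K_F Association constant of the full-complex-forming step (per
#'   ARU), strictly positive. Unused by the monomeric (AL) model.
#' @param activity Activity rate `e`: response units produced per full
#'   complex, non-negative.
#' @param id Optional ligand label used in tables.
#' @return An object of class `ligand_params`.
#' @examples
#' ligand_params(conc = 1, K_P = 1, K_F = 1)
#' @export
ligand_params <- function(conc, K_P, K_F = 1, activity = 1, id = NULL) {
  stopifnot(is.numeric(conc), length(conc) == 1L, is.finite(conc),
            is.numeric(K_P), length(K_P) == 1L, is.finite(K_P),
            is.numeric(K_F), length(K_F) == 1L, is.finite(K_F),
            is.numeric(activity), length(activity) == 1L, is.finite(activity))
  if (conc < 0) stop("ligand concentration must be non-negative")
  if (K_P <= 0 || K_F <= 0) stop("association constants must be strictly positive")
  if (activity < 0) stop("activity rate must be non-negative")
  structure(list(conc = conc, K_P = K_P, K_F = K_F,
                 activity = activity, id = id),
            class = "ligand_params")
}

#' @export
print.ligand_params <- function(x, ...) {
  cat(sprintf("ligand%s: C = %g ACU, K_P = %g, K_F = %g, e = %g\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$conc, x$K_P, x$K_F, x$activity))
  invisible(x)
}

#' Per-cell receptor subunit totals
#'
#' @param A0 Total amount of the (first) receptor subunit (ARU),
#'   non-negative.
#' @param B0 Total amount of the second subunit (ARU) for heterodimeric
#'   models; `NA` for single-subunit architectures.
#' @return An object of class `receptor_config`.
#' @examples
#' receptor_config(A0 = 1)
#' receptor_config(A0 = 1, B0 = 2)
#' @export
receptor_config <- function(A0, B0 = NA_real_) {
  stopifnot(is.numeric(A0), length(A0) == 1L, is.finite(A0))
  if (A0 < 0) stop("A0 must be non-negative")
  if (!is.na(B0)) {
    stopifnot(is.numeric(B0), length(B0) == 1L, is.finite(B0))
    if (B0 < 0) stop("B0 must be non-negative")
  }
  structure(list(A0 = as.numeric(A0), B0 = as.numeric(B0)),
            class = "receptor_config")
}

#' @export
print.receptor_config <- function(x, ...) {
  if (is.na(x$B0)) cat(sprintf("receptors: A0 = %g ARU\n", x$A0))
  else cat(sprintf("receptors: A0 = %g, B0 = %g ARU\n", x$A0, x$B0))
  invisible(x)
}

## Recognized receptor architectures. Each maps to one solver and one set of
## conservation laws.
MODEL_KINDS <- c("AL", "ALA", "LAAL", "ALB_SEQ", "ALB_NONSEQ")

#' Receptor architecture identifiers
#'
#' Validates and normalizes a model-kind string. Supported architectures:
#' \describe{
#'   \item{AL}{monomeric receptor, ligand + one subunit form the complex.}
#'   \item{ALA}{homodimeric receptor, one ligand sequentially binds two
#'     identical subunits (partial then full complex).}
#'   \item{LAAL}{homodimeric receptor with two ligands: two
#'     ligand--subunit partial complexes pair into the full complex.}
#'   \item{ALB_SEQ}{heterodimeric receptor, ligand binds subunit A first,
#'     the partial complex then recruits subunit B.}
#'   \item{ALB_NONSEQ}{heterodimeric receptor where the ligand may bind
#'     either subunit first (requires extra affinities and detailed
#'     balance; solved numerically).}
#' }
#'
#' @param model Character scalar, one of the names above (case-insensitive).
#' @return The normalized model string.
#' @export
model_kind <- function(model) {
  m <- toupper(as.character(model)[1L])
  if (m %in% c("ALB", "ALB-SEQ")) m <- "ALB_SEQ"
  if (m == "ALB-NONSEQ") m <- "ALB_NONSEQ"
  if (!m %in% MODEL_KINDS)
    stop("unknown model kind '", model, "'; expected one of ",
         paste(MODEL_KINDS, collapse = ", "))
  m
}

is_heterodimeric <- function(model) model %in% c("ALB_SEQ", "ALB_NONSEQ")

#' Log-spaced grid
#'
#' @param from,to Positive range endpoints.
#' @param n Number of points.
#' @return Numeric vector of `n` log-uniformly spaced values.
#' @export
log_space <- function(from, to, n) {
  stopifnot(from > 0, to > 0, n >= 1)
  exp(seq(log(from), log(to), length.out = n))
}
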