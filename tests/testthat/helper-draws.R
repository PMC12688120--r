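# Log-uniform parameter draws used by the property-style tests.
runif_log <- function(n, lo = 1e-4, hi = 1e4) {
  exp(stats::runif(n, log(lo), log(hi)))
}

random_ligand <- function(lo = 1e-4, hi = 1e4) {
  ligand_params(conc = runif_log(1, lo, hi), K_P = runif_log(1, lo, hi),
                K_F = runif_log(1, lo, hi))
}

# Independent scalar oracle: bisection on the conservation residual in free A
# (monotone increasing), written without reference to the package solvers.
bisect_free_A <- function(residual, hi, tol = 1e-15) {
  lo <- 0
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (residual(mid) > 0) hi <- mid else lo <- mid
    # relative width: the root can be many orders below the initial bracket
    if ((hi - lo) < tol * hi) break
  }
  (lo + hi) / 2
}
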