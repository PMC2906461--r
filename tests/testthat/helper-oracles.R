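# Independent oracles, implemented before (and independently of) the
# package internals they check.

# Brute-force half-reaction balancing: electrons released by
#   CxHyOzNw + a H2O -> x CO2 + w NH3 + b H+ + b e-
# Solve the O and H element balances as a linear system; b is the answer.
# This shares no code with the valence-sum in the package.
gamma_oracle <- function(counts) {
  x <- if ("C" %in% names(counts)) counts[["C"]] else 0
  y <- if ("H" %in% names(counts)) counts[["H"]] else 0
  z <- if ("O" %in% names(counts)) counts[["O"]] else 0
  w <- if ("N" %in% names(counts)) counts[["N"]] else 0
  # unknowns u = (a, b):  O: a = 2x - z ;  H: 2a - b = 3w - y
  A <- matrix(c(1, 0,
                2, -1), 2, 2, byrow = TRUE)
  rhs <- c(2 * x - z, 3 * w - y)
  u <- solve(A, rhs)
  u[2]
}

# random small CxHyOzNw formula as a named count vector
random_formula_counts <- function() {
  counts <- c(C = sample(0:12, 1), H = sample(0:24, 1),
              O = sample(0:12, 1), N = sample(0:3, 1))
  counts[counts > 0]
}

# unit-analysis oracle for DNA copy number: grams -> moles -> molecules
copies_oracle <- function(ng, bp, g_per_mol_bp = 660) {
  grams <- ng * 1e-9
  moles <- grams / (bp * g_per_mol_bp)
  moles * 6.02214076e23
}
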