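# Residue-level chemistry tables used for pore lining characterisation and
# for the pseudo-residue decoration of the synthetic bead model.

# Kyte-Doolittle hydropathy index (one-letter codes).
KD_HYDROPATHY <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

# Formal side-chain charges at neutral pH; histidine treated as neutral.
FORMAL_CHARGE <- c(D = -1L, E = -1L, K = 1L, R = 1L)

AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

# Draw pseudo-residues from the fixed lining composition:
# 10% each D/E/K/R, 30% hydrophobic, 30% polar-neutral.
sample_pseudo_residues <- function(n, seed) {
  hydrophobic <- c("A", "V", "L", "I", "F", "M")
  polar <- c("S", "T", "N", "Q", "G", "Y")
  classes <- c("D", "E", "K", "R", "hydrophobic", "polar")
  probs <- c(0.1, 0.1, 0.1, 0.1, 0.3, 0.3)
  rng <- local_rng(seed)
  cls <- rng(function() sample(classes, n, replace = TRUE, prob = probs))
  res <- cls
  nh <- sum(cls == "hydrophobic")
  np <- sum(cls == "polar")
  res[cls == "hydrophobic"] <- rng(function() sample(hydrophobic, nh, replace = TRUE))
  res[cls == "polar"] <- rng(function() sample(polar, np, replace = TRUE))
  res
}

# One generator per operation call: run `fn` under a private RNG stream seeded
# from `seed`, restoring the caller's global state afterwards. Repeated calls
# on the returned closure continue the same private stream.
local_rng <- function(seed) {
  state <- NULL
  function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state, envir = globalenv())
    out <- fn()
    state <<- get(".Random.seed", globalenv())
    out
  }
}
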