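# Physical constants (CODATA 2018) used by the conductivity model.
.const <- list(
  q_e = 1.602176634e-19,  # elementary charge, C
  k_B = 1.380649e-23,     # Boltzmann constant, J/K
  N_A = 6.02214076e23     # Avogadro constant, 1/mol
)

# Angstrom -> metre
.ang <- 1e-10

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Tiny stable polynomial hash (31-based, mod 2^31) of a config list,
# for embedding in output metadata.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483648
  sprintf("%08x", h)
}

stop_ellipore <- function(msg, class = "ellipore_error") {
  abort(msg, class = class)
}
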