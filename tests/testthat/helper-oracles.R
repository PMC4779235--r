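# independent oracles and small fixture builders shared across tests

# term-by-term summation of the binomial upper tail, independent of pbinom
binom_tail_oracle <- function(n, m, n_S, m_S_act) {
  if (m_S_act > n_S) return(0)
  i <- m_S_act:n_S
  p <- m / n
  sum(choose(n_S, i) * p^i * (1 - p)^(n_S - i))
}

# lower tail, for the complement identity
binom_lower_oracle <- function(n, m, n_S, k) {
  if (k < 0) return(0)
  i <- 0:k
  p <- m / n
  sum(choose(n_S, i) * p^i * (1 - p)^(n_S - i))
}

write_smiles_file <- function(lines) {
  tf <- tempfile(fileext = ".smi")
  writeLines(lines, tf)
  tf
}

# sorted identifier multiset per molecule: a practical graph-isomorphism
# proxy (equal environments at all radii up to 3)
env_signature <- function(record) {
  e <- enumerate_atom_environments(record, 0:3)
  sort(e$identifier)
}

# default categorical recovery fixture of the validation studies
cat_spec <- function(seed, n = 200, p_act = 0.4, p_inact = 0.02) {
  fixture_spec(n, seed = seed, p_frag_given_active = p_act,
               p_frag_given_inactive = p_inact)
}

cont_spec <- function(seed, n = 300, shift = 1.0, sd = 0.3, p_carrier = 0.2) {
  fixture_spec(n, seed = seed, p_carrier = p_carrier, shift = shift,
               noise_sd = sd)
}
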