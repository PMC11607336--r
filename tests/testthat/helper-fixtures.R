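# Shared fixture builders.  Everything is generated in code at test time
# under fixed seeds; nothing is read from disk.

tiny_universe <- function(n_codes = 6, seed = 1) {
  build_code_universe(n_codes = n_codes, seed = seed)
}

tiny_corpus <- function(universe, n_notes = 60, seed = 1, ...) {
  args <- utils::modifyList(
    list(n_notes = n_notes, seed = seed, note_length_tokens = c(30, 60)),
    list(...))
  generate_corpus(universe, do.call(corpus_config, args))
}

# A separable membership fixture: members confident (probabilities pushed
# toward 0/1), non-members diffuse.
separable_membership <- function(m = 80, k = 80, L = 10, seed = 1) {
  set.seed(seed)
  mem <- matrix(runif(m * L), m)
  mem <- ifelse(mem > 0.5, 1 - mem * 0.02, mem * 0.02)
  non <- matrix(runif(k * L), k)
  membership_dataset(mem, non)
}

# Exchangeable null membership fixture: both groups i.i.d. uniform.
null_membership <- function(m = 200, k = 200, L = 10, seed = 1) {
  set.seed(seed)
  membership_dataset(matrix(runif(m * L), m), matrix(runif(k * L), k))
}
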