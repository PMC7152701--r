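# A condition holding one chunk that fully matches a single cue with
# weight 1 and fan 1, so its noiseless activation is beta + MAS. Tests set
# the activation directly through MAS (beta = 0).
one_chunk_condition <- function() {
  condition_spec(
    chunks = list(chunk("only", c(cue = "v"))),
    cues = cue_set(c(cue = "v"), weights = c(cue = 1))
  )
}

# Parameters putting the single chunk's activation at A.
params_with_activation <- function(A, ...) {
  model_params(MAS = A, beta = 0, ...)
}

# Highest noiseless activation in a condition: the ANS = 0 winner.
noiseless_winner_activation <- function(cond, params) {
  max(vapply(cond$chunks, function(ch) {
    base_level(ch, params) +
      spreading_activation(ch, cond$cues, params) +
      mismatch_penalty(ch, cond$cues, params)
  }, numeric(1)))
}
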