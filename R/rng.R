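# RNG draw contract
#
# One master seed per run seeds R's global stream; every stochastic step in
# the schedule consumes that stream through exactly one primitive:
#
#   draw_int(n): one uniform deviate u, mapped to floor(u * n) in 0..n-1
#   one uniform deviate on [0, 1) for adoption threshold tests
#
# in this fixed order: initialization (secondary-trait rejection draws, agents
# in canonical breed order) -> per tick: agent shuffle (Fisher-Yates from the
# top), per-agent interaction draws (trait slot, partner index, threshold,
# replaced slot, gained trait), culture tie-breaks (breeds in canonical
# order), breed-switch coin flips (agents in index order), rebirth draws
# (agents in index order). The compiled engine consumes the same stream
# through unif_rand() with the identical mapping, which is what makes the
# R reference schedule and the compiled engine bit-identical under a shared
# seed.

draw_int <- function(n) {
  # one draw, uniform on 0..n-1
  j <- floor(stats::runif(1L) * n)
  as.integer(min(j, n - 1))
}

# Fisher-Yates permutation of 0..(n-1), consuming n-1 draws (i = n-1 .. 1)
draw_permutation <- function(n) {
  ord <- 0:(n - 1L)
  if (n < 2L) return(ord)
  for (i in (n - 1L):1L) {
    j <- draw_int(i + 1L)
    tmp <- ord[i + 1L]
    ord[i + 1L] <- ord[j + 1L]
    ord[j + 1L] <- tmp
  }
  ord
}

# rejection-sample one value uniform on lo..hi excluding `held`
draw_excluding <- function(lo, hi, held) {
  n <- hi - lo + 1L
  repeat {
    v <- lo + draw_int(n)
    if (!(v %in% held)) return(v)
  }
}
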