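# Independent oracle for the calibration algebra: exhaustively enumerate
# every gate-outcome sequence (a terminating gate that fires prunes the rest
# of the pathway; non-terminating gates branch both ways) and accumulate the
# probability mass with which each gate fires — the implied cohort marginal.
enumerate_marginals <- function(conditional, terminates) {
  n <- length(conditional)
  marg <- numeric(n)
  rec <- function(i, mass) {
    if (i > n || mass == 0) return()
    p <- conditional[i]
    marg[i] <<- marg[i] + mass * p
    if (terminates[i]) {
      rec(i + 1L, mass * (1 - p))
    } else {
      rec(i + 1L, mass * p)
      rec(i + 1L, mass * (1 - p))
    }
  }
  rec(1L, 1)
  marg
}
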