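# Independent oracles used across tests. These deliberately recompute
# everything from scratch (no incremental bookkeeping) so they stay
# independent of the implementation paths they check.

# pooled within-SS of a set of values about their mean
ss_oracle <- function(v) sum((v - mean(v))^2)

# exhaustive greedy CONISS: blocks as a list of index vectors; at every
# step recompute the pooled-SS increase of every adjacent merger in full
# and fuse the minimum (ties: oldest pair, i.e. largest index).
coniss_oracle <- function(values, transform = "sqrt") {
  v <- if (transform == "sqrt") sqrt(values) else values
  blocks <- as.list(seq_along(v))
  merges <- data.frame(boundary = integer(0), increment = numeric(0))
  while (length(blocks) > 1L) {
    inc <- vapply(seq_len(length(blocks) - 1L), function(j) {
      ss_oracle(v[c(blocks[[j]], blocks[[j + 1L]])]) -
        ss_oracle(v[blocks[[j]]]) - ss_oracle(v[blocks[[j + 1L]]])
    }, numeric(1))
    cand <- which(inc == min(inc))
    j <- cand[length(cand)]
    merges <- rbind(merges, data.frame(
      boundary = max(blocks[[j]]), increment = inc[j]))
    blocks[[j]] <- c(blocks[[j]], blocks[[j + 1L]])
    blocks[[j + 1L]] <- NULL
  }
  merges
}

# two-point linear interpolation written out longhand
interp_oracle <- function(age, value, targets) {
  vapply(targets, function(a) {
    if (a < min(age) || a > max(age)) return(NA_real_)
    i <- findInterval(a, age)
    if (age[i] == a) return(value[i])
    value[i] + (value[i + 1L] - value[i]) * (a - age[i]) / (age[i + 1L] - age[i])
  }, numeric(1))
}

# convenience: a two-regime series mirroring the Holocene geometry
two_regime_record <- function(seed) generate_record(holocene_preset(seed = seed))
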