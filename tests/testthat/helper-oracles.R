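# Independent oracle for the toy-family MCMC chain: exact enumeration of the
# 16-state transition kernel (2 proteins x 2 columns over {A, V}, one contact
# A2-B1, full per-step resampling, Hastings-corrected acceptance), and its
# stationary distribution.

toy_chain_oracle <- function(fam, pd, sub, temperature = 1) {
  codes <- c(1L, 18L)                      # A, V
  states <- as.matrix(expand.grid(a1 = codes, a2 = codes, b1 = codes, b2 = codes))
  n_st <- nrow(states)
  lut <- rbind(fam$profile_a$log_odds, fam$profile_a$gap_penalty)
  f <- apply(states, 1, function(st) {
    sum(lut[cbind(st[1:2], 1:2)]) + sum(lut[cbind(st[3:4], 1:2)])
  })
  find_state <- function(v) which(colSums(abs(t(states) - v)) == 0)
  P <- matrix(0, n_st, n_st)
  for (i in seq_len(n_st)) {
    st <- states[i, ]
    for (b1n in codes) for (a1n in codes) for (b2n in codes) {
      # label 1: fair coin fixed the A side; b1 resampled from P(b | a2)
      qf <- pd$cond_b_given_a[st[2], b1n] * sub[st[1], a1n] * sub[st[4], b2n]
      qr <- pd$cond_b_given_a[st[2], st[3]] * sub[a1n, st[1]] * sub[b2n, st[4]]
      j <- find_state(c(a1n, st[2], b1n, b2n))
      alpha <- min(1, exp((f[j] - f[i]) / temperature) * qr / qf)
      P[i, j] <- P[i, j] + 0.5 * qf * alpha
    }
    for (a2n in codes) for (a1n in codes) for (b2n in codes) {
      # label 2: coin fixed the B side; a2 resampled from P(a | b1)
      qf <- pd$cond_a_given_b[st[3], a2n] * sub[st[1], a1n] * sub[st[4], b2n]
      qr <- pd$cond_a_given_b[st[3], st[2]] * sub[a1n, st[1]] * sub[b2n, st[4]]
      j <- find_state(c(a1n, a2n, st[3], b2n))
      alpha <- min(1, exp((f[j] - f[i]) / temperature) * qr / qf)
      P[i, j] <- P[i, j] + 0.5 * qf * alpha
    }
    P[i, i] <- P[i, i] + (1 - sum(P[i, ]))
  }
  ev <- eigen(t(P))
  k <- which.min(abs(ev$values - 1))
  stat <- Re(ev$vectors[, k]); stat <- stat / sum(stat)
  list(states = states, transition = P, stationary = stat,
       fitness = f, find_state = find_state)
}
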