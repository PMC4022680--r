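# Independent brute-force re-implementations of the two core operations,
# written link-by-link from the closed-form update rules. They deliberately
# share no code with the package internals.

# Link transfer, literal per-link form: a cross-area link shrinks by the
# transfer fraction; a within-area link gains an equal share of the owner's
# total cross-area loss. Owner alone in its area: row untouched. No split:
# matrix untouched.
bf_transfer_update <- function(w, assign, transfer) {
  n <- nrow(w)
  f <- transfer / 100
  if (length(unique(assign)) < 2L) return(w)
  out <- w
  for (i in seq_len(n)) {
    N <- sum(assign == assign[i]) - 1L
    if (N == 0L) next
    total_loss <- 0
    for (j in seq_len(n))
      if (j != i && assign[j] != assign[i]) total_loss <- total_loss + w[i, j] * f
    for (k in seq_len(n)) {
      if (k == i) next
      out[i, k] <- if (assign[k] != assign[i]) w[i, k] * (1 - f)
                   else w[i, k] + total_loss / N
    }
  }
  out
}

# Movement probabilities, literal sum over occupants.
bf_move_probabilities <- function(w, i, occupancy, C, lambda1, lambda2) {
  s1 <- 0; s2 <- 0
  for (k in seq_len(nrow(w))) {
    if (k == i) next
    if (occupancy[k] == 1L) s1 <- s1 + w[i, k]
    if (occupancy[k] == 2L) s2 <- s2 + w[i, k]
  }
  c(p1 = lambda1 + C * s1, p2 = lambda2 + C * s2)
}

# All 1/2 assignments of n individuals.
all_assignments <- function(n) {
  as.matrix(expand.grid(rep(list(1:2), n)))
}

# A random valid grooming network (rows sum to 100).
random_network <- function(n) {
  w <- matrix(stats::runif(n * n, 0.1, 1), n, n)
  diag(w) <- 0
  w <- 100 * w / rowSums(w)
  social_network(w)
}
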