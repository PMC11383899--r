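# Independent brute-force oracles used to validate the analytic test
# implementations. These deliberately share no code with the package:
# straight enumeration over tables, assignments, sign patterns and
# within-row permutations.

oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  total <- 0; p_obs <- NA
  for (x in 0:min(r1, c1)) {
    y <- c1 - x
    if (y < 0 || y > r2) next
    p <- choose(r1, x) * choose(r2, y) / choose(r1 + r2, c1)
    if (x == a) p_obs <- p
  }
  for (x in 0:min(r1, c1)) {
    y <- c1 - x
    if (y < 0 || y > r2) next
    p <- choose(r1, x) * choose(r2, y) / choose(r1 + r2, c1)
    if (p <= p_obs * (1 + 1e-12)) total <- total + p
  }
  total
}

oracle_mw <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  us <- utils::combn(N, n, FUN = function(idx)
    sum(r[idx]) - n * (n + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

oracle_wsr <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  ws <- vapply(0:(2^n - 1), function(mask) {
    keep <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[keep])
  }, numeric(1))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# All (k!)^n rearrangements of each row's midranks; p = P(Q >= Q_obs).
oracle_friedman <- function(blocks) {
  n <- nrow(blocks); k <- ncol(blocks)
  R <- t(apply(blocks, 1, rank))
  q_of <- function(cs) 12 / (n * k * (k + 1)) * sum(cs^2) - 3 * n * (k + 1)
  perm_rows <- lapply(seq_len(n), function(i) {
    p <- all_perms(k)
    unique(t(apply(p, 1, function(idx) R[i, idx])))
  })
  grids <- lapply(perm_rows, function(m) seq_len(nrow(m)))
  combos <- expand.grid(grids)
  qs <- apply(combos, 1, function(sel) {
    cs <- colSums(do.call(rbind, lapply(seq_len(n), function(i)
      perm_rows[[i]][sel[i], ])))
    q_of(cs)
  })
  q_obs <- q_of(colSums(R))
  mean(qs >= q_obs - 1e-9)
}

all_perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_perms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    shifted <- cbind(i, sub + (sub >= i))
    out <- rbind(out, shifted)
  }
  out
}

oracle_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) {
        rank_j <- sum(p <= p[j])
        cand <- min(cand, p[j] * m / rank_j)
      }
    }
    q[i] <- min(1, cand)
  }
  q
}
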