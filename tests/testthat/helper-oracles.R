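# Independent oracles and small fixtures shared across tests.

# Constrained least squares by Lagrange-multiplier normal equations:
# minimize ||m - (gamma + lambda_tail - lambda_head)||^2 s.t. sum(lambda) = 0.
# Independent of the package's drop-one/QR route.  Returns NULL when the
# bordered system is singular.
oracle_constrained_ls <- function(tails, heads, m) {
  units <- unique(c(tails, heads))
  p <- length(units)
  x <- cbind(1, outer(tails, units, "==") - outer(heads, units, "=="))
  a <- rbind(cbind(t(x) %*% x, c(0, rep(1, p))),
             c(0, rep(1, p), 0))
  b <- c(t(x) %*% m, 0)
  z <- tryCatch(solve(a, b), error = function(e) NULL)
  if (is.null(z)) return(NULL)
  # bordered system can be solvable even when the LS problem is not unique;
  # verify uniqueness via the rank of the constrained design
  xc <- x[, -p - 1L, drop = FALSE] -
    cbind(0, matrix(rep(x[, p + 1L], p - 1L), ncol = p - 1L))
  if (qr(xc)$rank < p) return(NULL)
  gamma <- z[1L]
  lambda <- stats::setNames(z[2:(p + 1L)], units)
  fitted <- x %*% z[seq_len(p + 1L)]
  list(gamma = gamma, lambda = lambda, rss = sum((m - fitted)^2))
}

# Hypergeometric upper tail P(X >= k) by direct enumeration of the pmf
# via log-binomials (never calls phyper).
oracle_hyper_tail <- function(k, list_size, K, N) {
  lo <- max(0, K + list_size - N)
  hi <- min(K, list_size)
  if (k > hi) return(0)
  i <- max(k, lo):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, list_size - i) -
            lchoose(N, list_size)))
}

# A 3-unit directed triangle, the smallest design with gamma identifiable.
toy_triangle <- function() {
  loop_design(
    units = data.frame(unit_id = c("A", "B", "C"),
                       individual = c("A", "B", "C")),
    arrays = data.frame(array_id = c("a1", "a2", "a3"),
                        tail = c("A", "B", "C"),
                        head = c("B", "C", "A"))
  )
}

# Random connected design: a directed cycle over n units plus extra chords.
random_design <- function(n_units, n_extra = 2L) {
  ids <- paste0("u", seq_len(n_units))
  ord <- sample(ids)
  tails <- ord
  heads <- ord[c(2:n_units, 1L)]
  for (k in seq_len(n_extra)) {
    pair <- sample(ids, 2L)
    tails <- c(tails, pair[1L])
    heads <- c(heads, pair[2L])
  }
  loop_design(
    units = data.frame(unit_id = ids, individual = ids),
    arrays = data.frame(array_id = paste0("a", seq_along(tails)),
                        tail = tails, head = heads)
  )
}

fig1 <- fig1_design()
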