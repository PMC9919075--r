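# Independent oracles, written as literal step-by-step evaluations so they
# share no code path with the package implementations they check.

# Deng's relational degree, five explicit steps with scalar loops.
oracle_gra <- function(y0, X, rho = 0.5, normalization = "mean") {
  norm1 <- function(v) {
    if (normalization == "mean") v / mean(v)
    else if (normalization == "initial") v / v[1]
    else v
  }
  yn <- norm1(y0)
  n <- length(y0); p <- ncol(X)
  Xn <- matrix(0, n, p)
  for (j in seq_len(p)) Xn[, j] <- norm1(X[, j])
  delta <- matrix(0, n, p)
  for (j in seq_len(p)) for (k in seq_len(n)) {
    delta[k, j] <- abs(yn[k] - Xn[k, j])
  }
  dmin <- Inf; dmax <- -Inf
  for (j in seq_len(p)) for (k in seq_len(n)) {
    if (delta[k, j] < dmin) dmin <- delta[k, j]
    if (delta[k, j] > dmax) dmax <- delta[k, j]
  }
  r <- numeric(p)
  for (j in seq_len(p)) {
    xi <- numeric(n)
    for (k in seq_len(n)) {
      xi[k] <- (dmin + rho * dmax) / (delta[k, j] + rho * dmax)
    }
    r[j] <- mean(xi)
  }
  r
}

# Upper hypergeometric tail P(X >= k) by summing binomial-coefficient counts
# of the favourable draws (complete enumeration of overlap counts).
oracle_hyper_tail <- function(N, K, n, k) {
  total <- choose(N, n)
  hits <- 0
  for (i in seq(k, min(K, n))) {
    hits <- hits + choose(K, i) * choose(N - K, n - i)
  }
  hits / total
}

# Literal enumeration over every possible study set of size n from a
# universe of size N: fraction with overlap >= k against a fixed term.
oracle_hyper_enum <- function(N, K, n, k) {
  universe <- seq_len(N)
  term <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(s) length(intersect(s, term)) >= k))
}

# Minimal total |delta rt| over all injective assignments of sample peaks to
# reference peaks within the window (exhaustive; use only for <= 6 peaks).
oracle_assignment_cost <- function(reference, sample_rt, window) {
  nr <- length(reference)
  ns <- length(sample_rt)
  best <- list(cost = Inf, matched = -1L)
  recurse <- function(r, used, cost, matched) {
    if (r > nr) {
      if (matched > best$matched ||
          (matched == best$matched && cost < best$cost)) {
        best <<- list(cost = cost, matched = matched)
      }
      return(invisible())
    }
    recurse(r + 1L, used, cost, matched)   # leave reference peak r unmatched
    for (s in seq_len(ns)) {
      d <- abs(reference[r] - sample_rt[s])
      if (!used[s] && d <= window) {
        used[s] <- TRUE
        recurse(r + 1L, used, cost + d, matched + 1L)
        used[s] <- FALSE
      }
    }
  }
  recurse(1L, logical(ns), 0, 0L)
  best
}

# A small random instance shared by several property tests.
random_instance <- function(seed, n = 10, p = 20) {
  set.seed(seed)
  X <- matrix(rlnorm(n * p, 0, 0.5), n, p,
              dimnames = list(sprintf("S%d", 1:n), sprintf("P%d", 1:p)))
  y <- rlnorm(n, 2, 0.3)
  list(X = X, y = y)
}
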