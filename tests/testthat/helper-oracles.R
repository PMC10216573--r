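# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (explicit loops, no shared code with R/) so they can
# arbitrate the vectorized implementations.

# Pearson correlation matrix from first principles, O(R^2 * T)
naive_cor_matrix <- function(ts) {
  R <- ncol(ts); T_len <- nrow(ts)
  out <- matrix(0, R, R)
  for (i in 1:R) {
    for (j in 1:R) {
      xi <- ts[, i] - mean(ts[, i])
      yj <- ts[, j] - mean(ts[, j])
      out[i, j] <- sum(xi * yj) / sqrt(sum(xi^2) * sum(yj^2))
    }
  }
  out
}

# Benjamini-Hochberg step-up by direct enumeration of the rule
bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0
  for (k in 1:m) if (ps[k] <= k * q / m) kmax <- k
  rej <- logical(m)
  if (kmax > 0) rej[ord[1:kmax]] <- TRUE
  rej
}

# connected components of an undirected edge list by flood fill
floodfill_components <- function(edges, n_nodes) {
  if (nrow(edges) == 0) return(list())
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n_nodes)
  comps <- list()
  for (v in seq_len(n_nodes)) {
    if (seen[v] || is.null(adj[[v]])) next
    queue <- v; members <- integer(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (seen[u]) next
      seen[u] <- TRUE
      members <- c(members, u)
      queue <- c(queue, adj[[u]])
    }
    members <- sort(members)
    in_comp <- edges[, 1] %in% members & edges[, 2] %in% members
    comps[[length(comps) + 1]] <-
      list(nodes = members, extent = sum(in_comp))
  }
  comps
}

# literal per-edge coupling loops (no matrix indexing tricks)
naive_whole_brain <- function(sc, fc) {
  R <- nrow(sc)
  scv <- c(); fcv <- c()
  for (i in 1:(R - 1)) for (j in (i + 1):R) {
    if (sc[i, j] > 0) {
      scv <- c(scv, sc[i, j]); fcv <- c(fcv, fc[i, j])
    }
  }
  n <- length(scv)
  r <- rank(scv, ties.method = "average")
  g <- qnorm((r - 0.375) / (n + 0.25))
  cor(g, fcv)
}

naive_node_coupling <- function(sc, fc, i) {
  scv <- c(); fcv <- c()
  for (j in seq_len(nrow(sc))) if (j != i) {
    scv <- c(scv, sc[i, j]); fcv <- c(fcv, fc[i, j])
  }
  cor(scv, fcv)
}

naive_global_network <- function(sc, fc, atlas, nw) {
  mem <- which(atlas$network == nw)
  if (length(mem) < 3) return(NA_real_)
  scv <- c(); fcv <- c()
  for (a in seq_along(mem)) for (b in seq_along(mem)) {
    if (a < b) {
      scv <- c(scv, sc[mem[a], mem[b]]); fcv <- c(fcv, fc[mem[a], mem[b]])
    }
  }
  cor(scv, fcv)
}

naive_partner_coupling <- function(sc, fc, atlas, i, same_network) {
  scv <- c(); fcv <- c()
  for (j in seq_len(nrow(sc))) {
    if (j == i) next
    same <- atlas$network[j] == atlas$network[i]
    if (same == same_network) {
      scv <- c(scv, sc[i, j]); fcv <- c(fcv, fc[i, j])
    }
  }
  if (length(scv) < 3) return(NA_real_)
  cor(scv, fcv)
}

# random symmetric matrix with zero diagonal, entries in [lo, hi]
random_symmetric <- function(R, lo = -1, hi = 1) {
  m <- matrix(0, R, R)
  m[upper.tri(m)] <- runif(R * (R - 1) / 2, lo, hi)
  m + t(m)
}

# closed-form Jensen-Shannon divergence (base 2) between two normal
# densities by adaptive quadrature
jsd_normals_quadrature <- function(m1, s1, m2, s2) {
  f <- function(x) dnorm(x, m1, s1)
  g <- function(x) dnorm(x, m2, s2)
  term <- function(d1) {
    function(x) {
      a <- d1(x); m <- (f(x) + g(x)) / 2
      out <- ifelse(a > 0, a * log2(a / m), 0)
      out[!is.finite(out)] <- 0
      out
    }
  }
  lo <- min(m1 - 9 * s1, m2 - 9 * s2)
  hi <- max(m1 + 9 * s1, m2 + 9 * s2)
  0.5 * integrate(term(f), lo, hi, rel.tol = 1e-9)$value +
    0.5 * integrate(term(g), lo, hi, rel.tol = 1e-9)$value
}

# small matched SC/FC pair with positive baseline agreement plus noise
random_coupled_pair <- function(R, seed) {
  set.seed(seed)
  base <- random_symmetric(R, 0.05, 0.95)
  fc <- base + random_symmetric(R, -0.3, 0.3)
  fc <- pmin(pmax(fc, -1), 1)
  diag(fc) <- 0
  list(sc = base, fc = fc)
}
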