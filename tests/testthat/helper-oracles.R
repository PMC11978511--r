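# brute-force betweenness oracle: enumerate all shortest vertex paths by BFS
oracle_betweenness <- function(edges, n) {
  adj <- lapply(seq_len(n), function(i) integer())
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    if (a == b) next
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    # BFS shortest paths from s, counting paths
    dist <- rep(Inf, n); sigma <- numeric(n)
    dist[s] <- 0; sigma[s] <- 1
    q <- s
    order <- integer()
    while (length(q)) {
      v <- q[1]; q <- q[-1]; order <- c(order, v)
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; q <- c(q, w) }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    if (is.infinite(dist[t]) || sigma[t] == 0) next
    # count, for every interior v, the shortest s-t paths through v
    for (v in seq_len(n)) {
      if (v == s || v == t || is.infinite(dist[v])) next
      if (dist[v] + 1 > dist[t]) next
      # sigma from t side
      dist2 <- rep(Inf, n); sigma2 <- numeric(n)
      dist2[t] <- 0; sigma2[t] <- 1
      q2 <- t
      while (length(q2)) {
        u <- q2[1]; q2 <- q2[-1]
        for (w in adj[[u]]) {
          if (is.infinite(dist2[w])) { dist2[w] <- dist2[u] + 1; q2 <- c(q2, w) }
          if (dist2[w] == dist2[u] + 1) sigma2[w] <- sigma2[w] + sigma2[u]
        }
      }
      if (dist[v] + dist2[v] == dist[t])
        btw[v] <- btw[v] + sigma[v] * sigma2[v] / sigma[t]
    }
  }
  btw
}
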