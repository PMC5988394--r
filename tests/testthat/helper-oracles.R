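# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/.

# O(N^2) sample-entropy by direct template enumeration
brute_sampen <- function(x, m = 2L, tau = 1L, r_factor = 0.2) {
  n <- length(x)
  sd_pop <- sqrt(mean((x - mean(x))^2))
  if (sd_pop == 0) return(0)
  r <- r_factor * sd_pop
  ntempl <- n - m * tau
  templ_m <- vapply(seq_len(ntempl), function(i) x[i + (0:(m - 1)) * tau],
                    numeric(m))
  templ_m1 <- vapply(seq_len(ntempl), function(i) x[i + (0:m) * tau],
                     numeric(m + 1))
  dim(templ_m) <- c(m, ntempl)
  dim(templ_m1) <- c(m + 1, ntempl)
  A <- 0L; B <- 0L
  for (i in seq_len(ntempl - 1L)) {
    for (j in (i + 1L):ntempl) {
      if (max(abs(templ_m[, i] - templ_m[, j])) <= r) {
        B <- B + 1L
        if (max(abs(templ_m1[, i] - templ_m1[, j])) <= r) A <- A + 1L
      }
    }
  }
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)
}

# triangle-enumeration clustering coefficient
brute_cc <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]] == 1) tri <- tri + 1
    2 * tri / (k * (k - 1))
  })
}

# breadth-first-search connected components; returns membership vector
brute_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] == 1 & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# all-pairs BFS shortest paths -> mean over unordered pairs (connected only)
brute_path_length <- function(adj) {
  n <- nrow(adj)
  total <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] == 1 & is.infinite(dist))
      dist[nb] <- dist[v] + 1
      queue <- c(queue, nb)
    }
    total <- total + sum(dist[-s])
  }
  total / (n * (n - 1))
}

# direct Eq.-style participation coefficient
brute_pc <- function(adj, labels) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    k <- sum(adj[i, ])
    if (k == 0) return(0)
    1 - sum(sapply(unique(labels),
                   function(m) (sum(adj[i, labels == m]) / k)^2))
  })
}

# random symmetric hollow binary adjacency
random_adjacency <- function(n, p = 0.3) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1L, p)
  a + t(a)
}

# random connected adjacency (rejection sampling)
random_connected_adjacency <- function(n, p = 0.4, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    a <- random_adjacency(n, p)
    if (length(unique(brute_components(a))) == 1L) return(a)
  }
  stop("failed to sample a connected graph")
}

# adjacency from a graph index: bits of `idx` fill the upper triangle
index_to_adjacency <- function(idx, n) {
  nb <- n * (n - 1L) / 2L
  bits <- as.integer(intToBits(idx))[seq_len(nb)]
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- bits
  a + t(a)
}
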