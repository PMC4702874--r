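# Independent oracles and small generators used across the suite. These are
# deliberately written from first principles (breadth-first search, brute
# force distance scans, generic least-squares pseudo-inverse) so that they
# share no code path with the implementation they check.

# Breadth-first-search component labelling over a 0/1 adjacency matrix.
bfs_components <- function(adj) {
  n <- nrow(adj)
  label <- rep(NA_integer_, n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (!is.na(label[start])) next
    comp <- comp + 1L
    queue <- start
    label[start] <- comp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] != 0 & is.na(label))
      label[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  label
}

# Random point cloud in a cubic box; density tuned so the 7.3 A contact
# graph is usually connected. Resamples (deterministically) until connected
# when `connected = TRUE`.
random_points <- function(n, seed, connected = TRUE, cutoff = 7.3) {
  for (try in 0:50) {
    xyz <- gnmkit:::with_seed(seed + 1000L * try,
                              matrix(runif(3 * n, 0, (n * 60)^(1/3)),
                                     ncol = 3))
    if (!connected) return(xyz)
    d <- as.matrix(dist(xyz))
    adj <- (d <= cutoff) & upper.tri(d)
    adj <- adj | t(adj)
    if (max(bfs_components(adj * 1)) == 1L) return(xyz)
  }
  stop("could not generate a connected cloud for n = ", n)
}

# Brute-force O(N^2) contact oracle.
brute_contacts <- function(xyz, cutoff) {
  d <- as.matrix(dist(xyz))
  out <- (d <= cutoff) * 1
  diag(out) <- 0
  unname(out)
}

# Laplacian straight from the contact oracle.
brute_laplacian <- function(xyz, cutoff) {
  a <- brute_contacts(xyz, cutoff)
  diag(a) <- 0
  l <- -a
  diag(l) <- rowSums(a)
  l
}

# Minimal hand-built mode object (for closed-form collectivity checks etc.).
fake_modes <- function(values, vectors, n_zero = 1L) {
  structure(list(values = values, vectors = vectors,
                 n_zero = n_zero, n = nrow(vectors)),
            class = "gnm_modes")
}

fixture_path <- function(...) {
  f <- tempfile(fileext = ".pdb")
  gnm_fixture(..., path = f)
  f
}

run_gnm_on <- function(path, cutoff = 7.3) {
  nodes <- select_nodes(read_structure(path))
  k <- build_kirchhoff(nodes, cutoff = cutoff)
  modes <- gnm_modes(k)
  list(nodes = nodes, k = k, modes = modes, profile = gnm_profile(modes))
}
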