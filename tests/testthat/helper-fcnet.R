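# Shared fixtures and independent brute-force oracles for the graph metrics.

rand_sym_matrix <- function(K, seed) {
  set.seed(seed)
  W <- matrix(0, K, K)
  W[upper.tri(W)] <- runif(K * (K - 1) / 2)
  W <- W + t(W)
  dimnames(W) <- list(paste0("n", 1:K), paste0("n", 1:K))
  W
}

rand_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
  A
}

# all-pairs shortest paths, Floyd-Warshall triple loop
oracle_fw <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_cpl <- function(A) {
  D <- oracle_fw(A)
  diag(D) <- NA
  li <- apply(D, 1, function(row) {
    fin <- row[is.finite(row) & !is.na(row)]
    if (length(fin) == 0) 0 else mean(fin)
  })
  mean(li)
}

# per-node clustering by exhaustive triangle counting
oracle_clustering <- function(A) {
  n <- nrow(A)
  sapply(1:n, function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    t_i <- sum(A[nb, nb]) / 2
    2 * t_i / (k * (k - 1))
  })
}

# betweenness by explicit enumeration of every shortest path
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_fw(A)
  b <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    paths <- list()
    walk <- function(v, path) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- path
        return(invisible(NULL))
      }
      for (w in which(A[v, ] == 1)) {
        if (is.finite(D[w, t]) && D[v, t] == D[w, t] + 1) walk(w, c(path, w))
      }
    }
    walk(s, s)
    interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(interior)) {
      cnt <- table(interior)
      idx <- as.integer(names(cnt))
      b[idx] <- b[idx] + as.numeric(cnt) / length(paths)
    }
  }
  b
}

# two pure sinusoids with a fixed phase offset
sine_pair <- function(freq_hz = 10, phase = pi / 2, duration_s = 30, fs = 250) {
  tt <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  region_recording(rbind(sin(2 * pi * freq_hz * tt),
                         sin(2 * pi * freq_hz * tt - phase)),
                   fs, c("a", "b"))
}

white_recording <- function(K, duration_s, fs = 250, seed = 1) {
  set.seed(seed)
  region_recording(matrix(rnorm(K * duration_s * fs), K), fs)
}

band_icoh_of <- function(recording, band) {
  sp <- epoch_spectra(segment_epochs(recording))
  imaginary_coherence(sp, band)
}
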