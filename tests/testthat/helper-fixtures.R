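## Shared fixtures (built in code) and independent brute-force oracles.

smallParcellation <- function() generateParcellation(8L, 4L)

smallConfig <- function(...) {
  defaults <- list(nCorticalPerHemi = 8L, nSubcortical = 4L, nSites = 3L,
                   nPatients = 60L, nControls = 60L,
                   epicenterRegions = c("L_ctx_03", "R_ctx_03"))
  do.call(GenerativeConfig, utils::modifyList(defaults, list(...)))
}

## Minimal all-cortical parcellation with n nodes (n even), for wrapping raw
## weight matrices in the graph-metric oracles.
graphParcellation <- function(n) {
  stopifnot(n %% 2 == 0)
  half <- n %/% 2
  a <- seq(0.3, 1.2, length.out = half)
  b <- seq(0, 2, length.out = half)
  left <- cbind(-cos(a), sin(a) * cos(b), sin(a) * sin(b))
  right <- left %*% diag(c(-1, 1, 1))
  Parcellation(c(sprintf("L_n%02d", seq_len(half)),
                 sprintf("R_n%02d", seq_len(half))),
               rep(c("left", "right"), each = half),
               rep("cortical", n), rbind(left, right))
}

graphConn <- function(W, modality = "functional") {
  parc <- graphParcellation(nrow(W))
  dimnames(W) <- NULL
  preprocessConnectivity(ConnectivityMatrix(W, parc, modality))
}

## Dense random connected weighted graph (zero diagonal, symmetric).
randomGraphMatrix <- function(n, seed) {
  set.seed(seed)
  W <- matrix(runif(n * n, 0.1, 2), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

## A zero-effect ground truth for null simulations.
nullTruth <- function(parc) {
  list(delta = RegionalMap(rep(0, length(regionNames(parc))), parc, "all",
                           "effect"),
       epicenters = "L_ctx_03", bEpi = 0, bHub = 0)
}

## --- brute-force oracles -------------------------------------------------

## Power iteration for the leading eigenvector, scaled to unit maximum.
powerIterationOracle <- function(W, iters = 500L, tol = 1e-12) {
  v <- rep(1, nrow(W))
  for (i in seq_len(iters)) {
    vn <- W %*% v
    vn <- vn / sqrt(sum(vn^2))
    if (max(abs(vn - v)) < tol) break
    v <- vn
  }
  as.vector(abs(vn) / max(abs(vn)))
}

## Floyd-Warshall distances and shortest-path counts under 1/weight lengths.
fwPaths <- function(W, tol = 1e-12) {
  n <- nrow(W)
  d <- ifelse(W > 0, 1 / W, Inf)
  diag(d) <- 0
  sigma <- ifelse(W > 0, 1, 0)
  diag(sigma) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || i == k || j == k) next
    alt <- d[i, k] + d[k, j]
    if (alt < d[i, j] - tol) {
      d[i, j] <- alt
      sigma[i, j] <- sigma[i, k] * sigma[k, j]
    } else if (abs(alt - d[i, j]) <= tol && is.finite(alt)) {
      sigma[i, j] <- sigma[i, j] + sigma[i, k] * sigma[k, j]
    }
  }
  list(d = d, sigma = sigma)
}

## Brandes-equivalent betweenness by explicit all-pairs enumeration
## (endpoints excluded, each unordered pair counted once).
bruteBetweenness <- function(W, tol = 1e-12) {
  n <- nrow(W)
  fp <- fwPaths(W, tol)
  b <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    if (v == s || v == t || !is.finite(fp$d[s, t]) || fp$sigma[s, t] == 0)
      next
    if (abs(fp$d[s, v] + fp$d[v, t] - fp$d[s, t]) <= tol)
      b[v] <- b[v] + fp$sigma[s, v] * fp$sigma[v, t] / fp$sigma[s, t]
  }
  b
}

bruteCloseness <- function(W) {
  fp <- fwPaths(W)
  (nrow(W) - 1) / rowSums(fp$d)
}

## Step-up Benjamini-Hochberg from the definition
## q_i = min_{j >= i} min(1, p_(j) * m / j).
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min((m / seq(i, m)) * ps[seq(i, m)]))
  out <- numeric(m)
  out[o] <- q
  out
}
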