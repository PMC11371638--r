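## Spatial-autocorrelation-preserving nulls: mirrored spherical rotations
## with nearest-centroid reassignment for cortical maps, uniform label
## shuffles for subcortical maps. P-values use the add-one rule so they are
## never zero: p = (1 + #{null >= observed}) / (nPerm + 1).

## Uniform random proper rotation: QR of a Gaussian matrix with the sign
## convention fixed, determinant forced to +1.
.randomRotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Build a spin permutation null
#'
#' Draws \code{nPerm} uniformly random 3D rotations; each is applied to the
#' left-hemisphere cortical centroids and its x-mirror to the right
#' hemisphere, keeping the two nulls anatomically matched. Every rotated
#' parcel is then reassigned the value of the nearest original centroid
#' (great-circle distance) within its hemisphere, so repeats are allowed.
#'
#' @param parcellation a \linkS4class{Parcellation} with cortical centroids
#' @param nPerm number of rotations (default 10000; fewer than 100 triggers
#'   a warning because the p-value floor becomes coarse)
#' @param seed integer seed
#' @return a \linkS4class{SpinNull}
#' @export
buildSpinRotations <- function(parcellation, nPerm = 10000L, seed = 1L) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) warning("nPerm < 100: unstable p-value floor")
  ctx <- which(parcellation@structure == "cortical")
  hemi <- parcellation@hemisphere[ctx]
  CL <- parcellation@centroids[ctx[hemi == "left"], , drop = FALSE]
  CR <- parcellation@centroids[ctx[hemi == "right"], , drop = FALSE]
  M <- diag(c(-1, 1, 1))
  idxL <- which(hemi == "left")
  idxR <- which(hemi == "right")
  out <- matrix(NA_integer_, nPerm, length(ctx))
  set.seed(seed)
  for (pIdx in seq_len(nPerm)) {
    R <- .randomRotation()
    rotL <- CL %*% t(R)
    rotR <- CR %*% t(M %*% R %*% M)
    ## nearest original centroid = max cosine similarity
    out[pIdx, idxL] <- idxL[max.col(rotL %*% t(CL), ties.method = "first")]
    out[pIdx, idxR] <- idxR[max.col(rotR %*% t(CR), ties.method = "first")]
  }
  new("SpinNull", indices = out, seed = as.integer(seed),
      parcellation = parcellation)
}

## Row-standardize a matrix (each row centered, scaled to unit SD).
.standardizeRows <- function(M) {
  mu <- rowMeans(M)
  M <- M - mu
  s <- sqrt(rowSums(M^2) / (ncol(M) - 1))
  M / s
}

## Null correlations of the permuted x against one intact y.
.permCors <- function(x, P, y) {
  M <- matrix(x[P], nrow(P), ncol(P))
  yc <- y - mean(y)
  ys <- sqrt(sum(yc^2))
  mu <- rowMeans(M)
  num <- as.vector(M %*% yc)            # row centering drops out: sum(yc)=0
  den <- sqrt(rowSums(M^2) - ncol(P) * mu^2) * ys
  num / den
}

.tailP <- function(rObs, rNull, tail) {
  n <- length(rNull)
  k <- switch(tail,
              two = sum(abs(rNull) >= abs(rObs)),
              positive = sum(rNull >= rObs),
              negative = sum(rNull <= rObs))
  (1 + k) / (n + 1)
}

#' Spin-test p-value for the correlation of two cortical maps
#'
#' Pearson correlation of two cortical maps with a spatial null obtained by
#' permuting \code{mapX}'s values by each rotation of the
#' \linkS4class{SpinNull} against the intact \code{mapY}. Which map is
#' rotated is explicit in the argument order.
#'
#' @param mapX,mapY cortical \linkS4class{RegionalMap}s on the null's
#'   parcellation; \code{mapX} is the one rotated
#' @param null a \linkS4class{SpinNull}
#' @param tail \code{two} (default), \code{positive} or \code{negative}
#' @return list with \code{r} (observed Pearson r), \code{p} (add-one spin
#'   p-value) and \code{nPerm}
#' @export
spinPvalue <- function(mapX, mapY, null, tail = c("two", "positive",
                                                  "negative")) {
  tail <- match.arg(tail)
  if (mapX@scope != "cortical" || mapY@scope != "cortical")
    stop("spin test applies to cortical maps")
  if (!identical(names(mapX@values), names(mapY@values)))
    stop("maps must share a parcellation")
  x <- mapX@values; y <- mapY@values
  if (sd(x) == 0 || sd(y) == 0) stop("constant map: correlation undefined")
  rObs <- cor(x, y)
  rNull <- .permCors(x, null@indices, y)
  list(r = rObs, p = .tailP(rObs, rNull, tail), nPerm = nrow(null@indices))
}

#' Shuffle-test p-value for the correlation of two subcortical maps
#'
#' Subcortical structures are not projected onto spheres; the null instead
#' shuffles \code{mapX}'s labels uniformly at random.
#'
#' @param mapX,mapY subcortical \linkS4class{RegionalMap}s (>= 4 regions)
#' @param nPerm number of label permutations
#' @param seed integer seed
#' @param tail \code{two} (default), \code{positive} or \code{negative}
#' @return list with \code{r}, \code{p}, \code{nPerm}
#' @export
shufflePvalue <- function(mapX, mapY, nPerm = 10000L, seed = 1L,
                          tail = c("two", "positive", "negative")) {
  tail <- match.arg(tail)
  if (mapX@scope != "subcortical" || mapY@scope != "subcortical")
    stop("shuffle test applies to subcortical maps")
  x <- mapX@values; y <- mapY@values
  if (length(x) < 4) stop("need at least 4 regions")
  if (sd(x) == 0 || sd(y) == 0) stop("constant map: correlation undefined")
  set.seed(seed)
  n <- length(x)
  P <- t(replicate(nPerm, sample.int(n)))
  rObs <- cor(x, y)
  rNull <- .permCors(x, P, y)
  list(r = rObs, p = .tailP(rObs, rNull, tail), nPerm = as.integer(nPerm))
}

#' Export / import a spin null as TSV
#'
#' The index table can be reused across analyses so one null family serves
#' every map comparison. The seed is stored in a comment line.
#'
#' @param null a \linkS4class{SpinNull}
#' @param path TSV file path
#' @param parcellation the \linkS4class{Parcellation} the table was built on
#' @return [writeSpinNull()]: the path, invisibly; [readSpinNull()]: a
#'   \linkS4class{SpinNull}
#' @export
writeSpinNull <- function(null, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d", null@seed), con)
  write.table(null@indices, con, sep = "\t", quote = FALSE,
              row.names = FALSE,
              col.names = scopeRegions(null@parcellation, "cortical"))
  invisible(path)
}

#' @rdname writeSpinNull
#' @export
readSpinNull <- function(path, parcellation) {
  first <- readLines(path, n = 1)
  seed <- if (grepl("^# seed=", first))
    as.integer(sub("^# seed=", "", first)) else NA_integer_
  idx <- as.matrix(read.delim(path, comment.char = "#", check.names = FALSE))
  storage.mode(idx) <- "integer"
  expect <- scopeRegions(parcellation, "cortical")
  if (!identical(colnames(idx), expect))
    stop("spin null columns do not match the parcellation's cortical regions")
  dimnames(idx) <- NULL
  new("SpinNull", indices = idx, seed = seed, parcellation = parcellation)
}
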