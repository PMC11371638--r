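## Weighted-network preprocessing and nodal centrality, plus the
## hubs-most-affected ranking report. Path-based metrics interpret weights
## as connection strengths (edge length = 1/weight).

#' Nodal centrality profile of a connectome
#'
#' A \linkS4class{RegionalMap} of centrality values (kind
#' \code{centrality}) together with the metric, the modality of the source
#' matrix and the block scope (\code{cortico-cortical} or
#' \code{subcortico-cortical}).
#' @export
setClass("CentralityProfile",
  representation(map = "RegionalMap", metric = "character",
                 modality = "character", scope = "character"))

setMethod("show", "CentralityProfile", function(object) {
  cat(sprintf("CentralityProfile <%s %s, %s>: %d regions\n", object@modality,
              object@metric, object@scope, length(object@map@values)))
})

#' @rdname NetSuscept-accessors
setMethod("mapValues", "CentralityProfile", function(x) x@map@values)
#' @rdname NetSuscept-accessors
setMethod("parcellationOf", "CentralityProfile", function(x) x@map@parcellation)

#' Preprocess a connectivity matrix
#'
#' Functional matrices: negative weights set to 0 and diagonal zeroed.
#' Structural matrices: diagonal zeroed only (structural weights are already
#' nonnegative by construction). Provenance flags are recorded.
#'
#' @param conn a \linkS4class{ConnectivityMatrix}
#' @return the preprocessed \linkS4class{ConnectivityMatrix}
#' @export
preprocessConnectivity <- function(conn) {
  W <- conn@weights
  negZeroed <- conn@negativesZeroed
  if (conn@modality == "functional") {
    W[W < 0] <- 0
    negZeroed <- TRUE
  }
  diag(W) <- 0
  initialize(conn, weights = W, negativesZeroed = negZeroed,
             diagonalZeroed = TRUE)
}

.requirePreprocessed <- function(conn) {
  if (!conn@diagonalZeroed ||
      (conn@modality == "functional" && !conn@negativesZeroed))
    stop("connectivity must be preprocessed first (preprocessConnectivity)")
}

.ccGraph <- function(conn) {
  W <- corticoCortical(conn)
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

.profile <- function(values, conn, metric, scope) {
  p <- conn@parcellation
  mapScope <- if (scope == "subcortico-cortical") "subcortical" else "cortical"
  map <- RegionalMap(setNames(values, scopeRegions(p, mapScope)), p,
                     mapScope, "centrality")
  new("CentralityProfile", map = map, metric = metric,
      modality = conn@modality, scope = scope)
}

#' Weighted degree centrality
#'
#' Sum of weighted connections per region: for the cortico-cortical scope,
#' row sums of the cortical block; for the subcortico-cortical scope, each
#' subcortical region's summed connectivity to all cortical regions.
#'
#' @param conn a preprocessed \linkS4class{ConnectivityMatrix}
#' @param scope \code{cortico-cortical} or \code{subcortico-cortical}
#' @return a \linkS4class{CentralityProfile}
#' @export
degreeCentrality <- function(conn, scope = c("cortico-cortical",
                                             "subcortico-cortical")) {
  scope <- match.arg(scope)
  .requirePreprocessed(conn)
  vals <- if (scope == "cortico-cortical") rowSums(corticoCortical(conn))
          else rowSums(subcorticoCortical(conn))
  .profile(vals, conn, "degree", scope)
}

#' Eigenvector centrality
#'
#' Leading (Perron) eigenvector of the cortico-cortical weight block, scaled
#' to unit maximum. On a disconnected graph the leading eigenvector
#' concentrates on the largest component; a warning is emitted.
#'
#' @param conn a preprocessed \linkS4class{ConnectivityMatrix}
#' @return a \linkS4class{CentralityProfile}
#' @export
eigenvectorCentrality <- function(conn) {
  .requirePreprocessed(conn)
  g <- .ccGraph(conn)
  if (igraph::components(g)$no > 1)
    warning("graph disconnected; eigenvector concentrates on largest component")
  vals <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  .profile(pmax(vals, 0), conn, "eigenvector", "cortico-cortical")
}

#' Betweenness centrality
#'
#' Brandes betweenness on the cortico-cortical block with edge lengths
#' \code{1/weight} (zero-weight edges are absent); all shortest paths are
#' counted and endpoints are excluded.
#'
#' @param conn a preprocessed \linkS4class{ConnectivityMatrix}
#' @return a \linkS4class{CentralityProfile}
#' @export
betweennessCentrality <- function(conn) {
  .requirePreprocessed(conn)
  g <- .ccGraph(conn)
  vals <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                              directed = FALSE)
  .profile(vals, conn, "betweenness", "cortico-cortical")
}

#' Closeness centrality
#'
#' \code{(n-1) / sum_j dist(i,j)} with shortest-path distances under
#' inverse-weight edge lengths. If any pair is unreachable, the harmonic
#' variant \code{mean_j 1/dist(i,j)} is used instead, with a warning.
#'
#' @param conn a preprocessed \linkS4class{ConnectivityMatrix}
#' @return a \linkS4class{CentralityProfile}
#' @export
closenessCentrality <- function(conn) {
  .requirePreprocessed(conn)
  g <- .ccGraph(conn)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  n <- nrow(D)
  if (any(!is.finite(D))) {
    warning("unreachable pairs; using harmonic closeness")
    H <- 1 / D
    diag(H) <- 0
    H[!is.finite(H)] <- 0
    vals <- rowSums(H) / (n - 1)
  } else {
    vals <- (n - 1) / rowSums(D)
  }
  .profile(vals, conn, "closeness", "cortico-cortical")
}

#' Hubs most affected by disease
#'
#' Ranks regions by centrality (descending) and by reduction t (descending),
#' combines the two rank positions by their mean, and returns the
#' \code{ceil(fraction * n)} regions with the best combined score, ties
#' broken by centrality rank then region name. The \code{intersection}
#' method instead intersects the two top-fraction lists.
#'
#' @param centrality a \linkS4class{CentralityProfile}
#' @param alteration a \linkS4class{CaseControlResult} or a reduction-
#'   oriented \linkS4class{RegionalMap} on the same scope
#' @param fraction top fraction of regions to report, in (0, 1]
#' @param method \code{meanrank} (default) or \code{intersection}
#' @return character vector of region names
#' @export
hubsMostAffected <- function(centrality, alteration, fraction = 0.1,
                             method = c("meanrank", "intersection")) {
  method <- match.arg(method)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  altMap <- if (is(alteration, "CaseControlResult"))
    alterationMap(alteration, "t") else alteration
  cvals <- mapValues(centrality)
  avals <- altMap@values
  if (!identical(names(cvals), names(avals)))
    stop("centrality and alteration must share parcellation scope")
  n <- length(cvals)
  k <- ceiling(fraction * n)
  rc <- rank(-cvals, ties.method = "average")
  ra <- rank(-avals, ties.method = "average")
  if (method == "intersection") {
    top <- intersect(names(sort(rc)[seq_len(k)]), names(sort(ra)[seq_len(k)]))
    return(top)
  }
  combined <- (rc + ra) / 2
  ord <- order(combined, rc, names(cvals))
  names(cvals)[ord][seq_len(k)]
}
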