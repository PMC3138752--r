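#' Two-dimensional semantic layout by multidimensional scaling
#'
#' Terms are placed in the plane so that their distances approximate the
#' semantic distances d = 1 - similarity (or sqrt(1 - s) with
#' \code{distanceTransform = "sqrt"}).  The initial configuration comes
#' from classical scaling — an eigenvalue decomposition of the
#' double-centred squared-distance matrix, keeping the top two spectral
#' axes — and is then refined by iterative stress majorization (SMACOF/
#' Guttman transform) until the relative decrease of the normalized stress
#' falls below \code{tolerance} or \code{maxIterations} is reached.  The
#' reported stress is sqrt(sum((d - delta)^2) / sum(delta^2)) with delta
#' the target distances; majorization decreases it monotonically.
#'
#' Degenerate inputs are handled without error: a single term is placed at
#' the origin; two terms are separated by exactly their distance on the
#' x axis; a rank-1 configuration gets a zero second axis.
#'
#' @param simMatrix a \linkS4class{SimilarityMatrix}.
#' @param tolerance relative stress-change convergence threshold
#'   (default 1e-6).
#' @param maxIterations maximum majorization iterations (default 300).
#' @param distanceTransform \code{"linear"} for d = 1 - s (default) or
#'   \code{"sqrt"} for d = sqrt(1 - s).
#' @return a list with \code{coordinates} (n x 2 matrix, accession
#'   rownames, columns \code{PC1}, \code{PC2}), \code{stress} (final
#'   normalized stress), \code{stressTrace} (stress after initialisation
#'   and after each iteration) and \code{iterations}.
#' @export
mdsLayout <- function(simMatrix, tolerance = 1e-6, maxIterations = 300,
                      distanceTransform = c("linear", "sqrt")) {
  distanceTransform <- match.arg(distanceTransform)
  terms <- simMatrix@terms
  n <- length(terms)
  S <- simMatrix@values
  if (n && any(!is.finite(S)))
    stop("non-finite entries in similarity matrix")

  emptyLayout <- function(coords, stress = 0, trace = stress, iter = 0L) {
    dimnames(coords) <- list(terms, c("PC1", "PC2"))
    list(coordinates = coords, stress = stress,
         stressTrace = trace, iterations = iter)
  }
  if (n == 0)
    return(emptyLayout(matrix(numeric(0), 0, 2)))
  if (n == 1)
    return(emptyLayout(matrix(0, 1, 2)))

  D <- if (distanceTransform == "linear") 1 - S else sqrt(pmax(1 - S, 0))
  D <- pmax(D, 0)
  diag(D) <- 0
  D <- (D + t(D)) / 2

  if (n == 2) {
    coords <- rbind(c(0, 0), c(D[1, 2], 0))
    return(emptyLayout(coords))
  }

  denom <- sum(D^2) / 2  # over unordered pairs
  stressOf <- function(X) {
    if (denom == 0) return(0)
    dx <- as.matrix(stats::dist(X))
    sqrt(sum((dx - D)^2) / 2 / denom)
  }

  if (all(D == 0))
    return(emptyLayout(matrix(0, n, 2)))

  X <- suppressWarnings(stats::cmdscale(D, k = 2))
  if (is.null(dim(X)) || ncol(X) < 2)
    X <- cbind(X, matrix(0, n, 2 - if (is.null(dim(X))) 1 else ncol(X)))
  X <- as.matrix(X)

  trace <- stressOf(X)
  iter <- 0L
  prev <- trace[1]
  while (iter < maxIterations) {
    dx <- as.matrix(stats::dist(X))
    B <- matrix(0, n, n)
    pos <- dx > 0
    B[pos] <- -D[pos] / dx[pos]
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    iter <- iter + 1L
    cur <- stressOf(X)
    trace <- c(trace, cur)
    if (prev <= 0 || (prev - cur) / max(prev, .Machine$double.eps) < tolerance) {
      prev <- cur
      break
    }
    prev <- cur
  }

  dimnames(X) <- list(terms, c("PC1", "PC2"))
  list(coordinates = X, stress = prev, stressTrace = trace,
       iterations = iter)
}
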