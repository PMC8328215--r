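#' Deterministic 2-D sensor layout
#'
#' Places `n_channels` sensors on the unit disc along a sunflower (golden
#' angle) spiral — an irregular but space-filling arrangement that stands in
#' for a projected electrode montage. Deterministic for a given `n`.
#'
#' @param n_channels number of channels (>= 2)
#' @return object of class `sensor_layout`: `channels` (names `E01`, ...)
#'   and `pos` (n x 2 matrix of x/y on the unit disc; negative y posterior)
#' @export
make_layout <- function(n_channels) {
  if (n_channels < 2) stop("a layout needs at least 2 channels")
  n <- as.integer(n_channels)
  k <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((k - 0.5) / n)
  th <- golden * (k - 1)
  pos <- cbind(x = r * cos(th), y = r * sin(th))
  channels <- sprintf("E%02d", k)
  rownames(pos) <- channels
  structure(list(channels = channels, pos = pos), class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("sensor_layout: %d channels on the unit disc\n",
              length(x$channels)))
  invisible(x)
}

#' Sensor neighborhood graph for cluster formation
#'
#' Builds the symmetric, irreflexive neighbor relation used for
#' spatio-temporal clustering, either by thresholding pairwise distances
#' (default: 1.5 x the median nearest-neighbor distance, which yields a
#' connected graph on reasonable layouts) or by Delaunay triangulation
#' edges.
#'
#' @param layout [make_layout()] result (or any list with `channels`, `pos`)
#' @param method `"distance"` or `"triangulation"`
#' @param threshold distance threshold for `method = "distance"`; `NULL`
#'   for the default
#' @return object of class `sensor_adjacency`: `channels`, logical `matrix`
#'   (symmetric, zero diagonal), and `neighbors` (list of integer indices)
#' @export
build_adjacency <- function(layout, method = c("distance", "triangulation"),
                            threshold = NULL) {
  method <- match.arg(method)
  pos <- layout$pos
  n <- nrow(pos)
  if (n < 2) stop("adjacency needs >= 2 channels")
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  if (any(d < 1e-12)) stop("duplicate sensor positions")
  if (method == "distance") {
    if (is.null(threshold)) threshold <- 1.5 * stats::median(apply(d, 1, min))
    adj <- d <= threshold + 1e-12
  } else {
    adj <- .delaunay_edges(pos)
  }
  diag(adj) <- FALSE
  adj <- adj | t(adj)
  dimnames(adj) <- list(layout$channels, layout$channels)
  structure(list(channels = layout$channels, matrix = adj,
                 neighbors = apply(adj, 1, which, simplify = FALSE)),
            class = "sensor_adjacency")
}

# O(n^3) Delaunay edge set by the empty-circumcircle test; adequate for
# montages up to ~128 sensors
.delaunay_edges <- function(pos) {
  n <- nrow(pos)
  adj <- matrix(FALSE, n, n)
  if (n == 2) { adj[1, 2] <- TRUE; return(adj) }
  combs <- utils::combn(n, 3)
  for (c3 in seq_len(ncol(combs))) {
    i <- combs[1, c3]; j <- combs[2, c3]; k <- combs[3, c3]
    cc <- .circumcircle(pos[i, ], pos[j, ], pos[k, ])
    if (is.null(cc)) next  # collinear
    others <- setdiff(seq_len(n), c(i, j, k))
    dd <- sqrt((pos[others, 1] - cc$cx)^2 + (pos[others, 2] - cc$cy)^2)
    if (all(dd > cc$r - 1e-12)) {
      adj[i, j] <- adj[j, k] <- adj[i, k] <- TRUE
    }
  }
  if (!any(adj)) adj[lower.tri(adj)] <- TRUE  # degenerate all-collinear
  adj
}

.circumcircle <- function(a, b, c) {
  det <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(det) < 1e-12) return(NULL)
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  cx <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / det
  cy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / det
  list(cx = cx, cy = cy, r = sqrt((a[1] - cx)^2 + (a[2] - cy)^2))
}

#' @export
print.sensor_adjacency <- function(x, ...) {
  cat(sprintf("sensor_adjacency: %d channels, %d edges\n",
              length(x$channels), sum(x$matrix) / 2))
  invisible(x)
}

#' Is the adjacency graph connected?
#'
#' @param adjacency [build_adjacency()] result
#' @return logical
#' @export
adjacency_connected <- function(adjacency) {
  n <- length(adjacency$channels)
  seen <- logical(n)
  stack <- 1L
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, adjacency$neighbors[[v]][!seen[adjacency$neighbors[[v]]]])
  }
  all(seen)
}
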