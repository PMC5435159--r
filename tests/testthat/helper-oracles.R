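# Independent oracles for the Minkowski-functional machinery. These are
# deliberately naive (flood fill, exhaustive cell enumeration) and share no
# code with the package implementation.

# connected-component labelling by flood fill; connectivity 4 or 8
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  nbrs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(nbrs))) {
          ii <- p[1] + nbrs[k, 1]
          jj <- p[2] + nbrs[k, 2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# Euler characteristic oracle: white components (8-connectivity) minus
# enclosed black components (4-connectivity, not touching the border)
oracle_genus <- function(white) {
  w <- matrix(as.logical(white), nrow(white), ncol(white))
  if (!any(w)) return(0)
  n_white <- max(label_components(w, 8))
  black_lab <- label_components(!w, 4)
  border_labs <- unique(c(black_lab[1, ], black_lab[nrow(w), ],
                          black_lab[, 1], black_lab[, ncol(w)]))
  border_labs <- setdiff(border_labs, 0L)
  n_holes <- length(setdiff(unique(black_lab[black_lab > 0]), border_labs))
  n_white - n_holes
}

# perimeter oracle: unit edges with a white pixel on exactly one side
oracle_perimeter <- function(white) {
  w <- matrix(as.logical(white), nrow(white), ncol(white))
  nr <- nrow(w)
  nc <- ncol(w)
  total <- 0L
  at <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && w[i, j]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!w[i, j]) next
    total <- total + (!at(i - 1, j)) + (!at(i + 1, j)) +
      (!at(i, j - 1)) + (!at(i, j + 1))
  }
  as.integer(total)
}

# brute-force distinct-cell enumeration of the union of closed unit squares
oracle_pev <- function(white) {
  w <- matrix(as.logical(white), nrow(white), ncol(white))
  edges <- character(0)
  verts <- character(0)
  p <- 0L
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w))) {
    if (!w[i, j]) next
    p <- p + 1L
    # pixel (i, j) occupies [i-1, i] x [j-1, j]; cells keyed by coordinates
    edges <- c(edges,
               sprintf("h_%d_%d", i - 1, j), sprintf("h_%d_%d", i, j),
               sprintf("v_%d_%d", i, j - 1), sprintf("v_%d_%d", i, j))
    verts <- c(verts,
               sprintf("%d_%d", i - 1, j - 1), sprintf("%d_%d", i - 1, j),
               sprintf("%d_%d", i, j - 1), sprintf("%d_%d", i, j))
  }
  c(p = p, e = length(unique(edges)), v = length(unique(verts)))
}

random_binary <- function(nr, nc, prob = 0.5) {
  matrix(stats::runif(nr * nc) < prob, nr, nc)
}
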