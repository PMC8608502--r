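# Connected-component labeling by run-based union-find.
#
# The lung pipeline needs two specific connectivities: 6-connectivity
# (faces) in 3D for lung-field selection and 4-connectivity in 2D for
# per-slice hole filling. Labels are computed from vertical pixel runs
# merged with a union-find, which keeps everything vectorized except the
# (short) union loop.

# label runs of TRUE along contiguous blocks of length I in vector v
.label_runs <- function(v, I) {
  n <- length(v)
  first <- (seq_len(n) - 1L) %% I == 0L
  prev <- c(FALSE, v[-n])
  start <- v & (first | !prev)
  rid <- cumsum(start)
  rid[!v] <- 0L
  as.integer(rid)
}

# union-find over n elements given an m x 2 pair matrix; returns root ids
.uf_roots <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (nrow(pairs)) {
    for (t in seq_len(nrow(pairs))) {
      ra <- find(pairs[t, 1L])
      rb <- find(pairs[t, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Label connected components of a binary array
#'
#' Components are labeled 1..n (0 = background) with a deterministic order
#' (ascending first linear index). Two connectivities are provided, matching
#' the pipeline's conventions: `"face3d"` is 6-connectivity in 3D (voxels
#' sharing a face); `"plane4"` is 4-connectivity within each slice, slices
#' independent (a 2D matrix is treated as a single slice).
#'
#' @param x logical/0-1 array, dim `(slice, row, col)`, or a 2D matrix.
#' @param connectivity `"face3d"` or `"plane4"`.
#' @return integer array of labels, same shape as `x`.
#' @export
label_components <- function(x, connectivity = c("face3d", "plane4")) {
  connectivity <- match.arg(connectivity)
  two_d <- is.matrix(x)
  if (two_d) x <- array(x, dim = c(1L, dim(x)))
  if (length(dim(x)) != 3L)
    stop("x must be a 3D array or a matrix", call. = FALSE)
  dk <- dim(x)
  # work in (row, col, slice) layout so runs go down image columns
  y <- aperm(x != 0, c(2, 3, 1))
  I <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  v <- as.logical(y)
  n <- length(v)
  rid <- .label_runs(v, I)
  nrun <- if (n) max(rid) else 0L

  pairs <- NULL
  if (nrun > 1L) {
    # in-plane neighbors one column to the right (exclude last column)
    p <- seq_len(n - I)
    jcol <- ((p - 1L) %/% I) %% J + 1L
    ok <- jcol < J & v[p] & v[p + I]
    pr <- cbind(rid[p][ok], rid[p + I][ok])
    pairs <- pr
    if (connectivity == "face3d" && K > 1L) {
      q <- seq_len(n - I * J)
      ok2 <- v[q] & v[q + I * J]
      pairs <- rbind(pairs, cbind(rid[q][ok2], rid[q + I * J][ok2]))
    }
    pairs <- unique(pairs)
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)

  roots <- if (nrun) .uf_roots(nrun, pairs) else integer(0)
  # dense labels in order of first appearance (runs are numbered by
  # ascending linear index, so match() preserves a deterministic order)
  lab_of_run <- if (nrun) match(roots, unique(roots)) else integer(0)
  out <- integer(n)
  fg <- rid > 0L
  out[fg] <- lab_of_run[rid[fg]]
  lab <- array(out, dim = c(I, J, K))
  lab <- aperm(lab, c(3, 1, 2))
  if (two_d) lab <- array(lab, dim = dk[2:3]) else dim(lab) <- dk
  lab
}

# sizes of components (voxel counts), index = label
.component_sizes <- function(lab) {
  m <- max(lab)
  if (m == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = m)
}

# labels present on border faces of a 3D label array.
# faces: "all", "side" (row/col faces only) or "top" (slice 1).
.border_labels <- function(lab, faces = "all") {
  d <- dim(lab)
  sel <- switch(faces,
    top = list(lab[1, , ]),
    side = list(lab[, 1, ], lab[, d[2], ], lab[, , 1], lab[, , d[3]]),
    list(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
         lab[, , 1], lab[, , d[3]]))
  u <- unique(unlist(lapply(sel, function(f) unique(as.integer(f)))))
  u[u > 0L]
}
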