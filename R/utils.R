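# Internal helpers shared across modules. Images are numeric matrices
# indexed [row, col] (row = y), masks are logical matrices.

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + dr):min(nr, nr + dr)
  sc <- max(1, 1 + dc):min(nc, nc + dc)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

# Number of 8-connected foreground neighbours for every pixel.
neighbor_count <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  n <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + shift_mat(m, dr, dc)
  }
  n
}

# 8-connected component membership of foreground pixels (igraph-backed).
# Returns a list with `idx` (linear indices) and `membership` (component id
# per entry of idx), plus the component count `no`.
label_components8 <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L)
    return(list(idx = integer(0), membership = integer(0), no = 0L))
  nr <- nrow(mask)
  id <- seq_along(idx)
  pos <- integer(length(mask)); pos[idx] <- id
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (o in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + o[1]; cc <- c + o[2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol(mask)
    j <- (cc[ok] - 1L) * nr + rr[ok]
    nb <- pos[j]
    from <- c(from, id[ok][nb > 0L]); to <- c(to, nb[nb > 0L])
  }
  g <- igraph::make_empty_graph(n = length(id), directed = FALSE)
  if (length(from) > 0)
    g <- igraph::add_edges(g, rbind(from, to))
  cm <- igraph::components(g)
  list(idx = idx, membership = cm$membership, no = cm$no)
}

count_components8 <- function(mask) label_components8(mask)$no

# Cluster count of 8-connected groups among a small set of pixels given as
# (row, col) pairs; used to merge adjacent junction pixels.
cluster_count8 <- function(rows, cols) {
  n <- length(rows)
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    adj <- which(abs(rows[-seq_len(i)] - rows[i]) <= 1 &
                 abs(cols[-seq_len(i)] - cols[i]) <= 1) + i
    for (j in adj) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

as_image_matrix <- function(x, name = "image") {
  if (inherits(x, "vessel_mask")) return(x$mask)
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 1L)
    return(x[, , 1L])
  abort(sprintf("`%s` must be a 2D matrix.", name))
}
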