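# shared low-level helpers: matrix shifts, 8-connected labeling, seeded RNG

#' Shift a matrix by (dr, dc), filling vacated cells
#'
#' @param m matrix.
#' @param dr,dc integer shift in rows / columns; positive moves content down /
#'   right.
#' @param fill value for vacated cells.
#' @return matrix of the same dimensions.
#' @keywords internal
#' @noRd
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighbour offsets in clockwise order starting north (used by thinning
# and topology code; order matters for the crossing-number test)
.nbr8 <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
               dc = c(0, 1, 1, 1, 0, -1, -1, -1))

#' Count 8-neighbours of every pixel of a binary mask
#' @param mask logical matrix.
#' @return integer matrix.
#' @keywords internal
#' @noRd
neighbor_count <- function(mask) {
  m <- mask * 1L
  acc <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(8)) {
    acc <- acc + shift_mat(m, .nbr8[i, 1], .nbr8[i, 2], 0L)
  }
  acc
}

#' Label connected components of a binary mask (8-connectivity)
#'
#' EBImage's `bwlabel` is 4-connected; skeletons and nuclei here use
#' 8-connectivity throughout, so components are found on the shift-pair
#' adjacency graph. Labels are contiguous `1..N`, ordered by each
#' component's smallest column-major pixel index (deterministic).
#'
#' @param mask logical or 0/1 numeric matrix.
#' @return integer matrix; 0 background, labels `1..N`.
#' @export
label_components <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  # edges to E, S, SE, SW neighbours cover all unique 8-adjacencies
  edges <- list()
  dirs <- cbind(c(0, 1, 1, 1), c(1, 0, 1, -1))
  pos <- matrix(FALSE, nr, nc); pos[idx] <- TRUE
  for (k in seq_len(4)) {
    nb <- shift_mat(pos, dirs[k, 1], dirs[k, 2], FALSE)
    both <- which(pos & nb)
    if (length(both)) {
      from <- both - dirs[k, 1] - dirs[k, 2] * nr
      edges[[length(edges) + 1L]] <- cbind(from, both)
    }
  }
  # map pixel indices to vertex ids
  vid <- integer(nr * nc); vid[idx] <- seq_along(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, rbind(vid[e[, 1]], vid[e[, 2]]))
  }
  memb <- igraph::components(g)$membership
  # relabel by first occurrence in column-major order
  first <- match(unique(memb[order(idx)]), memb[order(idx)])
  relab <- integer(max(memb))
  relab[unique(memb[order(idx)])] <- seq_along(unique(memb[order(idx)]))
  lab[idx] <- relab[memb]
  lab
}

#' Derive a per-task 32-bit seed from a master seed and an index
#' @keywords internal
#' @noRd
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + as.double(index) * 16807 + 1) %%
               2147483629)
}

#' Evaluate code with a temporary RNG seed, restoring global RNG state
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Integer pixel offsets within a Euclidean radius (a rasterized disc)
#' @keywords internal
#' @noRd
disc_offsets <- function(radius_px) {
  r <- ceiling(radius_px)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius_px^2, , drop = FALSE]
  as.matrix(g)
}

#' Odd-sized disc brush for EBImage morphology
#' @keywords internal
#' @noRd
disc_brush <- function(radius_px) {
  size <- 2L * max(1L, as.integer(ceiling(radius_px))) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

stop_input <- function(...) stop(..., call. = FALSE)
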