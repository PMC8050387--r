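# skeletonization, spur pruning, topology and physical length measurement

# crossing number A(p): 0->1 transitions around the 8-neighbour cycle;
# returned per pixel as matrices of the cyclic neighbour pattern
zs_neighbors <- function(m) {
  lapply(seq_len(8), function(i) shift_mat(m, -.nbr8[i, 1], -.nbr8[i, 2], 0L))
}

#' Thin a binary mask to a unit-width skeleton
#'
#' Zhang-Suen morphological thinning iterated to convergence, followed by a
#' simple-point cleanup pass that removes any remaining pixels forming a
#' fully set 2x2 block, so the result satisfies the unit-width property: no
#' 2x2 block of the skeleton is fully set, and connectivity is preserved
#' under 8-adjacency.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix, the skeleton.
#' @export
skeletonize <- function(mask) {
  m <- (mask > 0) * 1L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- zs_neighbors(m)
      bsum <- Reduce(`+`, nb)
      cyc <- c(nb, nb[1])
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in seq_len(8)) a <- a + (cyc[[i]] == 0L & cyc[[i + 1]] == 1L)
      # nb order: P2=N, P3=NE, P4=E, P5=SE, P6=S, P7=SW, P8=W, P9=NW
      if (sub == 1) {
        c1 <- nb[[1]] * nb[[3]] * nb[[5]] == 0L   # P2*P4*P6
        c2 <- nb[[3]] * nb[[5]] * nb[[7]] == 0L   # P4*P6*P8
      } else {
        c1 <- nb[[1]] * nb[[3]] * nb[[7]] == 0L   # P2*P4*P8
        c2 <- nb[[1]] * nb[[5]] * nb[[7]] == 0L   # P2*P6*P8
      }
      del <- m == 1L & bsum >= 2L & bsum <= 6L & a == 1L & c1 & c2
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m <- remove_2x2_blocks(m)
  m <- remove_staircase_pixels(m)
  m == 1L
}

# adjacency among the 8 neighbour offsets (chebyshev distance <= 1),
# computed on first use (utils.R defines .nbr8 later in collation order)
ring_adj <- function() {
  if (is.null(.skel_cache$ring_adj)) {
    a <- matrix(FALSE, 8, 8)
    for (i in 1:8) for (j in 1:8)
      a[i, j] <- i != j && max(abs(.nbr8[i, ] - .nbr8[j, ])) <= 1L
    .skel_cache$ring_adj <- a
  }
  .skel_cache$ring_adj
}
.skel_cache <- new.env(parent = emptyenv())

# number of 8-connected components among the foreground neighbours of a
# pixel (true ring connectivity; the Zhang-Suen crossing number
# overestimates it for staircase doubles)
ring_components <- function(pat) {
  on <- which(pat == 1L)
  if (!length(on)) return(0L)
  adj <- ring_adj()
  seen <- logical(length(on))
  comps <- 0L
  for (s in seq_along(on)) {
    if (seen[s]) next
    comps <- comps + 1L
    stack <- s
    while (length(stack)) {
      i <- stack[[1]]; stack <- stack[-1]
      if (seen[i]) next
      seen[i] <- TRUE
      stack <- c(stack, which(adj[on[i], on] & !seen))
    }
  }
  comps
}

# remove redundant pixels left by parallel thinning (staircase doubles,
# corner pixels): a non-endpoint pixel whose foreground neighbours form a
# single mutually 8-connected set carries no connectivity; deleting it
# leaves its neighbours connected and makes the skeleton a minimal
# 8-path, which the unique-adjacent-pair length convention assumes.
# Sequential in raster order, iterated to convergence.
remove_staircase_pixels <- function(m) {
  nr <- nrow(m)
  repeat {
    ncount <- neighbor_count(m == 1L)
    cand <- which(m == 1L & ncount >= 2L)
    removed <- FALSE
    for (i in cand) {
      r <- (i - 1L) %% nr + 1L
      c <- (i - 1L) %/% nr + 1L
      if (m[r, c] != 1L) next
      pat <- nbr_pattern(m, r, c)
      if (sum(pat) >= 2L && ring_components(pat) == 1L) {
        m[r, c] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) return(m)
  }
}

# delete deletable pixels (crossing number 1) until no 2x2 block is full
remove_2x2_blocks <- function(m) {
  repeat {
    full <- m == 1L &
      shift_mat(m, 0, -1, 0L) == 1L &
      shift_mat(m, -1, 0, 0L) == 1L &
      shift_mat(m, -1, -1, 0L) == 1L
    idx <- which(full)
    if (!length(idx)) return(m)
    removed <- FALSE
    # candidates: the four pixels of each offending block, raster order
    nr <- nrow(m)
    cand <- unique(c(idx, idx + 1L, idx + nr, idx + nr + 1L))
    cand <- sort(cand)
    for (i in cand) {
      r <- (i - 1L) %% nr + 1L
      c <- (i - 1L) %/% nr + 1L
      if (m[r, c] != 1L) next
      pat <- nbr_pattern(m, r, c)
      if (crossing_number(pat) == 1L && sum(pat) >= 2L) {
        m[r, c] <- 0L
        removed <- TRUE
        break
      }
    }
    if (!removed) {
      # degenerate tie (e.g. isolated 2x2 square): drop the first pixel
      r <- (cand[1] - 1L) %% nr + 1L
      c <- (cand[1] - 1L) %/% nr + 1L
      m[r, c] <- 0L
    }
  }
}

nbr_pattern <- function(m, r, c) {
  vapply(seq_len(8), function(i) {
    rr <- r + .nbr8[i, 1]; cc <- c + .nbr8[i, 2]
    if (rr < 1 || cc < 1 || rr > nrow(m) || cc > ncol(m)) 0L
    else as.integer(m[rr, cc] > 0)
  }, integer(1))
}

crossing_number <- function(pat) {
  cyc <- c(pat, pat[1])
  sum(cyc[-length(cyc)] == 0L & cyc[-1] == 1L)
}

#' Skeleton topology: branch points and endpoints
#'
#' A branch point has at least 3 skeleton neighbours (8-connectivity); an
#' endpoint exactly 1.
#'
#' @param mask logical skeleton matrix.
#' @return list with integer matrices `branch_points` and `endpoints`
#'   (columns `row`, `col`) and the neighbour-count matrix `n_neighbors`.
#' @export
skeleton_topology <- function(mask) {
  mask <- mask > 0
  nc <- neighbor_count(mask)
  bp <- which(mask & nc >= 3L, arr.ind = TRUE)
  ep <- which(mask & nc == 1L, arr.ind = TRUE)
  colnames(bp) <- colnames(ep) <- c("row", "col")
  list(branch_points = bp, endpoints = ep, n_neighbors = nc)
}

step_weight <- function(dr, dc) ifelse(dr != 0 & dc != 0, sqrt(2), 1)

walk_from_endpoint <- function(mask, nc, start) {
  # follow the skeleton from an endpoint until a branch point (>=3
  # neighbours), another endpoint, or exhaustion; returns visited pixels
  # (excluding a terminating branch point) and the path's weighted length
  path <- list(start)
  len <- 0
  prev <- c(NA_integer_, NA_integer_)
  cur <- start
  repeat {
    nbrs <- sweep(.nbr8, 2, cur, `+`)
    ok <- nbrs[, 1] >= 1 & nbrs[, 2] >= 1 &
      nbrs[, 1] <= nrow(mask) & nbrs[, 2] <= ncol(mask)
    nbrs <- nbrs[ok, , drop = FALSE]
    on <- nbrs[mask[nbrs] , , drop = FALSE]
    if (!is.na(prev[1]))
      on <- on[!(on[, 1] == prev[1] & on[, 2] == prev[2]), , drop = FALSE]
    if (nrow(on) == 0L)
      return(list(pixels = path, length_steps = len, hit_branch = FALSE))
    if (nrow(on) > 1L)  # current pixel is adjacent to a junction cluster
      return(list(pixels = path, length_steps = len, hit_branch = TRUE))
    nxt <- on[1, ]
    if (nc[nxt[1], nxt[2]] >= 3L) {
      len <- len + step_weight(nxt[1] - cur[1], nxt[2] - cur[2])
      return(list(pixels = path, length_steps = len, hit_branch = TRUE))
    }
    len <- len + step_weight(nxt[1] - cur[1], nxt[2] - cur[2])
    path[[length(path) + 1L]] <- nxt
    prev <- cur
    cur <- nxt
  }
}

#' Iteratively prune short terminal spurs from a skeleton
#'
#' Walks inward from every endpoint; a terminal branch that reaches a branch
#' point within `max_length_px` weighted steps (weights 1 orthogonal,
#' sqrt(2) diagonal) is deleted. Whole components that are simple paths are
#' never pruned (they are neurites, not spurs). Repeats until stable.
#'
#' @param mask logical skeleton matrix.
#' @param max_length_px prune spurs strictly shorter than this (px units).
#' @return logical matrix.
#' @export
prune_spurs <- function(mask, max_length_px) {
  mask <- mask > 0
  if (max_length_px <= 0) return(mask)
  repeat {
    topo <- skeleton_topology(mask)
    ep <- topo$endpoints
    if (nrow(ep) == 0L) return(mask)
    changed <- FALSE
    for (k in seq_len(nrow(ep))) {
      p <- ep[k, ]
      if (!mask[p[1], p[2]]) next
      if (topo$n_neighbors[p[1], p[2]] != 1L) next
      w <- walk_from_endpoint(mask, topo$n_neighbors, p)
      if (w$hit_branch && w$length_steps < max_length_px) {
        for (px in w$pixels) mask[px[1], px[2]] <- FALSE
        changed <- TRUE
      }
    }
    # a deleted spur can leave its attachment pixel as a redundant corner
    # hugging the main branch; reduce before the next pass
    if (changed) mask <- remove_staircase_pixels(mask * 1L) == 1L
    if (!changed) return(mask)
  }
}

check_unit_width <- function(mask) {
  full <- mask &
    shift_mat(mask, 0, -1, FALSE) &
    shift_mat(mask, -1, 0, FALSE) &
    shift_mat(mask, -1, -1, FALSE)
  if (any(full))
    stop_input("contract violation: skeleton mask is not unit-width ",
               "(fully set 2x2 block present)")
}

#' Measure the physical length of a unit-width skeleton
#'
#' Length is the sum over unique 8-adjacent skeleton pixel pairs of the step
#' weight (1 for orthogonal, sqrt(2) for diagonal neighbours) times the
#' pixel size; each adjacency is counted once. No corner-cut or perimeter
#' corrections are applied.
#'
#' @param skeleton_mask logical unit-width matrix (see [skeletonize()]).
#' @param pixel_size_um µm per pixel.
#' @param labels optional integer component-label matrix (same dims); when
#'   given, per-component lengths are returned for labels `1..max`.
#' @return list with `total_um` and, when `labels` is supplied,
#'   `per_component_um` (numeric vector indexed by label).
#' @export
skeleton_length <- function(skeleton_mask, pixel_size_um, labels = NULL) {
  mask <- skeleton_mask > 0
  check_unit_width(mask)
  dirs <- cbind(dr = c(0, 1, 1, 1), dc = c(1, 0, 1, -1))
  wts <- c(1, 1, sqrt(2), sqrt(2))
  total <- 0
  per <- if (!is.null(labels)) numeric(max(0L, max(labels))) else NULL
  for (k in seq_len(4)) {
    nb <- shift_mat(mask, dirs[k, 1], dirs[k, 2], FALSE)
    both <- mask & nb
    n <- sum(both)
    total <- total + wts[k] * n
    if (!is.null(per) && n > 0) {
      l <- labels[both]
      add <- tabulate(l, nbins = length(per)) * wts[k]
      per <- per + add
    }
  }
  out <- list(total_um = total * pixel_size_um)
  if (!is.null(per)) out$per_component_um <- per * pixel_size_um
  out
}
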