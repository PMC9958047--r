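#' Rigid-cluster decomposition by the (6,6) body-bar pebble game
#'
#' Each body holds 6 pebbles (its 6 degrees of freedom). A bar is accepted
#' as independent iff 7 pebbles can be gathered on its two endpoints; the
#' accepting endpoint pays one pebble and the bar is inserted as a directed
#' edge. After all bars are processed, two adjacent bodies belong to the
#' same rigid cluster iff 7 pebbles can no longer be gathered on the pair
#' (all 6 relative degrees of freedom are exhausted); clusters are the
#' transitive closure of this relation. Bars are processed in a canonical
#' order, so the decomposition is deterministic and invariant under
#' permutation of the input rows.
#'
#' @param network a [constraint_network()].
#' @return An object of class `rigid_decomposition`: list with `labels`
#'   (cluster id per body, clusters numbered by decreasing size), `sizes`
#'   (cluster sizes, decreasing), `largest_fraction`, `n_bodies`,
#'   `n_independent` and `n_redundant` bar counts, and `floppy_modes`
#'   (internal degrees of freedom beyond the 6 trivial ones).
#' @export
pebble_game <- function(network) {
  tl_assert(inherits(network, "constraint_network"), "not a constraint_network")
  n <- network$n_bodies
  bars <- network$bars
  st <- new.env(parent = emptyenv())
  st$peb <- rep.int(6L, n)
  st$adj <- vector("list", n)  # out-neighbour integer vectors (multi-edges)

  n_indep <- 0L; n_redund <- 0L
  if (nrow(bars)) {
    for (k in seq_len(nrow(bars))) {
      u <- bars$i[k]; v <- bars$j[k]
      for (cpy in seq_len(bars$mult[k])) {
        if (.pg_collect7(st, u, v)) {
          if (st$peb[u] > 0L) {
            st$peb[u] <- st$peb[u] - 1L
            st$adj[[u]] <- c(st$adj[[u]], v)
          } else {
            st$peb[v] <- st$peb[v] - 1L
            st$adj[[v]] <- c(st$adj[[v]], u)
          }
          n_indep <- n_indep + 1L
        } else n_redund <- n_redund + 1L
      }
    }
  }

  # rigid clusters: union adjacent pairs on which 7 pebbles cannot be gathered
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(bars)) {
    pairs <- unique(bars[, c("i", "j")])
    for (k in seq_len(nrow(pairs))) {
      u <- pairs$i[k]; v <- pairs$j[k]
      if (find(u) == find(v)) next
      if (!.pg_collect7(st, u, v)) parent[find(u)] <- find(v)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab <- match(roots, unique(roots))
  sizes <- tabulate(lab)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(length(sizes)); relabel[ord] <- seq_along(ord)
  lab <- relabel[lab]
  sizes <- sort(sizes, decreasing = TRUE)
  structure(list(labels = lab, sizes = sizes,
                 largest_fraction = sizes[1] / n,
                 n_bodies = n, n_independent = n_indep,
                 n_redundant = n_redund,
                 floppy_modes = 6L * n - n_indep - 6L),
            class = "rigid_decomposition")
}

#' @export
print.rigid_decomposition <- function(x, ...) {
  cat(sprintf(
    "Rigid decomposition: %d bodies, %d clusters (largest %d, %.1f%%)\n",
    x$n_bodies, length(x$sizes), x$sizes[1], 100 * x$largest_fraction))
  invisible(x)
}

# Try to gather 7 pebbles on {u, v}; pebble moves persist (they do not
# change the matroid state). Returns TRUE iff 7 gathered.
.pg_collect7 <- function(st, u, v) {
  repeat {
    if (st$peb[u] + st$peb[v] >= 7L) return(TRUE)
    moved <- FALSE
    if (st$peb[u] < 6L && .pg_search(st, u, v)) moved <- TRUE
    else if (st$peb[v] < 6L && .pg_search(st, v, u)) moved <- TRUE
    if (!moved) return(FALSE)
  }
}

# Depth-first pebble search from `s`, never taking a pebble off `forbid`
# (or `s` itself). On success reverses the path and moves one pebble to `s`.
.pg_search <- function(st, s, forbid) {
  n <- length(st$peb)
  visited <- logical(n)
  visited[s] <- TRUE; visited[forbid] <- TRUE
  parent <- integer(n)
  stack <- st$adj[[s]]
  from <- rep.int(s, length(stack))
  found <- 0L
  while (length(stack)) {
    w <- stack[[length(stack)]]; f <- from[[length(from)]]
    stack <- stack[-length(stack)]; from <- from[-length(from)]
    if (visited[w]) next
    visited[w] <- TRUE
    parent[w] <- f
    if (st$peb[w] > 0L) { found <- w; break }
    nxt <- st$adj[[w]]
    if (length(nxt)) {
      stack <- c(stack, nxt)
      from <- c(from, rep.int(w, length(nxt)))
    }
  }
  if (!found) return(FALSE)
  # reverse edges along s -> ... -> found, move pebble to s
  path <- found
  while (path[1] != s) path <- c(parent[path[1]], path)
  for (k in seq_len(length(path) - 1L)) {
    a <- path[k]; b <- path[k + 1L]
    pos <- match(b, st$adj[[a]])
    st$adj[[a]] <- st$adj[[a]][-pos]
    st$adj[[b]] <- c(st$adj[[b]], a)
  }
  st$peb[found] <- st$peb[found] - 1L
  st$peb[s] <- st$peb[s] + 1L
  TRUE
}

#' Cluster configuration entropy (type 2)
#'
#' Size-squared weighted configuration entropy of a rigid-cluster
#' decomposition: `H = -sum_i w_i log(w_i)` with `w_i = s_i^2 / sum_j s_j^2`
#' over clusters `i` of size `s_i`. A single spanning cluster gives 0; `k`
#' equal clusters give `log(k)`. The quadratic weighting makes the entropy
#' insensitive to a dust of small clusters while the largest cluster still
#' dominates, so `H` jumps when the largest rigid cluster stops dominating
#' the network.
#'
#' @param decomposition a `rigid_decomposition` (or an integer vector of
#'   cluster sizes).
#' @return Non-negative scalar entropy (dimensionless, natural log).
#' @export
cluster_entropy <- function(decomposition) {
  sizes <- if (inherits(decomposition, "rigid_decomposition"))
    decomposition$sizes else as.numeric(decomposition)
  tl_assert(length(sizes) >= 1 && all(sizes >= 1), "invalid decomposition")
  w <- sizes^2 / sum(sizes^2)
  -sum(w * log(w))
}
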