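# Independent oracles used across the suite. These deliberately do not share
# code with the package implementation.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Generic rigidity-matrix rank oracle for body-bar frameworks: each body
# gets 6 velocity coordinates (v, omega about the origin); each bar with
# random generic attachment points contributes one row; bodies are mutually
# rigid iff their twists agree on the whole null space.
oracle_decomposition <- function(net, seed = 1) {
  set.seed(seed)
  n <- net$n_bodies
  rows <- list()
  for (k in seq_len(nrow(net$bars))) {
    u <- net$bars$i[k]; v <- net$bars$j[k]
    for (m in seq_len(net$bars$mult[k])) {
      au <- rnorm(3); av <- rnorm(3); d <- av - au
      r <- numeric(6 * n)
      r[(u - 1) * 6 + 1:3] <- d
      r[(u - 1) * 6 + 4:6] <- cross3(au, d)
      r[(v - 1) * 6 + 1:3] <- r[(v - 1) * 6 + 1:3] - d
      r[(v - 1) * 6 + 4:6] <- r[(v - 1) * 6 + 4:6] - cross3(av, d)
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows)) return(seq_len(n))
  R <- do.call(rbind, rows)
  sv <- svd(R, nv = ncol(R))
  tol <- max(dim(R)) * max(sv$d, 0) * 1e-9
  rank <- sum(sv$d > tol)
  null_basis <- sv$v[, setdiff(seq_len(ncol(R)), seq_len(rank)), drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }
    x
  }
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    du <- null_basis[(u - 1) * 6 + 1:6, , drop = FALSE]
    dv <- null_basis[(v - 1) * 6 + 1:6, , drop = FALSE]
    if (max(abs(du - dv)) < 1e-6) parent[find(u)] <- find(v)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# canonical signature of a partition, independent of label values
partition_sig <- function(lab) {
  blocks <- lapply(split(seq_along(lab), lab), sort)
  unname(blocks[order(vapply(blocks, min, numeric(1)))])
}

# independently coded Mayo-form energy (duplicate-implementation oracle)
mayo_energy_oracle <- function(r_da, angle_deg) {
  f <- if (angle_deg >= 90) cos(angle_deg * pi / 180)^2 else 0
  8 * (5 * (2.8 / r_da)^12 - 6 * (2.8 / r_da)^10) * f
}

# random network drawn with plain base R (no package generator involved)
random_test_network <- function(seed, n_max = 12) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  ne <- sample(2:26, 1)
  i <- sample.int(n, ne, replace = TRUE)
  j <- sample.int(n, ne, replace = TRUE)
  ok <- i != j
  i <- i[ok]; j <- j[ok]
  if (!length(i)) { i <- 1L; j <- 2L }
  type <- sample(c("cov_rot", "cov_lock", "tether", "hbond"),
                 length(i), replace = TRUE)
  e <- ifelse(type == "hbond", -runif(length(i), 0.1, 6), NA_real_)
  constraint_network(n, data.frame(i = i, j = j, type = type, e_hb = e))
}

hairpin_path <- function() {
  system.file("extdata", "synthetic_hairpin.pdb", package = "thermolegacy")
}
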