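#' Constraint networks for rigidity analysis
#'
#' A constraint network represents a protein (or a toy system) as rigid
#' bodies (atoms) connected by bars. Bar multiplicities follow the FIRST
#' body-bar conventions: rotatable covalent bonds contribute 5 bars, locked
#' covalent bonds (peptide and double bonds) 6 bars, hydrogen bonds and salt
#' bridges 5 bars, and hydrophobic tethers 2 bars. Hydrogen-bond class bars
#' carry an empirical energy `e_hb` (kcal/mol) used by the thermal-dilution
#' schedule; covalent bars and tethers are never diluted.
#'
#' @param n_bodies number of bodies (vertices).
#' @param bars data.frame with columns `i`, `j` (1-based body indices),
#'   `type` (one of `"cov_rot"`, `"cov_lock"`, `"hbond"`, `"saltbridge"`,
#'   `"tether"`) and optionally `e_hb` (kcal/mol, required and finite for
#'   `hbond`/`saltbridge` bars, `NA` otherwise).
#' @return An object of class `constraint_network`.
#' @export
constraint_network <- function(n_bodies, bars) {
  tl_assert(is.numeric(n_bodies) && length(n_bodies) == 1 && n_bodies >= 1,
            "n_bodies must be a single count >= 1")
  n_bodies <- as.integer(n_bodies)
  if (is.null(bars) || nrow(bars) == 0) {
    bars <- data.frame(i = integer(), j = integer(), type = character(),
                       mult = integer(), e_hb = numeric())
  } else {
    tl_assert(all(c("i", "j", "type") %in% names(bars)),
              "bars must have columns i, j, type")
    bars$i <- as.integer(bars$i); bars$j <- as.integer(bars$j)
    tl_assert(all(bars$i >= 1 & bars$i <= n_bodies &
                  bars$j >= 1 & bars$j <= n_bodies),
              "bar endpoints out of range")
    tl_assert(all(bars$i != bars$j), "self-loop bars are not allowed")
    tl_assert(all(bars$type %in% names(.bar_mult)),
              "unknown bar type; allowed: %s",
              paste(names(.bar_mult), collapse = ", "))
    if (is.null(bars$e_hb)) bars$e_hb <- NA_real_
    noncov <- bars$type %in% c("hbond", "saltbridge")
    tl_assert(all(is.finite(bars$e_hb[noncov])),
              "hbond/saltbridge bars must carry a finite e_hb")
    tl_assert(all(bars$e_hb[noncov] <= 0),
              "hbond/saltbridge bars with e_hb > 0 must be excluded upstream")
    bars$mult <- .bar_mult[bars$type]
    # canonical form: i < j, ordered rows -> deterministic pebble game
    swap <- bars$i > bars$j
    tmp <- bars$i[swap]; bars$i[swap] <- bars$j[swap]; bars$j[swap] <- tmp
    bars <- bars[order(bars$i, bars$j, bars$type, bars$e_hb), , drop = FALSE]
    rownames(bars) <- NULL
  }
  structure(list(n_bodies = n_bodies, bars = bars),
            class = "constraint_network")
}

.bar_mult <- c(cov_rot = 5L, cov_lock = 6L, hbond = 5L,
               saltbridge = 5L, tether = 2L)

#' @export
print.constraint_network <- function(x, ...) {
  cat(sprintf("Constraint network: %d bodies, %d bar groups\n",
              x$n_bodies, nrow(x$bars)))
  if (nrow(x$bars)) print(table(x$bars$type))
  invisible(x)
}

# covalent radii (Angstrom) used for bond inference
.cov_radius <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07)
.vdw_radius <- c(C = 1.70, S = 1.80)

.elem_radius <- function(element, table, default) {
  r <- unname(table[element])
  r[is.na(r)] <- default
  r
}

.dist <- function(a, b) sqrt(sum((a - b)^2))

# Infer covalent bonds from interatomic distances (d <= r1 + r2 + 0.4 A).
infer_bonds <- function(structure) {
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2) return(data.frame(i = integer(), j = integer()))
  rad <- .elem_radius(structure$element, .cov_radius, 0.77)
  out_i <- integer(); out_j <- integer()
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    d2 <- (xyz[js, 1] - xyz[i, 1])^2 + (xyz[js, 2] - xyz[i, 2])^2 +
      (xyz[js, 3] - xyz[i, 3])^2
    cut <- (rad[i] + rad[js] + 0.4)^2
    hit <- js[d2 <= cut & d2 > 0.16]
    # no H-H bonds
    if (structure$element[i] == "H")
      hit <- hit[structure$element[hit] != "H"]
    out_i <- c(out_i, rep.int(i, length(hit)))
    out_j <- c(out_j, hit)
  }
  data.frame(i = out_i, j = out_j)
}

#' Detect hydrogen bonds and salt bridges from geometry
#'
#' Scans donor-H...acceptor triples (N/O/S donors and acceptors) with the
#' usual geometric screens and classifies pairs between oppositely charged
#' side-chain groups as salt bridges. The input structure must be protonated;
#' without explicit hydrogens no donors can be identified.
#'
#' @param structure a protein structure as returned by [read_pdb()].
#' @param bonds optional covalent bond list (columns `i`, `j`); inferred
#'   from distances when omitted.
#' @param h_a_max,d_a_max maximum H...acceptor and donor...acceptor
#'   distances (Angstrom).
#' @param dha_min minimum donor-H-acceptor angle (degrees).
#' @param min_bond_sep minimum covalent separation (number of bonds)
#'   between donor and acceptor; the default 4 excludes 1-2, 1-3 and 1-4
#'   pairs (e.g. the same-residue amide-carbonyl contact).
#' @return data.frame with one row per candidate bond: atom indices
#'   (`donor`, `hydrogen`, `acceptor`), geometry (`r_ha`, `r_da`,
#'   `angle_dha`) and `type` (`"hbond"` or `"saltbridge"`).
#' @export
detect_hbonds <- function(structure, bonds = NULL,
                          h_a_max = 2.6, d_a_max = 3.6, dha_min = 90,
                          min_bond_sep = 4) {
  tl_assert(any(structure$element == "H"),
            "no hydrogens found: protonate the structure first (e.g. Reduce)")
  if (is.null(bonds)) bonds <- infer_bonds(structure)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  polar <- structure$element %in% c("N", "O", "S")
  # hydrogen -> bonded heavy atom (donor)
  hyd <- which(structure$element == "H")
  don_of <- rep(NA_integer_, nrow(structure))
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    if (structure$element[i] == "H" && polar[j]) don_of[i] <- j
    if (structure$element[j] == "H" && polar[i]) don_of[j] <- i
  }
  pos_names <- c("NZ", "NH1", "NH2", "NE", "ND1", "NE2")
  neg_names <- c("OD1", "OD2", "OE1", "OE2", "OXT")
  pos_res <- c("LYS", "ARG", "HIS")
  neg_res <- c("ASP", "GLU")
  is_pos <- structure$name %in% pos_names & structure$resname %in% pos_res
  is_neg <- structure$name %in% neg_names &
    (structure$resname %in% neg_res | structure$name == "OXT")
  acc <- which(polar)
  # covalent adjacency for the separation rule
  nb <- vector("list", nrow(structure))
  for (k in seq_len(nrow(bonds))) {
    nb[[bonds$i[k]]] <- c(nb[[bonds$i[k]]], bonds$j[k])
    nb[[bonds$j[k]]] <- c(nb[[bonds$j[k]]], bonds$i[k])
  }
  near_set <- function(v, depth) {
    seen <- v
    frontier <- v
    for (step in seq_len(depth)) {
      frontier <- setdiff(unique(unlist(nb[frontier])), seen)
      if (!length(frontier)) break
      seen <- c(seen, frontier)
    }
    seen
  }
  res <- list()
  for (h in hyd) {
    d <- don_of[h]
    if (is.na(d)) next
    too_close <- near_set(d, min_bond_sep - 1L)
    for (a in acc) {
      if (a == d || a == h) next
      if (a %in% too_close) next
      r_ha <- .dist(xyz[h, ], xyz[a, ])
      if (r_ha > h_a_max) next
      r_da <- .dist(xyz[d, ], xyz[a, ])
      if (r_da > d_a_max) next
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang < dha_min) next
      type <- if (is_pos[d] && is_neg[a]) "saltbridge" else "hbond"
      res[[length(res) + 1L]] <- data.frame(
        donor = d, hydrogen = h, acceptor = a,
        r_ha = r_ha, r_da = r_da, angle_dha = ang, type = type)
    }
  }
  if (!length(res))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), r_ha = numeric(),
                      r_da = numeric(), angle_dha = numeric(),
                      type = character()))
  do.call(rbind, res)
}

#' Mayo-type empirical hydrogen-bond energy
#'
#' `E = V0 * (5 (R0/R)^12 - 6 (R0/R)^10) * F(theta)` with well depth
#' `V0 = 8` kcal/mol at equilibrium donor-acceptor distance `R0 = 2.8` A.
#' The angular factor is `F = cos^2(theta_DHA)` for angles of at least 90
#' degrees and 0 otherwise, so a perpendicular arrangement contributes
#' nothing and an ideal linear bond at `R = R0` yields `-V0`.
#'
#' @param r_da donor-acceptor distance (Angstrom, > 0).
#' @param angle_dha donor-hydrogen-acceptor angle (degrees).
#' @param v0 well depth (kcal/mol).
#' @param r0 equilibrium distance (Angstrom).
#' @return Energy in kcal/mol (<= 0 for favourable geometries).
#' @export
hbond_energy <- function(r_da, angle_dha, v0 = 8, r0 = 2.8) {
  tl_assert(all(r_da > 0), "degenerate geometry: zero donor-acceptor distance")
  f <- ifelse(angle_dha >= 90, cos(angle_dha * pi / 180)^2, 0)
  v0 * (5 * (r0 / r_da)^12 - 6 * (r0 / r_da)^10) * f
}

#' Build a constraint network from a protonated structure
#'
#' Atoms become bodies. Covalent bonds become 5-bar (rotatable) or 6-bar
#' (locked: peptide C-N and carbonyl C=O) edges, hydrogen bonds and salt
#' bridges 5-bar edges annotated with their Mayo energy, and hydrophobic
#' tethers 2-bar edges between nonpolar carbon/sulfur pairs. Unfavourable
#' (E > 0) hydrogen bonds are excluded. If the covalent graph is
#' disconnected, only its largest component is analysed (with a warning).
#'
#' @param structure a structure as returned by [read_pdb()].
#' @param options list of switches: `tethers` (default `TRUE`),
#'   `tether_cut` (distance cap, default 3.5 A), `salt_mayo` (default
#'   `TRUE`; when `FALSE` salt bridges get the fixed energy `salt_energy`),
#'   `salt_energy` (default -10 kcal/mol), plus the geometric screens of
#'   [detect_hbonds()].
#' @return A [constraint_network()] with an `atoms` attribute mapping bodies
#'   back to the retained atoms.
#' @export
build_network <- function(structure, options = list()) {
  opt <- modifyList(list(tethers = TRUE, tether_cut = 3.5,
                         salt_mayo = TRUE, salt_energy = -10,
                         h_a_max = 2.6, d_a_max = 3.6, dha_min = 90),
                    options)
  tl_assert(nrow(structure) >= 1, "empty structure")
  bonds <- infer_bonds(structure)
  # covalent connectivity: keep largest component
  comp <- components_undirected(nrow(structure), bonds$i, bonds$j)
  keep <- comp == which.max(tabulate(comp))
  if (!all(keep)) {
    warning(sprintf(
      "covalent graph disconnected: analysing largest component (%d of %d atoms)",
      sum(keep), length(keep)))
    idx <- cumsum(keep)
    structure <- structure[keep, , drop = FALSE]
    bonds <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
    bonds$i <- idx[bonds$i]; bonds$j <- idx[bonds$j]
  }
  n <- nrow(structure)
  bar_i <- bonds$i; bar_j <- bonds$j
  locked <- logical(nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$i[k]; b <- bonds$j[k]
    na <- structure$name[a]; nb <- structure$name[b]
    ra <- structure$resid[a]; rb <- structure$resid[b]
    # peptide bond C(i)-N(i+1); carbonyl C=O within a residue
    pep <- (na == "C" && nb == "N" && rb == ra + 1) ||
      (nb == "C" && na == "N" && ra == rb + 1)
    dbl <- (ra == rb) && ((na == "C" && nb == "O") ||
                          (nb == "C" && na == "O"))
    locked[k] <- pep || dbl
  }
  bars <- data.frame(i = bar_i, j = bar_j,
                     type = ifelse(locked, "cov_lock", "cov_rot"),
                     e_hb = NA_real_)
  # hydrogen-free (toy/coarse) structures simply get no hbond bars
  hb <- if (any(structure$element == "H"))
    detect_hbonds(structure, bonds, opt$h_a_max, opt$d_a_max, opt$dha_min)
  else data.frame(donor = integer(), hydrogen = integer(),
                  acceptor = integer(), r_ha = numeric(), r_da = numeric(),
                  angle_dha = numeric(), type = character())
  if (nrow(hb)) {
    e <- hbond_energy(hb$r_da, hb$angle_dha)
    if (!opt$salt_mayo) e[hb$type == "saltbridge"] <- opt$salt_energy
    ok <- e <= 0
    hb <- hb[ok, , drop = FALSE]; e <- e[ok]
    if (nrow(hb)) {
      key <- paste(pmin(hb$donor, hb$acceptor), pmax(hb$donor, hb$acceptor))
      best <- tapply(seq_len(nrow(hb)), key, function(ix) ix[which.min(e[ix])])
      hb <- hb[unlist(best), , drop = FALSE]
      bars <- rbind(bars, data.frame(i = hb$donor, j = hb$acceptor,
                                     type = hb$type,
                                     e_hb = e[unlist(best)]))
    }
  }
  if (isTRUE(opt$tethers)) {
    te <- find_tethers(structure, bonds, opt$tether_cut)
    if (nrow(te))
      bars <- rbind(bars, data.frame(i = te$i, j = te$j, type = "tether",
                                     e_hb = NA_real_))
  }
  net <- constraint_network(n, bars)
  attr(net, "atoms") <- structure
  net
}

# hydrophobic tethers: C/S pairs, not bonded and not 1-3 neighbours,
# d <= min(cut, r_vdw_i + r_vdw_j + 0.25)
find_tethers <- function(structure, bonds, cut = 3.5) {
  cs <- which(structure$element %in% c("C", "S"))
  if (length(cs) < 2) return(data.frame(i = integer(), j = integer()))
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  nb <- vector("list", nrow(structure))
  for (k in seq_len(nrow(bonds))) {
    nb[[bonds$i[k]]] <- c(nb[[bonds$i[k]]], bonds$j[k])
    nb[[bonds$j[k]]] <- c(nb[[bonds$j[k]]], bonds$i[k])
  }
  rad <- .elem_radius(structure$element, .vdw_radius, 1.7)
  out_i <- integer(); out_j <- integer()
  for (ii in seq_along(cs)) {
    for (jj in seq_along(cs)) {
      if (jj <= ii) next
      a <- cs[ii]; b <- cs[jj]
      if (b %in% nb[[a]]) next
      if (length(intersect(nb[[a]], nb[[b]]))) next
      d <- .dist(xyz[a, ], xyz[b, ])
      if (d <= min(cut, rad[a] + rad[b] + 0.25)) {
        out_i <- c(out_i, a); out_j <- c(out_j, b)
      }
    }
  }
  data.frame(i = out_i, j = out_j)
}

# connected components of an undirected graph, label per vertex
components_undirected <- function(n, ei, ej) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_along(ei)) {
    a <- find(ei[k]); b <- find(ej[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
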