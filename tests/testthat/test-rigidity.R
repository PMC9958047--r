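test_that("hbond energy follows the Mayo form", {
  expect_equal(hbond_energy(2.8, 180), -8)           # -V0 at the minimum
  expect_equal(hbond_energy(2.8, 90), 0)             # perpendicular F = 0
  expect_equal(hbond_energy(2.8, 80), 0)             # below screen angle
  expect_error(hbond_energy(0, 180), "degenerate")
  # duplicate-implementation oracle on a spread of geometries
  for (r in c(2.2, 2.6, 2.8, 3.1, 3.5)) for (a in c(95, 120, 141, 160, 180))
    expect_equal(hbond_energy(r, a), mayo_energy_oracle(r, a), tolerance = 1e-9)
})

test_that("hydrogen bonds are detected on the hairpin fixture", {
  st <- read_pdb(hairpin_path())
  hb <- detect_hbonds(st)
  # hand-audited fixture: exactly the three designed inter-strand bonds
  expect_equal(nrow(hb), 3)
  expect_true(all(hb$type == "hbond"))
  expect_equal(hb$r_da, rep(2.9, 3), tolerance = 1e-6)
  e <- hbond_energy(hb$r_da, hb$angle_dha)
  expect_equal(e, rep(e[1], 3))
  expect_lt(e[1], 0)
  # far-apart donor/acceptor pairs are never reported
  expect_true(all(hb$r_da <= 3.6) && all(hb$r_ha <= 2.6))
  # unprotonated structure is rejected
  heavy <- st[st$element != "H", ]
  class(heavy) <- class(st)
  expect_error(detect_hbonds(heavy), "protonate")
})

test_that("detect_hbonds rejects long donor-acceptor distances", {
  # two waters-worth of N-H / O at 5 A: geometry screen must fail
  st <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                   resname = c("ALA", "ALA", "GLY"), chain = "A",
                   resid = c(1L, 1L, 5L),
                   x = c(0, 0, 5), y = c(0, 1, 1), z = 0,
                   element = c("N", "H", "O"))
  expect_equal(nrow(detect_hbonds(st)), 0)
})

test_that("build_network assigns FIRST bar multiplicities", {
  # diatomic: one rotatable covalent bond -> a single 5-bar edge
  st <- data.frame(serial = 1:2, name = c("C1", "C2"), resname = "LIG",
                   chain = "A", resid = 1L, x = c(0, 1.5), y = 0, z = 0,
                   element = "C")
  net <- build_network(st)
  expect_equal(net$n_bodies, 2)
  expect_equal(nrow(net$bars), 1)
  expect_equal(net$bars$type, "cov_rot")
  expect_equal(net$bars$mult, 5L)
  # the hairpin fixture is two disconnected strands: warn, keep largest
  expect_warning(net2 <- build_network(read_pdb(hairpin_path())),
                 "disconnected")
  expect_equal(net2$n_bodies, 15)
  # hand enumeration on one strand: 14 covalent bonds of which 2 peptide
  # C-N and 3 carbonyl C=O are locked
  expect_equal(sum(net2$bars$type == "cov_lock"), 5)
  expect_equal(sum(net2$bars$type == "cov_rot"), 9)
  # bent carbon chain: ends approach within the tether cutoff without being
  # bonded or 1-3 neighbours -> exactly one 2-bar tether; option disables it
  st3 <- data.frame(serial = 1:4, name = paste0("C", 1:4), resname = "LIG",
                    chain = "A", resid = 1L,
                    x = c(0, 1.5, 2.25, 1.0), y = c(0, 0, 1.3, 2.1), z = 0,
                    element = "C")
  n_on <- build_network(st3)
  n_off <- build_network(st3, options = list(tethers = FALSE))
  expect_equal(sum(n_on$bars$type == "tether"), 1)
  expect_equal(n_on$bars$mult[n_on$bars$type == "tether"], 2L)
  expect_equal(sum(n_off$bars$type == "tether"), 0)
})

test_that("pebble game resolves two-body cases exactly", {
  lock <- constraint_network(2, data.frame(i = 1, j = 2, type = "cov_lock"))
  d <- pebble_game(lock)           # 6 bars remove all 6 relative DOF
  expect_equal(length(d$sizes), 1)
  expect_equal(d$largest_fraction, 1)
  expect_equal(d$n_independent, 6)
  tether <- constraint_network(2, data.frame(i = 1, j = 2, type = "tether"))
  d2 <- pebble_game(tether)        # 2 bars leave relative motion
  expect_equal(length(d2$sizes), 2)
  expect_equal(d2$floppy_modes, 4)
})

test_that("pebble game matches the rank oracle on random networks", {
  for (s in 1:120) {
    net <- random_test_network(s)
    pg <- pebble_game(net)
    oc <- oracle_decomposition(net, seed = s + 7)
    expect_identical(partition_sig(pg$labels), partition_sig(oc),
                     label = sprintf("partition (case %d)", s))
    # redundancy consistency: independent bars = 6n - 6 - floppy modes
    expect_equal(pg$n_independent + pg$n_redundant, sum(net$bars$mult))
  }
})

test_that("decomposition is invariant under bar-row permutation", {
  for (s in c(3, 11, 42)) {
    net <- random_test_network(s)
    set.seed(s)
    perm <- sample(nrow(net$bars))
    net2 <- constraint_network(net$n_bodies, net$bars[perm, ])
    expect_identical(partition_sig(pebble_game(net)$labels),
                     partition_sig(pebble_game(net2)$labels))
  }
})

test_that("cluster entropy has its closed forms", {
  expect_equal(cluster_entropy(10), 0)                      # one cluster
  expect_equal(cluster_entropy(c(5, 5)), log(2))
  for (k in 1:20)
    expect_equal(cluster_entropy(rep(3, k)), log(k), tolerance = 1e-12)
  # H = 0 iff a single cluster; H <= log(number of clusters)
  for (s in 1:50) {
    set.seed(s)
    sizes <- sample(1:9, sample(1:6, 1), replace = TRUE)
    h <- cluster_entropy(sizes)
    if (length(sizes) == 1) expect_equal(h, 0) else expect_gt(h, 0)
    expect_lte(h, log(length(sizes)) + 1e-12)
  }
})

test_that("the cutoff-temperature map is the printed linear law", {
  expect_equal(ecut_to_temperature(-0.1), 302)
  expect_equal(ecut_to_temperature(-6.0), 420)
  expect_equal(ecut_to_temperature(0), 300)
  sched <- default_schedule()
  expect_equal(length(sched), 60)
  expect_equal(diff(ecut_to_temperature(sched)), rep(2, 59))
  # exact linearity: T(a) + T(b) = 2 T((a+b)/2)
  set.seed(1)
  a <- runif(20, -6, 0); b <- runif(20, -6, 0)
  expect_equal(ecut_to_temperature(a) + ecut_to_temperature(b),
               2 * ecut_to_temperature((a + b) / 2))
})

test_that("dilution removes bars monotonically and maps the schedule", {
  cfg <- gen_config(seed = 5)
  net <- gen_toy_network(12, -2.5, cfg)
  traj <- dilute(net)
  expect_equal(nrow(traj), 60)
  expect_true(all(diff(traj$n_bars_present) <= 0))
  expect_true(all(diff(traj$largest_fraction) <= 1e-12))
  expect_equal(traj$T_K, ecut_to_temperature(traj$e_cut))
  # no dilutable bars -> constant trajectory
  chain <- constraint_network(4, data.frame(i = 1:3, j = 2:4, type = "cov_lock"))
  tr2 <- dilute(chain)
  expect_equal(unique(tr2$h_type2), 0)
  expect_equal(unique(tr2$n_bars_present), 18)
  # all hbonds stronger than the schedule end -> never removed
  strong <- constraint_network(3, data.frame(i = c(1, 2), j = c(2, 3),
                                             type = "hbond", e_hb = -10))
  tr3 <- dilute(strong)
  expect_equal(unique(tr3$n_bars_present), 10)
  expect_error(dilute(net, numeric(0)), "empty")
})

test_that("planted transitions are recovered within one schedule step", {
  cfg <- gen_config(seed = 9)
  for (ec in c(-1.0, -3.0, -5.0)) {
    net <- gen_toy_network(30, ec, cfg)
    tp <- compute_tp(dilute(net))
    expect_equal(tp$tp_K, ecut_to_temperature(ec), tolerance = 2,
                 label = sprintf("Tp at planted %.1f", ec))
  }
  # planted at the first step: the cluster is already collapsed at the
  # start, H jumps at trajectory start and no transition is resolvable
  net0 <- gen_toy_network(30, -0.1, cfg)
  tr0 <- dilute(net0)
  expect_gt(tr0$h_type2[1], log(20))
  expect_error(compute_tp(tr0), "transition")
})

test_that("Td rule selects the higher transition on two-step fixtures", {
  n <- 24
  i <- seq_len(n - 1)
  # two planted shells: odd links melt at -2.0 (chain -> dimers, the large
  # entropy jump), even links at -4.0 (dimers -> singletons, smaller jump)
  e <- ifelse(i %% 2 == 1, -1.95, -3.95)
  net <- constraint_network(n, rbind(
    data.frame(i = i, j = i + 1, type = "cov_rot", e_hb = NA),
    data.frame(i = i, j = i + 1, type = "hbond", e_hb = e)))
  traj <- dilute(net)
  tp_low <- compute_tp(traj, td = 40)
  tp_high <- compute_tp(traj, td = 55)
  expect_equal(tp_low$rule_applied, "largest_slope")
  expect_equal(tp_high$rule_applied, "td_gt_50_second")
  expect_equal(tp_low$tp_K, 340, tolerance = 3)
  expect_equal(tp_high$tp_K, 380, tolerance = 3)
})

test_that("replicate aggregation is plain mean and SEM", {
  a <- aggregate_replicates(rep(360, 5))
  expect_equal(a$mean, 360)
  expect_equal(a$sem, 0)
  b <- aggregate_replicates(c(358, 360, 362))
  expect_equal(b$mean, 360)
  expect_equal(b$sem, 2 / sqrt(3))
  c1 <- aggregate_replicates(412)
  expect_true(is.na(c1$sem))
  expect_error(aggregate_replicates(numeric(0)), "empty")
})
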