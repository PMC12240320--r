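test_that("salt bridges obey the acidic-O/basic-N distance rule", {
  crit <- contact_criteria()  # sb_cutoff 3.2
  hit <- salt_bridges(glu_arg_pair(3.1), crit, partition = list(a = "A", b = "B"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$atom_a, "OE2")
  expect_equal(hit$atom_b, "NH1")
  miss <- salt_bridges(glu_arg_pair(3.3), crit, partition = list(a = "A", b = "B"))
  expect_equal(nrow(miss), 0L)
})

test_that("backbone oxygens never qualify as salt-bridge partners", {
  # put the GLU backbone O right next to the ARG NH1 but the side-chain OE2 far
  s <- glu_arg_pair(3.1)
  s$x[s$name == "OE2"] <- 50
  s$x[s$name == "O" & s$chain == "A"] <- s$x[s$name == "NH1"] - 3.0
  s$y[s$name == "O" & s$chain == "A"] <- s$y[s$name == "NH1"]
  s$z[s$name == "O" & s$chain == "A"] <- s$z[s$name == "NH1"]
  expect_equal(nrow(salt_bridges(s, partition = list(a = "A", b = "B"))), 0L)
})

test_that("histidine counts as basic only when requested", {
  s <- tiny_structure(data.frame(
    chain = c("A", "A", "B", "B"), resseq = c(1, 1, 1, 1),
    resname = c("GLU", "GLU", "HIS", "HIS"),
    name = c("CA", "OE1", "CA", "NE2"),
    x = c(0, 1, 5, 1), y = c(0, 0, 0, 3.0), z = 0))
  part <- list(a = "A", b = "B")
  expect_equal(nrow(salt_bridges(s, contact_criteria(), part)), 0L)
  expect_equal(nrow(salt_bridges(s, contact_criteria(include_his = TRUE), part)), 1L)
})

test_that("heavy-only hydrogen bonds use the donor-acceptor distance rule", {
  # serine OG donor 2.8 A from glutamate OE1 acceptor
  mk <- function(d) tiny_structure(data.frame(
    chain = c("A", "A", "B", "B"), resseq = c(1, 1, 1, 1),
    resname = c("SER", "SER", "GLU", "GLU"),
    name = c("CA", "OG", "CA", "OE1"),
    x = c(0, 0, 5, 0), y = c(-1.5, 0, d + 1.5, d), z = 0))
  part <- list(a = "A", b = "B")
  crit <- contact_criteria("heavy_only", hb_da_cutoff = 3.0)
  expect_equal(nrow(hydrogen_bonds(mk(2.8), crit, part)), 1L)
  expect_equal(nrow(hydrogen_bonds(mk(3.5), crit, part)), 0L)
})

test_that("explicit mode applies the D-H...A angle criterion", {
  mk <- function(hx) tiny_structure(data.frame(
    chain = c("A", "A", "A", "B", "B"), resseq = c(1, 1, 1, 1, 1),
    resname = c("SER", "SER", "SER", "GLU", "GLU"),
    name = c("CA", "OG", "HG", "CA", "OE1"),
    x = c(-1.5, 0, hx, 5, 0), y = c(0, 0, 0.6, 4.3, 2.8), z = 0))
  part <- list(a = "A", b = "B")
  crit <- contact_criteria("explicit")
  # hydrogen on the donor-acceptor axis: near-linear, accepted
  expect_equal(nrow(hydrogen_bonds(mk(0), crit, part)), 1L)
  # hydrogen still attached but well off the axis: angle fails
  expect_equal(nrow(hydrogen_bonds(mk(0.9), crit, part)), 0L)
  # no hydrogens at all: explicit mode refuses with advice
  nohyd <- as.data.frame(mk(0))[-3, ]
  expect_error(hydrogen_bonds(as_structure(nohyd), crit, part), "heavy_only")
})

test_that("partitions exclude intra-chain pairs", {
  s <- tiny_structure(data.frame(
    chain = c("A", "A", "A", "A", "B"), resseq = c(1, 1, 5, 5, 1),
    resname = c("SER", "SER", "GLU", "GLU", "ALA"),
    name = c("CA", "OG", "CA", "OE1", "CA"),
    x = c(0, 0, 5, 0, 50), y = c(-1.5, 0, 4.3, 2.8, 0), z = 0))
  crit <- contact_criteria("heavy_only")
  expect_equal(nrow(hydrogen_bonds(s, crit, NULL)), 1L)  # intra allowed
  expect_equal(nrow(hydrogen_bonds(s, crit, list(a = "A", b = "B"))), 0L)
})

test_that("interface residues respect strict cutoffs and monotonicity", {
  # closest heavy atoms exactly 5.5 A apart
  s <- tiny_structure(data.frame(
    chain = c("A", "A", "B", "B"), resseq = c(1, 1, 1, 1),
    resname = "ALA", name = c("CA", "CB", "CA", "CB"),
    x = c(0, 0, 0, 0), y = c(-1.5, 0, 5.5, 7.0), z = 0))
  in6 <- interface_residues(s, "A", "B", cutoff = 6)
  in5 <- interface_residues(s, "A", "B", cutoff = 5)
  expect_equal(nrow(in6$a), 1L)
  expect_equal(in6$a$min_dist, 5.5)
  expect_equal(nrow(in5$a), 0L)
  expect_equal(nrow(in5$b), 0L)
  expect_error(interface_residues(s, "A", "Z", 6), "unknown chain")
})

test_that("interface sets are nested across the 6/5/4 A cutoffs and symmetric", {
  s <- tiny_structure(data.frame(
    chain = rep(c("A", "B"), each = 3), resseq = rep(1:3, 2),
    resname = "ALA", name = "CA",
    x = rep(c(0, 10, 20), 2), y = c(0, 0, 0, 3.5, 4.5, 5.5), z = 0))
  key <- function(df) paste(df$chain, df$resseq)
  r6 <- interface_residues(s, "A", "B", 6)
  r5 <- interface_residues(s, "A", "B", 5)
  r4 <- interface_residues(s, "A", "B", 4)
  expect_equal(nrow(r6$a), 3L)
  expect_equal(nrow(r5$a), 2L)
  expect_equal(r4$a$resseq, 1L)
  expect_true(all(key(r5$a) %in% key(r6$a)))
  expect_true(all(key(r4$a) %in% key(r5$a)))
  # symmetry: each reported A residue has a matching reported B partner
  expect_equal(r6$b$resseq, r6$a$resseq)
  expect_equal(r5$b$min_dist, r5$a$min_dist)
})

test_that("persistence recovers planted duty cycles and tiers", {
  resn_a <- rep("ALA", 30); resn_a[c(5, 15, 25)] <- "GLU"
  resn_b <- rep("ALA", 30); resn_b[c(5, 15, 25)] <- "LYS"
  sp <- sim_spec(n_res_a = 30, n_res_b = 30, resnames_a = resn_a,
                 resnames_b = resn_b, sigma = 0.2, n_snapshots = 2000,
                 dt_ns = 2, seed = 20,
                 contacts = list(
                   list(a = "A:5:OE1",  b = "B:5:NZ",  bound = 3.0,
                        unbound = 8.0, duty = 0.002, schedule = "block"),
                   list(a = "A:15:OE1", b = "B:15:NZ", bound = 3.0,
                        unbound = 8.0, duty = 0.02, schedule = "random"),
                   list(a = "A:25:OE1", b = "B:25:NZ", bound = 3.0,
                        unbound = 8.0, duty = 0.2, schedule = "random")))
  tr <- simulate_traj(sp)
  gt <- ground_truth(sp)
  pers <- persistence(tr, contact_criteria(), partition = list(a = "A", b = "B"),
                      kind = "saltbridge")
  expect_equal(nrow(pers), 3L)
  rec <- pers[order(pers$resseq_a), ]
  # recovered fractions match the realized schedules exactly, and the planted
  # duty cycles within 3 binomial standard deviations
  expect_equal(rec$fraction, gt$contacts$realized_fraction)
  for (i in 1:3) {
    duty <- gt$contacts$duty[i]
    sd3 <- 3 * sqrt(duty * (1 - duty) / 2000)
    expect_lt(abs(rec$fraction[i] - duty), sd3 + 1e-9)
  }
  expect_equal(as.character(rec$tier), c(">0.1%", ">1%", "stable>5%"))
  # duration is fraction times nominal span
  expect_equal(rec$duration_ns, rec$fraction * 2000 * 2)
})

test_that("never-formed contacts are absent from persistence output", {
  resn_a <- rep("ALA", 5); resn_a[2] <- "GLU"
  resn_b <- rep("ALA", 5); resn_b[2] <- "LYS"
  sp <- sim_spec(n_res_a = 5, n_res_b = 5, resnames_a = resn_a,
                 resnames_b = resn_b, sigma = 0.1, n_snapshots = 50, seed = 21,
                 contacts = list(list(a = "A:2:OE1", b = "B:2:NZ", bound = 3.0,
                                      unbound = 8.0, duty = 0,
                                      schedule = "block")))
  pers <- persistence(simulate_traj(sp), contact_criteria(),
                      partition = list(a = "A", b = "B"), kind = "saltbridge")
  expect_equal(nrow(pers), 0L)
})

test_that("distance series reproduce planted geometry", {
  top <- ca_topology(2)
  # constant 4 A separation
  tr <- manual_traj(top, 5, function(t) rbind(c(0, 0, 0), c(4, 0, 0)), dt_ns = 2)
  ds <- distance_series(tr, "A:1:CA", "A:2:CA")
  expect_equal(ds$distance, rep(4, 5))
  expect_equal(ds$time_ns, seq(0, 8, by = 2))
  # planted sinusoidal separation
  sep <- function(t) 5 + sin(2 * pi * t / 20)
  tr2 <- manual_traj(top, 40, function(t) rbind(c(0, 0, 0), c(sep(t), 0, 0)))
  ds2 <- distance_series(tr2, "A:1:CA", "A:2:CA")
  expect_equal(ds2$distance, sep(1:40), tolerance = 1e-9)
  expect_equal(max(ds2$distance), 6, tolerance = 1e-6)
  expect_error(distance_series(tr2, "A:9:CA", "A:2:CA"), "A:9:CA")
})

test_that("multi-atom groups take the minimum pairwise distance", {
  top <- ca_topology(3)
  tr <- manual_traj(top, 2, function(t)
    rbind(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0)))
  ds <- distance_series(tr, "A:1:CA", c("A:2:CA", "A:3:CA"))
  expect_equal(ds$distance, c(3, 3))
})
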