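crit <- interaction_criteria()

test_that("hydrogen-bond detection is boundary-inclusive in distance and angle", {
  topo <- hbond_topology(with_h = FALSE)
  ev <- detect_contacts_frame(frame2(3.0), topo, crit)
  expect_identical(ev$type, "hbond")
  expect_true(ev$heavy_atom_only)
  # exactly at the 3.2 A cutoff: still a hydrogen bond
  expect_identical(detect_contacts_frame(frame2(3.2), topo, crit)$type, "hbond")
  expect_identical(nrow(detect_contacts_frame(frame2(3.2001), topo, crit)), 0L)
  # explicit hydrogen: angle test at exactly 135 degrees passes
  topoh <- hbond_topology(with_h = TRUE)
  mk <- function(angle) {
    # hydrogen at the origin, donor 1 A away on +x, acceptor 2.2 A from H
    # at exactly `angle` degrees: D-H-A angle is exact by construction
    th <- angle * pi / 180
    X <- matrix(0, 3, 3)
    rows <- match(c("ND", "HD", "OA"), topoh$atoms$atom_name)
    X[rows[2], ] <- c(0, 0, 0)
    X[rows[1], ] <- c(1, 0, 0)
    X[rows[3], ] <- 2.2 * c(cos(th), sin(th), 0)
    X
  }
  expect_identical(detect_contacts_frame(mk(150), topoh, crit)$type, "hbond")
  ev135 <- detect_contacts_frame(mk(135), topoh, crit)
  expect_identical(ev135$type, "hbond")
  expect_false(ev135$heavy_atom_only)
  expect_identical(nrow(detect_contacts_frame(mk(120), topoh, crit)), 0L)
})

test_that("salt bridges, pi stacks and hydrophobic contacts respect cutoffs", {
  st <- salt_topology()
  # the charged pair is also donor/acceptor: both event types are reported
  expect_true("salt_bridge" %in% detect_contacts_frame(frame2(3.1), st, crit)$type)
  expect_true("salt_bridge" %in% detect_contacts_frame(frame2(3.2), st, crit)$type)
  expect_identical(nrow(detect_contacts_frame(frame2(3.3), st, crit)), 0L)
  rt <- ring_topology()
  ring_frame <- function(d) rbind(ring_coords(c(0, 0, 0)),
                                  ring_coords(c(0, 0, d)))
  expect_true("pi_stack" %in% detect_contacts_frame(ring_frame(3.5), rt, crit)$type)
  expect_false("pi_stack" %in% detect_contacts_frame(ring_frame(3.6), rt, crit)$type)
  # nonpolar pair at exactly 4.5 A
  np <- toy_topology(2)
  np$atoms$nonpolar <- TRUE
  expect_identical(detect_contacts_frame(frame2(4.5), np, crit)$type,
                   "hydrophobic")
  expect_identical(nrow(detect_contacts_frame(frame2(4.6), np, crit)), 0L)
})

test_that("events are residue-deduplicated and symmetric in partner order", {
  rt <- ring_topology()   # 6 nonpolar atoms per residue: many atom pairs
  fr <- rbind(ring_coords(c(0, 0, 0)), ring_coords(c(0, 0, 4)))
  ev <- detect_contacts_frame(fr, rt, crit)
  hyd <- ev[ev$type == "hydrophobic", ]
  expect_identical(nrow(hyd), 1L)          # one residue pair, one event
  expect_true(hyd$res_a < hyd$res_b)
})

test_that("persistence fractions and flags follow the 75% rule exactly", {
  ev <- data.frame(res_a = "A:1", res_b = "A:2", type = "hbond",
                   heavy_atom_only = FALSE, frame = 1:80)
  tab <- persistence_table(ev, macrostate_labels = rep("M1", 100))
  expect_equal(tab$fraction, 0.80)
  expect_true(tab$persistent)
  tab74 <- persistence_table(ev[1:74, ], rep("M1", 100))
  expect_false(tab74$persistent)
  tab75 <- persistence_table(ev[1:75, ], rep("M1", 100))
  expect_true(tab75$persistent)   # inclusive at exactly 0.75
  # absent contacts are omitted rather than reported at fraction 0
  expect_identical(nrow(tab[tab$fraction == 0, ]), 0L)
  # frame permutation within a state leaves fractions unchanged
  ev_perm <- ev; ev_perm$frame <- sample(ev$frame)
  expect_equal(persistence_table(ev_perm, rep("M1", 100))$fraction, 0.80)
  expect_error(persistence_table(ev, factor(rep("M1", 100),
                                            levels = c("M1", "M2"))),
               "zero frames")
})

test_that("noise-free template detection contains the encoded patterns", {
  fx <- xpd_fx()
  f <- fx$fixture
  for (s in c("S1", "S4", "S5", "S7")) {
    ev <- detect_contacts_frame(f$templates[[s]], fx$topology, crit)
    got <- event_keys(ev)
    expected <- expected_contact_keys(fx, s)
    expect_true(all(expected %in% got),
                label = sprintf("state %s: all encoded contacts detected", s))
    # encoded-off contacts stay off: the S4-only nucleotide zipper must not
    # appear in the apo template, and the apo C2 anchors must vanish in S4
    if (s == "S1") {
      expect_false(any(grepl("L:901|L:902", got)))      # no ligand contacts
      expect_true(any(grepl("P:112", got)))             # R112-DNA on
    }
    if (s == "S4") {
      expect_false("D:10 P:112 salt_bridge" %in% got)   # C2 grip released
      expect_true(any(grepl("L:901|L:902", got)))       # nucleotide zipper
    }
  }
})

test_that("interface filtering and state differencing behave set-wise", {
  fx <- xpd_fx()
  f <- fx$fixture
  frames <- lapply(c("S1", "S4"), function(s) f$templates[[s]])
  traj <- toy_trajectory(frames)
  ev <- detect_contacts(traj, fx$topology, crit)
  tab <- persistence_table(ev, c("S1", "S4"))
  # protein-DNA restriction returns only protein-nucleotide rows
  pd <- interface_filter(tab, "RecA2", "DNA", topology = fx$topology)
  ch <- cbind(sub(":.*", "", pd$res_a), sub(":.*", "", pd$res_b))
  expect_true(all(apply(ch, 1, function(r) "D" %in% r)))
  # RecA1-RecA2 interface in the ATP state includes the motif V / motif Ia
  # hydrophobic pair
  ifc <- interface_filter(tab, "RecA1", "RecA2", topology = fx$topology)
  expect_true(any(ifc$state == "S4" &
                  ifc$res_a == "P:608" & ifc$res_b == "P:78" |
                  ifc$res_a == "P:78" & ifc$res_b == "P:608"))
  expect_error(interface_filter(tab, "RecA1", "RecA1", topology = fx$topology),
               "overlap")
  # diff: identical states yield empty gained/lost; S1 vs S4 equals the
  # symmetric difference of the encoded persistent sets
  d0 <- contact_diff(tab, "S1", "S1")
  expect_identical(nrow(d0$gained), 0L)
  expect_identical(nrow(d0$lost), 0L)
  d14 <- contact_diff(tab, "S1", "S4")
  d41 <- contact_diff(tab, "S4", "S1")
  expect_identical(d14$gained, d41$lost)
  expect_identical(d14$lost, d41$gained)
  expect_true("P:511" %in% unlist(d14$gained[, c("res_a", "res_b")]))
  expect_true("P:112" %in% unlist(d14$lost[, c("res_a", "res_b")]))
})

test_that("constriction contact counts switch reciprocally between apo and ATP", {
  fx <- xpd_fx()
  f <- fx$fixture
  traj <- toy_trajectory(lapply(c("S1", "S4"), function(s) f$templates[[s]]))
  tab <- persistence_table(detect_contacts(traj, fx$topology, crit),
                           c("S1", "S4"))
  members <- list(
    c1 = c(f$constrictions$c1$wall_a, f$constrictions$c1$wall_b,
           505, 508, 511, 540, 541, 542, 543, 599, 601, 625, 626, 627, 628,
           683, 686),
    c2 = c(f$constrictions$c2$wall_a, f$constrictions$c2$wall_b,
           111, 112, 113, 192, 223, 303, 304, 305))
  cc <- constriction_contact_counts(tab, members)
  apo <- cc[cc$state == "S1", ]; atp <- cc[cc$state == "S4", ]
  expect_gt(apo$c2, atp$c2)    # Constriction 2 grips DNA in the apo state
  expect_gt(atp$c1, apo$c1)    # Constriction 1 grips in the ATP-bound state
  # empty member sets count zero
  cc0 <- constriction_contact_counts(tab, list(c1 = integer(0),
                                               c2 = integer(0)))
  expect_true(all(cc0$c1 == 0 & cc0$c2 == 0))
  # manual tally on a 5-contact toy table
  toy <- data.frame(state = "M", res_a = c("P:1", "P:2", "D:1", "P:9", "P:1"),
                    res_b = c("D:3", "D:4", "P:3", "D:2", "P:2"),
                    type = "hbond", fraction = 1, persistent = TRUE)
  class(toy) <- c("helimsm_contact_table", "data.frame")
  ct <- constriction_contact_counts(toy, list(c1 = c(1, 2), c2 = c(3, 9)))
  expect_identical(ct$c1, 2); expect_identical(ct$c2, 2)
})
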