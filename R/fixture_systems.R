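# System definitions for the XPD-like and DinG-like fixtures.
#
# Residue numbering follows the human XPD / E. coli DinG citations used in
# the contact and mutation analyses (e.g. XPD R511, Y627, D234). Cited
# residues carry side-chain pseudo-atoms; filler residues flesh out the
# rigid domain bodies and the constriction walls.

xpd_state_order <- c("S1", "S2", "S3", "S4", "S5", "S6", "S7",
                     "T1", "T2", "T3")
ALL_XPD <- xpd_state_order
ding_state_order <- c("SD1", "SD2", "SD3", "SD4", "SD5",
                      "TD1", "TD2", "TD3", "TD4")
ALL_DING <- ding_state_order

residue_roster <- function(body, cited) {
  rbind(
    data.frame(resno = body, code = "A", role = "body",
               stringsAsFactors = FALSE),
    data.frame(resno = as.integer(names(cited)), code = unname(cited),
               role = "sc", stringsAsFactors = FALSE))
}

make_state <- function(id, w1, w2, dna_offset, ligand, reca1 = c(0, 0, 0),
                       reca2 = c(0, 0, 0), arch = c(0, 0, 0),
                       fes = c(0, 0, 0), bridge_z = 0, trap_shift = NULL) {
  list(id = id, widths = list(c1 = w1, c2 = w2), dna_offset = dna_offset,
       ligand = ligand,
       domain_shift = list(RecA1 = reca1, RecA2 = reca2, Arch = arch,
                           FeS = fes),
       bridge_z = bridge_z, trap_shift = trap_shift)
}

xpd_fixture_spec <- function() {
  cited <- c(
    # RecA1: Q-motif / motif I / motif Ia / motif II / C-terminal part
    `12` = "F", `14` = "Y", `17` = "I", `18` = "Y", `44` = "S", `48` = "K",
    `49` = "T", `50` = "V", `75` = "R", `76` = "T", `78` = "P", `223` = "K",
    `234` = "D", `235` = "E", `240` = "D", `694` = "P", `696` = "W",
    # FeS
    `111` = "S", `112` = "R", `113` = "K", `192` = "Y",
    # Arch
    `303` = "A", `304` = "H", `305` = "L", `415` = "T", `417` = "I",
    # RecA2: Constriction 1 / motif IV / motif V / spring helix / motif VI
    `461` = "L", `508` = "F", `511` = "R", `540` = "T", `541` = "S",
    `542` = "Y", `543` = "Q", `599` = "V", `601` = "R", `603` = "K",
    `608` = "I", `625` = "Y", `626` = "V", `627` = "Y", `628` = "T",
    `632` = "I", `635` = "A", `636` = "R", `658` = "R", `666` = "R",
    `669` = "R", `681` = "D", `683` = "R", `686` = "R",
    # constriction walls (side-chain rows define the channel width)
    `127` = "A", `130` = "A", `133` = "A", `135` = "H", `196` = "R",
    `210` = "H", `211` = "Y", `213` = "A", `217` = "I", `220` = "L",
    `505` = "Q", `536` = "Q", `546` = "Q", `549` = "Q", `552` = "Q",
    `630` = "Q", `634` = "Q", `638` = "Q", `650` = "Q", `654` = "Q")
  body <- c(5, 25, 35, 47, 55, 60, 65, 85, 90, 95, 205, 225, 230, 245,
            105, 120, 145, 150, 155, 160, 165, 170, 175, 180, 185,
            250, 260, 270, 280, 290, 300, 310, 320, 330, 340, 350, 360,
            370, 380, 390, 400, 410, 420, 430,
            445, 455, 465, 475, 485, 495, 515, 525, 555, 565, 575, 585,
            595, 602, 615, 645, 665, 675, 685)
  residues <- residue_roster(body, cited)
  domain_ranges <- data.frame(
    chain = "P",
    start_res = c(1, 100, 201, 247, 440, 690),
    end_res   = c(99, 200, 246, 439, 689, 700),
    label     = c("RecA1", "FeS", "RecA1", "Arch", "RecA2", "RecA1"),
    stringsAsFactors = FALSE)

  centers <- list(RecA1 = c(40, 6, -8), RecA2 = c(12, -6, -8),
                  Arch = c(52, 4, 14), FeS = c(62, -8, 2))
  lay <- function(dom, rng) {
    resno <- residues$resno[residues$role == "body" |
                            residues$resno %in% c(12, 14, 17, 18, 44, 48, 49,
                                                  50, 75, 76, 78, 223, 234,
                                                  235, 240, 694, 696, 111,
                                                  112, 113, 192, 303, 304,
                                                  305, 415, 417, 461, 508,
                                                  511, 540, 541, 542, 543,
                                                  599, 601, 603, 608, 625,
                                                  626, 627, 628, 632, 635,
                                                  636, 658, 666, 669, 681,
                                                  683, 686)]
    inr <- resno[vapply(resno, function(r) any(r >= rng[, 1] & r <= rng[, 2]),
                        TRUE)]
    list(resno = sort(inr), offsets = body_offsets(length(inr)))
  }
  rng <- function(lbl) as.matrix(domain_ranges[domain_ranges$label == lbl,
                                               c("start_res", "end_res")])
  body_layout <- list(RecA1 = lay("RecA1", rng("RecA1")),
                      RecA2 = lay("RecA2", rng("RecA2")),
                      Arch = lay("Arch", rng("Arch")),
                      FeS = lay("FeS", rng("FeS")))

  constrictions <- list(
    c1 = list(wall_a = c(630, 634, 638, 650, 654),
              wall_b = c(505, 536, 546, 549, 552),
              wall_x = site_x(1:5), y_mid = 0),
    c2 = list(wall_a = c(127, 135, 196, 130, 133),
              wall_b = c(213, 217, 220, 210, 211),
              wall_x = site_x(9:13), y_mid = -0.05))

  nuc <- c("S4", "S5")   # nucleotide-bound states
  atp3 <- c("S3", "S4", "S5")
  apo <- c("S1", "S2", "S7")
  ct <- rbind(
    # --- Constriction 1 / groove base (5' end) ---
    contact_row(627, "site:2:BAS", "hydrophobic", ALL_XPD, 200),
    contact_row(625, "site:2:C1'", "hydrophobic", ALL_XPD, 320),
    contact_row(543, "site:2:P", "hbond", atp3, 80),
    contact_row(508, "site:3:BAS", "hydrophobic", ALL_XPD, 150),
    contact_row(601, "site:3:P", "salt_bridge", ALL_XPD, 270),
    contact_row(628, "site:3:C1'", "hydrophobic", atp3, 30),
    contact_row(683, "site:4:P", "salt_bridge", ALL_XPD, 240),
    contact_row(540, "site:4:P", "hbond", atp3, 120),
    contact_row(542, "site:4:P", "hbond", atp3, 10),
    contact_row(626, "site:4:C1'", "hydrophobic", atp3, 60),
    contact_row(686, "site:5:P", "salt_bridge", ALL_XPD, 210),
    contact_row(541, "site:5:P", "hbond", atp3, 90),
    contact_row(599, "site:5:C1'", "hydrophobic", atp3, 330),
    contact_row(511, "site:3:P", "salt_bridge", atp3, 240),
    # --- bridge segment ---
    contact_row(76, "site:6:P", "hbond", c("S1", "S6", "S7"), 250),
    contact_row(75, "site:7:P", "salt_bridge", ALL_XPD, 110),
    contact_row(603, "site:8:P", "salt_bridge", "S5", 270),
    # --- Constriction 2 (3' end) ---
    contact_row(304, "site:10:P", "hbond", c("S1", "S2", "S5", "S7", "T1"), 140),
    contact_row(303, "site:10:C1'", "hydrophobic", "S5", 40),
    contact_row(111, "site:10:P", "hbond", "S5", 260),
    contact_row(112, "site:10:P", "salt_bridge", c("S1", "S2", "S7", "T1"), 320),
    contact_row(113, "site:11:P", "salt_bridge", "S5", 100),
    contact_row(305, "site:11:C1'", "hydrophobic", "S5", 170),
    contact_row(192, "site:11:BAS", "hydrophobic", "S5", 300),
    contact_row(223, "site:12:P", "salt_bridge", "S5", 230),
    # --- ATP/ADP pocket (ligand present in S4/S5 only) ---
    contact_row(48, "L:901:PG", "salt_bridge", "S4", 180),
    contact_row(48, "L:901:PB", "salt_bridge", "S5", 180),
    contact_row(666, "L:901:PG", "salt_bridge", "S4", 300),
    contact_row(669, "L:901:PB", "salt_bridge", "S4", 60),
    contact_row(44, "L:901:O3", "hbond", nuc, 200),
    contact_row(49, "L:901:O3", "hbond", nuc, 340),
    contact_row(234, "L:902:MG", "salt_bridge", "S4", 120),
    contact_row(235, "L:902:MG", "salt_bridge", "S4", 250),
    contact_row(14, "L:901:ADE", "hydrophobic", nuc, 90),
    contact_row(18, "L:901:ADE", "hydrophobic", nuc, 270),
    contact_row(12, "L:901:ADE", "hydrophobic", "S4", 30),
    contact_row(17, "L:901:ADE", "hydrophobic", "S4", 150),
    contact_row(50, "L:901:ADE", "hydrophobic", "S4", 330),
    # --- RecA1-RecA2 interface and spindle/spring couplings ---
    contact_row(78, "P:608:SC", "hydrophobic", c("S3", "S4", "T2"), 150),
    contact_row(461, "P:696:SC", "hydrophobic", nuc, 200),
    contact_row(240, "P:658:SC", "salt_bridge", c("S1", "S2", "S6", "S7"), 90),
    contact_row(240, "P:636:SC", "salt_bridge", atp3, 90),
    contact_row(632, "P:417:SC", "hydrophobic", ALL_XPD, 150),
    contact_row(635, "P:415:SC", "hydrophobic", ALL_XPD, 210),
    # D681 positions R683 via an intra-domain salt bridge; the 683 row above
    # must precede this one so the anchor side chain is already placed
    contact_row(681, "P:683:SC", "salt_bridge", ALL_XPD, 100))

  pinned_sc <- data.frame(
    key = c("P:608:SC", "P:636:SC", "P:658:SC", "P:694:SC", "P:696:SC",
            "P:415:SC", "P:417:SC"),
    domain = c("RecA2", "RecA2", "RecA2", "RecA1", "RecA1", "Arch", "Arch"),
    ox = c(8, 8, 8, -5, -5, -4, -6),
    oy = c(4, -8, -4, 6, 4, -7, -6),
    oz = c(-2, 4, 4, -6, -6, -8, -8),
    stringsAsFactors = FALSE)

  states <- list(
    S1 = make_state("S1", 13.2, 6.1, 0L, "none"),
    S2 = make_state("S2", 12.6, 6.4, 0L, "none", reca2 = c(2.5, 0, 0)),
    S3 = make_state("S3", 11.4, 8.5, 0L, "none", reca2 = c(4.5, 0, 0)),
    S4 = make_state("S4", 10.7, 11.7, 0L, "atp", reca2 = c(6, 0, 0),
                    arch = c(-2, 3, 6), fes = c(-2, 0, 0), bridge_z = 2.5),
    S5 = make_state("S5", 11.6, 7.4, 0L, "adp", reca2 = c(3.5, 0, 0),
                    arch = c(0, 1.5, -2), bridge_z = 1.2),
    S6 = make_state("S6", 12.5, 10.6, 0L, "none", reca2 = c(1.5, 0, 0),
                    arch = c(0, -2, 3), fes = c(1, 1, 0)),
    S7 = make_state("S7", 13.2, 6.1, 1L, "none"))
  states$T1 <- modifyList(states$S2, list(
    id = "T1", trap_shift = list(domain = "Arch", delta = c(0, 10, 5))))
  states$T2 <- modifyList(states$S4, list(
    id = "T2", trap_shift = list(domain = "FeS", delta = c(0, -9, 6))))
  states$T3 <- modifyList(states$S6, list(
    id = "T3", trap_shift = list(domain = "RecA2", delta = c(0, -6, -9))))
  states <- states[xpd_state_order]

  list(system = "xpd",
       residues = residues,
       sc_overrides = list(`211` = list(nonpolar = FALSE),
                           `133` = list(nonpolar = FALSE),
                           `628` = list(nonpolar = TRUE),
                           `415` = list(nonpolar = TRUE)),
       domain_ranges = domain_ranges,
       domain_centers = centers,
       body_layout = body_layout,
       constrictions = constrictions,
       contacts = ct,
       pinned_sc = pinned_sc,
       c2_dna_y = -0.45,
       bas_y_offset = function(j) if (j >= 9) 1.3 else -1.3,
       ligand_pocket = list(`L:901:PG` = c(26, 2, -12),
                            `L:901:PB` = c(26, 4.2, -12.5),
                            `L:901:O3` = c(24.8, 5.5, -11.5),
                            `L:901:ADE` = c(24, 7.5, -10.5),
                            `L:902:MG` = c(27.8, 0.8, -12.8)),
       ligand_solvent = list(`L:901:PG` = c(-25, -25, -20),
                             `L:901:PB` = c(-25, -23, -20),
                             `L:901:O3` = c(-24, -24, -18.5),
                             `L:901:ADE` = c(-23, -26, -17),
                             `L:902:MG` = c(-28, -22, -21)),
       states = states,
       dt_s = 1e-6,
       step_mfpt_s = c(3.6e-3, 2.6e-4, 4.1e-5, 1.2e-4, 9e-5, 9e-5),
       trap_host = c(2L, 4L, 6L),
       trap_entry = c(3.75e-4, 5.25e-4, 7.5e-4),
       trap_exit = c(6.0e-4, 1.05e-3, 2.1e-3),
       apo_state = "S1", atp_state = "S4")
}

ding_fixture_spec <- function() {
  cited <- c(
    `85` = "N", `86` = "V", `223` = "N", `233` = "S", `236` = "V",
    `459` = "S",
    `173` = "D", `176` = "D",
    `259` = "D", `335` = "R", `419` = "W",
    `461` = "T", `511` = "I", `545` = "R", `564` = "Q", `569` = "R",
    `571` = "R", `591` = "I", `593` = "S", `612` = "K", `615` = "F",
    `617` = "P", `621` = "P", `628` = "E", `636` = "Y", `651` = "I",
    `652` = "Q",
    # walls
    `150` = "A", `160` = "A", `170` = "A", `191` = "K", `211` = "R",
    `224` = "Q", `228` = "Q", `232` = "Q", `237` = "Q", `240` = "Q",
    `560` = "Q", `565` = "Q", `570` = "Q", `575` = "Q", `580` = "Q",
    `618` = "Q", `622` = "Q", `626` = "Q", `630` = "Q", `634` = "Q")
  body <- c(5, 15, 25, 35, 45, 55, 65, 75, 95,
            105, 110, 115, 120, 125, 130, 135, 140, 165, 175, 185, 200,
            205, 215,
            222, 226, 230, 238, 242, 246, 250, 255, 457,
            262, 270, 280, 290, 300, 310, 320, 330, 340, 350, 360, 370,
            380, 390, 400, 410, 420, 430,
            445, 448, 470, 480, 490, 500, 520, 530, 540, 550, 590, 600,
            640, 660, 670, 680, 690, 700)
  residues <- residue_roster(body, cited)
  domain_ranges <- data.frame(
    chain = "P",
    start_res = c(1, 100, 220, 259, 441, 455, 461),
    end_res   = c(99, 219, 258, 440, 454, 460, 700),
    label     = c("RecA1", "FeS", "RecA1", "Arch", "RecA2", "RecA1",
                  "RecA2"),
    stringsAsFactors = FALSE)

  centers <- list(RecA1 = c(40, 6, -8), RecA2 = c(12, -6, -8),
                  Arch = c(52, 4, 14), FeS = c(62, -8, 2))
  cited_body <- c(85, 86, 223, 233, 236, 459, 173, 176, 259, 335, 419, 461,
                  511, 545, 564, 569, 571, 591, 593, 612, 615, 617, 621,
                  628, 636, 651, 652)
  lay <- function(rng) {
    resno <- residues$resno[residues$role == "body" |
                            residues$resno %in% cited_body]
    inr <- resno[vapply(resno, function(r) any(r >= rng[, 1] & r <= rng[, 2]),
                        TRUE)]
    list(resno = sort(inr), offsets = body_offsets(length(inr)))
  }
  rng <- function(lbl) as.matrix(domain_ranges[domain_ranges$label == lbl,
                                               c("start_res", "end_res")])
  body_layout <- list(RecA1 = lay(rng("RecA1")), RecA2 = lay(rng("RecA2")),
                      Arch = lay(rng("Arch")), FeS = lay(rng("FeS")))

  constrictions <- list(
    c1 = list(wall_a = c(618, 622, 626, 630, 634),
              wall_b = c(560, 565, 570, 575, 580),
              wall_x = site_x(1:5), y_mid = 0),
    c2 = list(wall_a = c(150, 191, 211, 160, 170),
              wall_b = c(224, 228, 232, 237, 240),
              wall_x = site_x(9:13), y_mid = 0.25))

  closed2 <- c("SD1", "SD2", "SD4", "SD5", "TD1", "TD3", "TD4")
  ct <- rbind(
    contact_row(636, "site:2:BAS", "hydrophobic", ALL_DING, 200),
    contact_row(615, "site:3:BAS", "hydrophobic", ALL_DING, 150),
    # extensive bridging-segment engagement (distinct from XPD)
    contact_row(545, "site:6:P", "salt_bridge", ALL_DING, 240),
    contact_row(564, "site:6:P", "hbond", ALL_DING, 100),
    contact_row(511, "site:6:C1'", "hydrophobic", ALL_DING, 330),
    contact_row(612, "site:7:P", "salt_bridge", ALL_DING, 240),
    contact_row(593, "site:7:P", "hbond", ALL_DING, 100),
    contact_row(591, "site:7:C1'", "hydrophobic", ALL_DING, 330),
    contact_row(569, "site:8:P", "salt_bridge", ALL_DING, 240),
    contact_row(617, "site:8:C1'", "hydrophobic", ALL_DING, 330),
    # Constriction 2 engagement, released in the ATP-bound state
    contact_row(223, "site:10:P", "hbond", closed2, 140),
    contact_row(236, "site:10:C1'", "hydrophobic", closed2, 40),
    contact_row(233, "site:11:P", "hbond", closed2, 260),
    # Fe-S <-> RecA2 interface formed during cleft closure
    contact_row(176, "P:571:SC", "salt_bridge", c("SD2", "SD3", "TD1", "TD2"), 90),
    contact_row(173, "P:571:SC", "salt_bridge", c("SD2", "SD3", "TD1", "TD2"), 270),
    # contacts retained in the ADP-bound state
    contact_row(86, "P:651:SC", "hydrophobic", c("SD3", "SD4", "TD2", "TD3"), 180),
    contact_row(85, "P:652:SC", "hbond", c("SD3", "SD4", "TD2", "TD3"), 90),
    # spring helix <-> Arch allosteric coupling
    contact_row(621, "P:419:SC", "hydrophobic", ALL_DING, 150),
    contact_row(628, "P:335:SC", "salt_bridge", ALL_DING, 80),
    # nucleotide
    contact_row(461, "L:901:O3", "hbond", c("SD3", "SD4", "TD2", "TD3"), 60),
    contact_row(651, "L:901:ADE", "hydrophobic", c("SD3", "TD2"), 300))

  pinned_sc <- data.frame(
    key = c("P:571:SC", "P:651:SC", "P:652:SC", "P:335:SC", "P:419:SC"),
    domain = c("RecA2", "RecA2", "RecA2", "Arch", "Arch"),
    ox = c(8, 8, 6, -4, -6),
    oy = c(-6, 4, 5, -7, -6),
    oz = c(2, -2, -2, -8, -8),
    stringsAsFactors = FALSE)

  states <- list(
    SD1 = make_state("SD1", 13.0, 9.0, 0L, "none"),
    SD2 = make_state("SD2", 12.0, 9.5, 0L, "none", reca2 = c(3, 0, 0),
                     fes = c(-3, 1, 0)),
    SD3 = make_state("SD3", 11.0, 14.0, 0L, "atp", reca2 = c(6, 0, 0),
                     arch = c(-2, 3, 6), fes = c(-3, 1, 0)),
    SD4 = make_state("SD4", 12.0, 10.8, 0L, "adp", reca2 = c(3, 0, 0),
                     arch = c(0, 1.5, -2)),
    SD5 = make_state("SD5", 13.0, 9.0, 1L, "none"))
  states$TD1 <- modifyList(states$SD2, list(
    id = "TD1", trap_shift = list(domain = "Arch", delta = c(0, 10, 5))))
  states$TD2 <- modifyList(states$SD3, list(
    id = "TD2", trap_shift = list(domain = "FeS", delta = c(0, -9, 6))))
  states$TD3 <- modifyList(states$SD4, list(
    id = "TD3", trap_shift = list(domain = "RecA2", delta = c(0, -6, -9))))
  states$TD4 <- modifyList(states$SD5, list(
    id = "TD4", trap_shift = list(domain = "Arch", delta = c(0, -8, -6))))
  states <- states[ding_state_order]

  list(system = "ding",
       residues = residues,
       sc_overrides = list(`170` = list(nonpolar = FALSE)),
       domain_ranges = domain_ranges,
       domain_centers = centers,
       body_layout = body_layout,
       constrictions = constrictions,
       contacts = ct,
       pinned_sc = pinned_sc,
       c2_dna_y = -1.6,
       bas_y_offset = function(j) if (j >= 9) 1.3 else -1.3,
       ligand_pocket = list(`L:901:PG` = c(26, 2, -12),
                            `L:901:PB` = c(26, 4.2, -12.5),
                            `L:901:O3` = c(24.8, 5.5, -11.5),
                            `L:901:ADE` = c(24, 7.5, -10.5),
                            `L:902:MG` = c(27.8, 0.8, -12.8)),
       ligand_solvent = list(`L:901:PG` = c(-25, -25, -20),
                             `L:901:PB` = c(-25, -23, -20),
                             `L:901:O3` = c(-24, -24, -18.5),
                             `L:901:ADE` = c(-23, -26, -17),
                             `L:902:MG` = c(-28, -22, -21)),
       states = states,
       dt_s = 1e-6,
       step_mfpt_s = c(8.6e-3, 2.0e-4, 1.2e-4, 8e-5),
       trap_host = 2:5,
       trap_entry = c(3.3e-4, 4.5e-4, 6.0e-4, 8.25e-4),
       trap_exit = c(5.25e-4, 9.0e-4, 1.35e-3, 2.25e-3),
       apo_state = "SD1", atp_state = "SD3")
}

#' Build the XPD-like synthetic fixture
#'
#' Ten metastable states: S1-S7 on the translocation cycle (S1/S7 apo, S4
#' ATP-bound, S5 ADP-bound; S7 differs from S1 by a one-nucleotide advance
#' of the ssDNA register) plus three kinetic traps. Embedded stepwise MFPTs
#' are S1->S2 = 3.6e-3 s and S3->S4 = 4.1e-5 s with the full cycle at
#' ~4.2e-3 s; constriction widths are 13.2/6.1 A (apo C1/C2) and
#' 10.7/11.7 A (ATP-bound).
#'
#' @return list with elements `topology` and `fixture`
#' @export
build_xpd_fixture <- function() build_fixture_from_spec(xpd_fixture_spec())

#' Build the DinG-like synthetic fixture
#'
#' Nine metastable states: SD1-SD5 on the translocation cycle plus four
#' kinetic traps. MFPT(SD1->SD2) = 8.6e-3 s; full cycle 9.0e-3 s.
#' Constriction 2 is systematically wider than in the XPD fixture.
#'
#' @return list with elements `topology` and `fixture`
#' @export
build_ding_fixture <- function() build_fixture_from_spec(ding_fixture_spec())
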