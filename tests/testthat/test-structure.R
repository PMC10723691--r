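test_that("sidechain heavy atoms follow residue topology", {
  # position 3 glycine, 4 alanine, 5 arginine
  toy2 <- gen_structure(data.frame(pos_a = integer(), pos_b = integer(),
                                   distance = numeric(), relation = character()),
                        setNames(c("G", "A", "R"), c(3, 4, 5)),
                        extra_positions = 3L:5L)
  expect_equal(nrow(sidechain_heavy_atoms(toy2$model, "A", 3)), 0L)  # glycine
  ala <- sidechain_heavy_atoms(toy2$model, "A", 4)
  expect_equal(ala$elety, "CB")
  arg <- sidechain_heavy_atoms(toy2$model, "A", 5)
  expect_setequal(arg$elety, c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"))
  expect_error(sidechain_heavy_atoms(toy2$model, "A", 99), "not in structure")
})

test_that("contacts respect the inclusive 5 A cutoff boundary", {
  segmap <- small_segmap()
  mk <- function(d) gen_structure(
    data.frame(pos_a = 5L, pos_b = 45L, distance = d, relation = "intra"),
    setNames(c("L", "K"), c(5, 45)))
  near <- detect_contacts(mk(4.9)$model, c(5L, 45L), segmap)
  expect_equal(nrow(near), 1L)
  expect_equal(near$distance, 4.9, tolerance = 1e-6)
  expect_equal(near$relation, "intra")
  at_cut <- detect_contacts(mk(5.0)$model, c(5L, 45L), segmap)
  expect_equal(nrow(at_cut), 1L)   # inclusive boundary
  far <- detect_contacts(mk(5.1)$model, c(5L, 45L), segmap)
  expect_equal(nrow(far), 0L)
})

test_that("detection equals the brute-force all-atom-pair oracle", {
  toy <- toy_structure()
  expect_lt(nrow(toy$model$atoms), 500L)
  segmap <- small_segmap()
  pos <- sort(unique(c(toy$ground_truth$pos_a, toy$ground_truth$pos_b, 150L)))
  for (cutoff in c(4.5, 5.0, 6.0)) {
    got <- detect_contacts(toy$model, pos, segmap, cutoff)
    oracle <- contact_oracle(toy$model, pos, segmap, cutoff)
    expect_identical(contact_key(got), contact_key(oracle))
    m <- match(paste(got$pos_a, got$pos_b, got$relation),
               paste(oracle$pos_a, oracle$pos_b, oracle$relation))
    expect_equal(got$distance, oracle$distance[m], tolerance = 1e-9)
  }
})

test_that("contact sets are monotone in the cutoff", {
  toy <- toy_structure()
  segmap <- small_segmap()
  pos <- unique(c(toy$ground_truth$pos_a, toy$ground_truth$pos_b))
  k45 <- contact_key(detect_contacts(toy$model, pos, segmap, 4.5))
  k50 <- contact_key(detect_contacts(toy$model, pos, segmap, 5.0))
  k60 <- contact_key(detect_contacts(toy$model, pos, segmap, 6.0))
  expect_true(all(k45 %in% k50))
  expect_true(all(k50 %in% k60))
})

test_that("contact calls are rigid-body invariant", {
  toy <- toy_structure()
  segmap <- small_segmap()
  pos <- unique(c(toy$ground_truth$pos_a, toy$ground_truth$pos_b))
  base <- detect_contacts(toy$model, pos, segmap, 5.0)

  set.seed(31)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  rot <- Rx %*% Ry %*% Rz
  at <- toy$model$atoms
  xyz <- as.matrix(at[c("x", "y", "z")]) %*% t(rot)
  at$x <- xyz[, 1] + 17.3; at$y <- xyz[, 2] - 42.0; at$z <- xyz[, 3] + 5.5
  moved <- detect_contacts(vustriage:::new_structure_model(at), pos, segmap, 5.0)

  expect_identical(contact_key(base), contact_key(moved))
  m <- match(paste(base$pos_a, base$pos_b, base$relation),
             paste(moved$pos_a, moved$pos_b, moved$relation))
  expect_equal(base$distance, moved$distance[m], tolerance = 1e-6)
})

test_that("glycine never participates and infeasible plants error", {
  toy <- toy_structure()
  segmap <- small_segmap()
  pos <- unique(c(toy$ground_truth$pos_a, toy$ground_truth$pos_b, 150L))
  got <- detect_contacts(toy$model, pos, segmap, 50)  # huge cutoff
  expect_false(any(c(got$pos_a, got$pos_b) == 150L))
  expect_error(
    gen_structure(data.frame(pos_a = 1L, pos_b = 2L, distance = 4,
                             relation = "intra"),
                  setNames(c("G", "A"), c(1, 2))),
    "infeasible")
})

test_that("planted distances are realized and recovered through PDB io", {
  toy <- toy_structure()
  expect_true(all(abs(toy$ground_truth$realized - toy$ground_truth$distance) < 0.01))
  tmp <- tempfile(fileext = ".pdb")
  write_structure(toy$model, tmp)
  back <- read_structure(tmp)
  segmap <- small_segmap()
  pos <- unique(c(toy$ground_truth$pos_a, toy$ground_truth$pos_b))
  a <- detect_contacts(toy$model, pos, segmap, 5.0)
  b <- detect_contacts(back, pos, segmap, 5.0)
  expect_identical(contact_key(a), contact_key(b))
  expect_equal(a$distance, b$distance, tolerance = 2e-3)  # PDB has 3 decimals
})

test_that("altloc handling keeps the highest-occupancy conformer", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB AALA A   1       2.000   1.000   0.000  0.40  0.00           C",
    "ATOM      4  CB BALA A   1       9.000   9.000   9.000  0.60  0.00           C",
    "END"), tmp)
  m <- read_structure(tmp)
  cb <- m$atoms[m$atoms$elety == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$x, 9.0)  # occupancy 0.60 wins
})

test_that("contact categories follow the segment-pair rules", {
  expect_equal(classify_contact("S1", "S4", "intra"), "VSM activation")
  expect_equal(classify_contact("S4", "S1", "intra"), "VSM activation")
  expect_equal(classify_contact("P1", "P2", "intra"), "P-loop folding")
  expect_equal(classify_contact("S5", "P1", "intra"), "PM folding")
  expect_equal(classify_contact("S4", "S5", "inter"), "VSM-PM signal")
  expect_equal(classify_contact("S4-S5 linker", "S5", "inter"), "VSM-PM signal")
  expect_equal(classify_contact("S1", "S5", "inter"), "VSM-PM clamp")
  expect_equal(classify_contact("S5", "S6", "intra"), "activation gating")
  expect_equal(classify_contact("MHR1/2", "MHR3", "intra"), "unclassified")
  expect_equal(classify_contact("S1", "S4", "inter"), "unclassified")
})

test_that("contacts partition into regions with the spanning rule", {
  segmap <- read_segment_map()
  mk <- function(sa, sb, rel) {
    df <- data.frame(pos_a = 1L, segment_a = sa, chain_a = "A", pos_b = 2L,
                     segment_b = sb, chain_b = "A", distance = 4,
                     relation = rel, category = "unclassified",
                     vus_a = NA_character_, vus_b = NA_character_,
                     stringsAsFactors = FALSE)
    class(df) <- c("contact_set", "data.frame")
    df
  }
  p1 <- partition_by_region(mk("S5", "P1", "intra"), segmap)
  expect_equal(nrow(p1$transmembrane_extracellular), 1L)
  p2 <- partition_by_region(mk("MHR4", "TRP helix", "intra"), segmap)
  expect_equal(nrow(p2$cytoplasmic), 1L)
  # spanning: S5 (TM) with TRP helix (cytoplasmic) -> cytoplasmic, flagged
  p3 <- partition_by_region(mk("S5", "TRP helix", "intra"), segmap)
  expect_equal(nrow(p3$cytoplasmic), 1L)
  expect_true(p3$cytoplasmic$region_spanning)
  # pore-segment pairs stay transmembrane even if a map calls one cytoplasmic
  p4 <- partition_by_region(mk("S5", "S6", "intra"), segmap)
  expect_equal(nrow(p4$transmembrane_extracellular), 1L)
  empty <- detect_contacts(toy_structure()$model, 150L, small_segmap(), 5)
  p5 <- partition_by_region(empty, small_segmap())
  expect_equal(nrow(p5$transmembrane_extracellular), 0L)
  expect_equal(nrow(p5$cytoplasmic), 0L)
})

test_that("segment maps validate ranges and look up positions", {
  segmap <- read_segment_map()
  expect_equal(segment_of(segmap, c(790, 905, 966, 1113)),
               c("S1", "S4", "P1", "CTD"))
  expect_equal(region_of(segmap, "S4"), "transmembrane_extracellular")
  expect_equal(region_of(segmap, "MHR3"), "cytoplasmic")
  expect_true(is.na(segment_of(segmap, 815)))  # unannotated inter-segment gap
  expect_error(vustriage:::as_segment_map(data.frame(
    name = c("a", "b"), start = c(1L, 5L), end = c(10L, 20L),
    region = "cytoplasmic", stringsAsFactors = FALSE)), "overlap")
})
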