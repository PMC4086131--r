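test_that("site distance follows membership, Pythagoras and min-monotonicity", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0), c(30, 40, 0))
  s <- structure_from_xyz(xyz, seq_pos = c(1L, 2L, 3L))
  site <- new_site("ligand", 2)
  d <- site_distance(s, 1, site)
  expect_equal(d$distance, 5)
  expect_false(d$in_site)

  inside <- site_distance(s, 2, site)
  expect_equal(inside$distance, 0)
  expect_true(inside$in_site)

  # adding a farther site residue never increases the minimum
  wider <- new_site("ligand", c(2, 3))
  expect_lte(site_distance(s, 1, wider)$distance, d$distance)

  # variant residue absent from structure
  miss <- site_distance(s, 99, site)
  expect_true(miss$missing)
})

test_that("site distance equals the exhaustive all-pairs oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n_var <- sample(3:12, 1)
    n_site <- sample(5:40, 1)
    A <- matrix(stats::rnorm(n_var * 3, sd = 5), ncol = 3)
    B <- matrix(stats::rnorm(n_site * 3, mean = 4, sd = 5), ncol = 3)
    s <- structure_from_xyz(rbind(A, B),
                            seq_pos = c(rep(1L, n_var), rep(2L, n_site)))
    d <- site_distance(s, 1, new_site("ligand", 2))$distance
    expect_equal(d, oracle_min_dist(A, B), tolerance = 1e-12)
  }
})

test_that("binding-site extras pass through the best ligand site", {
  sites <- list(new_site("ligand", 1:3, confidence_a = 12,
                         confidence_b = 0.8),
                new_site("ligand", 2:4, confidence_a = 5,
                         confidence_b = 0.2),
                new_site("interface", 1:9, confidence_a = 99,
                         confidence_b = 99))
  hit <- binding_site_extras(1, sites)
  expect_true(hit$applicable)
  expect_equal(hit$confidence_a, 12)
  expect_equal(hit$confidence_b, 0.8)
  # in two ligand sites: the higher confidence_a wins
  both <- binding_site_extras(2, sites)
  expect_equal(both$confidence_a, 12)
  # outside all ligand sites (interface does not count)
  out <- binding_site_extras(9, sites)
  expect_false(out$applicable)
  expect_equal(out$confidence_a, MISSING_SENTINEL)
})

test_that("hydrogen-bond energy matches the literal formula", {
  expect_equal(hbond_energy(2.9, 3.5, 2.0, 3.4),
               0.084 * 332 * (1 / 2.9 + 1 / 3.5 - 1 / 2.0 - 1 / 3.4),
               tolerance = 1e-9)
  expect_equal(hbond_energy(2.9, 3.5, 2.0, 3.4), -4.561801,
               tolerance = 1e-6)
  # clash guard
  expect_lt(hbond_energy(0.1, 3, 3, 3), -5)
})

test_that("ideal helix is assigned H on interior residues", {
  h <- make_helix(15)
  ss <- assign_secondary_structure(h)
  expect_equal(ss$ss8[3:13], rep("H", 11))
  expect_equal(ss$ss3[3:13], rep("helix", 11))
  # chains shorter than 3 residues are unassigned
  tiny <- make_helix(6)
  tiny$atoms <- tiny$atoms[tiny$atoms$seq_pos <= 2, ]
  tiny <- new_structure(tiny$atoms)
  expect_true(all(assign_secondary_structure(tiny)$ss8 == "-"))
})

test_that("antiparallel strand pair is assigned E on paired residues", {
  sp <- make_strand_pair(6)
  ss <- assign_secondary_structure(sp)
  strand1 <- ss$ss8[ss$seq_pos %in% 2:5]
  strand2 <- ss$ss8[ss$seq_pos %in% 10:13]
  expect_true(all(strand1 == "E"))
  expect_true(all(strand2 == "E"))
  expect_true(all(ss$ss3[ss$ss8 == "E"] == "sheet"))
})

test_that("secondary-structure reduction is total and surjective", {
  codes <- c("H", "G", "I", "E", "B", "T", "S", "-")
  red <- reduce_ss(codes)
  expect_equal(red, c("helix", "helix", "helix", "sheet", "sheet",
                      "coil", "coil", "coil"))
  expect_setequal(unique(red), c("helix", "sheet", "coil"))
})

test_that("SASA matches the closed form and the Monte Carlo oracle", {
  # isolated atom: exact sphere area
  one <- structure_from_xyz(matrix(c(0, 0, 0), 1), seq_pos = 1L)
  res <- sasa(one, probe = 1.4, points = 960L)
  expect_equal(res$atoms$area, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.005)
  # two atoms far apart: no occlusion
  two <- structure_from_xyz(rbind(c(0, 0, 0), c(100, 0, 0)),
                            seq_pos = c(1L, 2L))
  res2 <- sasa(two)
  expect_equal(res2$atoms$area, rep(4 * pi * 3.1^2, 2), tolerance = 1e-9)
  # random 20-atom cluster vs high-resolution Monte Carlo oracle
  set.seed(33)
  xyz <- matrix(stats::rnorm(60, sd = 3), ncol = 3)
  cl <- structure_from_xyz(xyz, seq_pos = rep(1L, 20))
  impl <- sum(sasa(cl)$atoms$area)
  orac <- sum(oracle_sasa_mc(xyz, rep(1.7, 20), n_points = 100000L))
  expect_lt(abs(impl - orac) / orac, 0.03)
  # per-residue totals conserve the per-atom totals exactly
  h <- make_helix(10)
  sh <- sasa(h)
  expect_equal(sum(sh$residues$absolute_sasa), sum(sh$atoms$area))
  expect_true(all(sh$residues$relative_sasa >= 0 &
                    sh$residues$relative_sasa <= 1))
  # unknown element falls back with a warning
  odd <- structure_from_xyz(matrix(0, 1, 3), seq_pos = 1L, element = "Q")
  expect_warning(sasa(odd), "unknown element")
})

test_that("features are invariant under rigid-body motion", {
  h <- make_helix(12)
  rot <- rotation_matrix(c(1, 2, 3), 1.1)
  moved <- transform_structure(h, rot, c(10, -5, 2))
  ss_a <- assign_secondary_structure(h)
  ss_b <- assign_secondary_structure(moved)
  expect_identical(ss_a$ss8, ss_b$ss8)
  site <- new_site("ligand", 10:12)
  d_a <- site_distance(h, 2, site)$distance
  d_b <- site_distance(moved, 2, site)$distance
  expect_lt(abs(d_a - d_b), 1e-6)
  # SASA is re-sampled in the rotated frame; sample finely enough (3840
  # points) that quadrature noise sits below the 1% invariance tolerance
  sas_a <- sasa(h, points = 3840L)$residues$absolute_sasa
  sas_b <- sasa(moved, points = 3840L)$residues$absolute_sasa
  expect_lt(max(abs(sas_a - sas_b) / pmax(sas_a, 1)), 0.01)
})

test_that("the structural feature block composes with fixed schema", {
  # no structure: sentinels and indicator
  blk <- structural_feature_block(NULL, list(), 5)
  expect_equal(unname(blk["structure_missing"]), 1)
  expect_equal(unname(blk["ligand_distance"]), MISSING_SENTINEL)
  expect_equal(sum(blk[grep("^ss8_", names(blk))]), 0)

  # helix variant inside a ligand site
  h <- make_helix(15)
  sites <- list(new_site("ligand", 7:9, confidence_a = 4,
                         confidence_b = 0.5),
                new_site("interface", 1:2))
  blk2 <- structural_feature_block(h, sites, 8)
  expect_equal(unname(blk2["structure_missing"]), 0)
  expect_equal(unname(blk2["ligand_distance"]), 0)
  expect_equal(unname(blk2["binding_extra_a"]), 4)
  expect_equal(unname(blk2[c("ss3_helix", "ss3_sheet", "ss3_coil")]),
               c(1, 0, 0))
  expect_equal(sum(blk2[grep("^ss8_", names(blk2))]), 1)
  expect_gt(blk2["interface_distance"], 0)

  # fixed order, identical across variants
  blk3 <- structural_feature_block(h, sites, 14)
  expect_identical(names(blk2), names(blk3))
  expect_identical(names(blk2),
                   setdiff(feature_schema()$names,
                           c("jsd_conservation", "mass_ratio",
                             "charge_change", "functional_group_change")))
})

test_that("per-residue structural table exports sensible values", {
  h <- make_helix(10)
  sites <- list(new_site("ligand", 3:4))
  tab <- residue_structure_table(h, sites)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$ligand_distance[3], 0)
  expect_true(all(tab$relative_sasa >= 0 & tab$relative_sasa <= 1))
  expect_true(all(is.na(tab$interface_distance)))
})
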