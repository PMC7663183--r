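# SASA engine and structural descriptors.

test_that("isolated atom SASA matches the closed-form sphere area", {
  st <- fab_structure(data.frame(
    name = "X", element = "C", resname = "A", resno = 1, chain = "A",
    x = 0, y = 0, z = 0, radius = 1.5))
  s <- shrake_rupley(st, probe_radius = 1.4)
  expect_equal(s, 4 * pi * 2.9^2, tolerance = 0.01)
})

test_that("overlapping identical atoms share the pair total symmetrically", {
  st <- fab_structure(data.frame(
    name = c("X", "Y"), element = "C", resname = "A", resno = c(1, 2),
    chain = "A", x = c(0, 1), y = 0, z = 0, radius = 1.5))
  s <- shrake_rupley(st)
  # each atom gets half the total (up to lattice discretisation)
  expect_equal(s[1], s[2], tolerance = 0.01)
  expect_lt(s[1], 4 * pi * 2.9^2)              # and is partially buried
})

test_that("SASA converges: 960-point lattice within 2% of a 10x denser one", {
  st <- fixture_atom_cluster()
  lo <- shrake_rupley(st, n_sphere_points = 960)
  hi <- shrake_rupley(st, n_sphere_points = 9600)
  expect_equal(lo, hi, tolerance = 0.02)
  # and within 1% at the per-structure descriptor level vs 3840 points
  mid <- shrake_rupley(st, n_sphere_points = 3840)
  expect_equal(sum(lo), sum(mid), tolerance = 0.01)
})

test_that("RSA is clamped to [0,1] and near 1 for an extended Gly-X-Gly", {
  t3 <- make_toy_structure("GAG", "extended")
  surf <- residue_rsa(t3)
  expect_true(all(surf$rsa >= 0 & surf$rsa <= 1))
  # pseudo-radii reproduce MaxASA when isolated; 5 A spacing occludes little
  expect_gt(surf$rsa[2], 0.7)
  # fully buried residue: rsa 0 via zero-SASA atoms
  surf0 <- surf; surf0$sasa <- 0; surf0$rsa <- 0
  expect_equal(surf0$rsa, rep(0, 3))
})

test_that("NPR/PLR partition the alphabet and drive the SP descriptors", {
  expect_length(intersect(NPR_RESIDUES, PLR_RESIDUES), 0L)
  expect_setequal(c(NPR_RESIDUES, PLR_RESIDUES), fabqsar:::AA_LETTERS)

  surf <- data.frame(chain = "A", resno = 1:2, resname = c("A", "R"),
                     sasa = c(64.5, 274), rsa = c(0.5, 1.0),
                     kd = c(1.8, -4.5), polarity_class = c("NPR", "PLR"))
  rgA <- list(chain = "A", start = 0L, end = 1L)   # Ala only
  rgR <- list(chain = "A", start = 1L, end = 2L)   # Arg only
  rgAll <- list(chain = "A", start = 0L, end = 2L)
  expect_equal(sp_nonpolar(surf, rgA), 0.5 * 1.8)
  expect_equal(sp_polar(surf, rgA), 0)
  expect_equal(sp_polar(surf, rgR), 1.0 * -4.5)
  expect_equal(sp_nonpolar(surf, rgR), 0)
  # partition identity over the full region
  expect_equal(sp_polar(surf, rgAll) + sp_nonpolar(surf, rgAll),
               sum(surf$rsa * surf$kd))
  # linearity in RSA
  surf2 <- surf; surf2$rsa <- surf2$rsa * 2
  expect_equal(sp_nonpolar(surf2, rgA), 2 * sp_nonpolar(surf, rgA))
})

test_that("region SASA splits into polar + nonpolar and matches brute force", {
  fab <- fixture_fab(seed = 13)[[1]]
  ann <- annotate_fab(fab$heavy, fab$light)
  st <- make_fab_structure(fab)
  surf <- residue_rsa(st, n_sphere_points = 480)
  for (i in c(2, 6, 10)) {
    rg <- ann[i, ]
    all_s <- region_sasa(surf, rg, "all")
    expect_equal(region_sasa(surf, rg, "polar") +
                 region_sasa(surf, rg, "nonpolar"), all_s)
    # independent brute-force per-residue summation
    manual <- sum(surf$sasa[surf$chain == rg$chain &
                            surf$resno - 1 >= rg$start &
                            surf$resno - 1 < rg$end])
    expect_equal(all_s, manual)
  }
})

test_that("structural descriptors are invariant under rigid motion", {
  fab <- fixture_fab(seed = 17)[[1]]
  ann <- annotate_fab(fab$heavy, fab$light)
  st <- make_fab_structure(fab)
  moved <- rigid_move_structure(st)
  t1 <- build_struct_table(list(m = st), list(m = ann), "MD3D",
                           n_sphere_points = 480)
  t2 <- build_struct_table(list(m = moved), list(m = ann), "MD3D",
                           n_sphere_points = 480)
  expect_equal(unclass(t1), unclass(t2), tolerance = 1e-6)
})

test_that("struct table covers 28 regions x 5 surface descriptors minimum", {
  fab <- fixture_fab(seed = 19)[[1]]
  ann <- annotate_fab(fab$heavy, fab$light)
  st <- make_fab_structure(fab)
  tab <- build_struct_table(list(a = st), list(a = ann), "Hom3D",
                            n_sphere_points = 240)
  surf_cols <- grepl("\\.surf\\.", colnames(tab))
  expect_identical(sum(surf_cols), 28L * 5L)
  expect_identical(attr(tab, "provenance"), "Hom3D")
  # identical structures give identical rows; atom order is irrelevant
  perm <- st
  ord <- sample(nrow(perm$atoms))
  perm$atoms <- perm$atoms[ord, ]
  t2 <- build_struct_table(list(a = perm), list(a = ann), "Hom3D",
                           n_sphere_points = 240)
  expect_equal(unclass(tab), unclass(t2), tolerance = 1e-9)
})

test_that("PDB round trip preserves coordinates and descriptors", {
  fab <- fixture_fab(seed = 23)[[1]]
  st <- make_fab_structure(fab, geometry = "extended")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(st, path)
  back <- read_structure_pdb(path)
  expect_equal(nrow(back$atoms), nrow(st$atoms))
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(st$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_identical(back$atoms$resname, st$atoms$resname)
})
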