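# The 17-descriptor feature space.

cavityPockets <- function(seed = 17, lining = NULL) {
  args <- list(seed = seed)
  if (!is.null(lining)) args$lining <- lining
  spec <- do.call(cavitySpec, args)
  m <- makeCavityStructure(spec)
  cfg <- cavityDetectionConfig(spec, seed = seed)
  list(m = m, cfg = cfg, ps = detectPockets(m, cfg))
}

test_that("the descriptor vector has the 17 named fields", {
  fx <- cavityPockets()
  dt <- computeDescriptors(fx$ps, fx$m, config = fx$cfg)
  r <- descriptorRows(dt)
  expect_identical(setdiff(names(r), c("structure_id", "pocket_id")),
                   descriptorNames(extra = TRUE))
  expect_length(descriptorNames(extra = TRUE), 17)
  expect_length(descriptorNames(extra = FALSE), 16)
  d16 <- computeDescriptors(fx$ps, fx$m, config = fx$cfg, extra = FALSE)
  expect_false("n_apol_as" %in% names(descriptorRows(d16)))
})

test_that("descriptor invariants hold on computed pockets", {
  fx <- cavityPockets()
  r <- descriptorRows(computeDescriptors(fx$ps, fx$m, config = fx$cfg))
  expect_true(all(r$pock_vol > 0))
  expect_true(all(r$nb_AS >= 1))
  expect_equal(r$surf_pol_vdw + r$surf_apol_vdw, r$surf_vdw,
               tolerance = 1e-6)
  frac <- c("apol_as_prop", "prop_polar_atm", "mean_as_solv_acc")
  for (f in frac) expect_true(all(r[[f]] >= 0 & r[[f]] <= 1))
  expect_true(all(r$as_max_dst >= r$as_dens))
  expect_true(all(r$as_dens >= 0))
})

test_that("single-sphere and collinear pockets have closed-form geometry", {
  # a lone tetrahedron gives a 1-sphere pocket
  m <- pointStructure(tetrahedronCoords(5), resid = "LEU")
  ss <- computeAlphaSpheres(m, rMin = 3, rMax = 6)
  ps <- clusterPockets(ss, m, linkageDist = 2, minSpheres = 1)
  r <- descriptorRows(computeDescriptors(
    ps, m, config = detectionConfig(minSpheres = 1)))
  expect_equal(r$nb_AS, 1)
  expect_equal(r$as_dens, 0)
  expect_equal(r$as_max_dst, 0)
  expect_true(r$apol_as_prop %in% c(0, 1))

  # three collinear centers at 0, 3, 6: mean pair distance (3+3+6)/3
  fake <- new("PocketSet",
    spheres = data.frame(x = c(0, 3, 6), y = 0, z = 0, radius = 2,
                         a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L,
                         apolar = TRUE, pocket_id = 1L),
    summary = data.frame(pocket_id = 1L, n_spheres = 3L, cx = 3, cy = 0,
                         cz = 0),
    contactAtomList = list(1:4),
    contactResidueList = list(paste("A", 1:4, sep = ":")),
    structureId = "toy")
  r3 <- descriptorRows(computeDescriptors(fake, m,
                                          config = detectionConfig()))
  expect_equal(r3$as_max_dst, 6)
  expect_equal(r3$as_dens, 4)
})

test_that("Monte-Carlo volume matches closed forms", {
  # single sphere r = 3
  v1 <- pocketVolumeMC(matrix(0, 1, 3), 3, mcSamples = 1e5, seed = 2)
  expect_equal(v1, 4 / 3 * pi * 27, tolerance = 0.02)
  # two disjoint r = 2 spheres: volumes add
  v2 <- pocketVolumeMC(rbind(c(0, 0, 0), c(10, 0, 0)), c(2, 2),
                       mcSamples = 1e5, seed = 2)
  expect_equal(v2, 2 * 4 / 3 * pi * 8, tolerance = 0.03)
  # overlapping spheres: inclusion-exclusion with the lens volume
  v3 <- pocketVolumeMC(rbind(c(0, 0, 0), c(3, 0, 0)), c(3, 3),
                       mcSamples = 1e5, seed = 2)
  expect_equal(v3, twoSphereUnionVolume(3, 3, 3), tolerance = 0.02)
  # determinism
  expect_identical(v3, pocketVolumeMC(rbind(c(0, 0, 0), c(3, 0, 0)),
                                      c(3, 3), mcSamples = 1e5, seed = 2))
})

test_that("vdW surface areas split exactly and match the cap oracle", {
  mC <- pointStructure(matrix(0, 1, 3), element = "C")
  s1 <- vdwSurfaceAreas(mC, 1, nPoints = 2000, seed = 3)
  expect_equal(s1[["total"]], 4 * pi * 1.7^2, tolerance = 1e-9)
  expect_equal(s1[["apolar"]], s1[["total"]])
  expect_equal(s1[["polar"]], 0)

  mO <- pointStructure(matrix(0, 1, 3), element = "O")
  sO <- vdwSurfaceAreas(mO, 1, nPoints = 2000, seed = 3)
  expect_equal(sO[["polar"]], sO[["total"]])

  m2 <- pointStructure(rbind(c(0, 0, 0), c(1.7, 0, 0)), element = "C")
  s2 <- vdwSurfaceAreas(m2, 1:2, nPoints = 4000, seed = 3)
  expect_equal(s2[["total"]], twoSphereExposedArea(1.7, 1.7),
               tolerance = 0.03)
  expect_equal(s2[["polar"]] + s2[["apolar"]], s2[["total"]])

  mX <- pointStructure(matrix(0, 1, 3), element = "XX")
  expect_error(vdwSurfaceAreas(mX, 1), "XX")
})

test_that("descriptors transform correctly under coordinate scaling", {
  spec <- cavitySpec(seed = 23)
  m <- makeCavityStructure(spec)
  cfg <- cavityDetectionConfig(spec)
  ps <- detectPockets(m, cfg)
  r <- descriptorRows(computeDescriptors(ps, m, config = cfg))[1, ]

  k <- 2
  a2 <- atoms(m)
  a2[, c("x", "y", "z")] <- a2[, c("x", "y", "z")] * k
  m2 <- StructureModel(a2, sourceId = "scaled", modelKind = "predicted")
  cfg2 <- cfg
  cfg2$rMin <- cfg$rMin * k; cfg2$rMax <- cfg$rMax * k
  cfg2$linkageDist <- cfg$linkageDist * k
  cfg2$mergeDist <- cfg$mergeDist * k
  ps2 <- detectPockets(m2, cfg2)
  r2 <- descriptorRows(computeDescriptors(ps2, m2, config = cfg2))[1, ]

  expect_equal(r2$nb_AS, r$nb_AS)
  expect_equal(r2$as_dens, r$as_dens * k, tolerance = 1e-9)
  expect_equal(r2$as_max_dst, r$as_max_dst * k, tolerance = 1e-9)
  expect_equal(r2$pock_vol, r$pock_vol * k^3, tolerance = 0.05)
  expect_equal(r2$apol_as_prop, r$apol_as_prop)
  expect_equal(r2$hydrophobicity_score, r$hydrophobicity_score)
  expect_equal(r2$volume_score, r$volume_score)
  expect_equal(r2$polarity_score, r$polarity_score)
  expect_equal(r2$charge_score, r$charge_score)
})

test_that("hydrophobic linings outscore acidic/basic linings", {
  hyd <- cavityPockets(seed = 29, lining = c(ILE = 1, LEU = 1, PHE = 1))
  pol <- cavityPockets(seed = 29, lining = c(ASP = 1, LYS = 1))
  rh <- descriptorRows(computeDescriptors(hyd$ps, hyd$m, config = hyd$cfg))
  rp <- descriptorRows(computeDescriptors(pol$ps, pol$m, config = pol$cfg))
  expect_gt(rh$hydrophobicity_score[1], rp$hydrophobicity_score[1])
})

test_that("a fixed seed gives bit-identical descriptor vectors", {
  fx <- cavityPockets(seed = 31)
  d1 <- computeDescriptors(fx$ps, fx$m, config = fx$cfg)
  d2 <- computeDescriptors(fx$ps, fx$m, config = fx$cfg)
  expect_identical(descriptorRows(d1), descriptorRows(d2))
})

test_that("descriptor tables round-trip through TSV", {
  tab <- quickTable(n = c(LBP = 5, PP = 10), seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDescriptorTable(tab, path)
  back <- readDescriptorTable(path)
  expect_equal(descriptorRows(back)$hydrophobicity_score,
               descriptorRows(tab)$hydrophobicity_score)
  expect_equal(classCounts(back), classCounts(tab))
})
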