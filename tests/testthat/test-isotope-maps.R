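test_that("ratio maps divide channels and mask low denominators", {
  m <- matrix(rpois(64, 30) + 1L, 8, 8)
  acc <- make_test_acc(`34S` = m, `32S` = m)
  r <- ratio_map(acc, "34S", "32S")
  expect_true(all(r$values == 1))

  den <- m; den[1, 1] <- 0L
  acc2 <- make_test_acc(`34S` = m, `32S` = den)
  r2 <- ratio_map(acc2, "34S", "32S")
  expect_false(r2$mask[1, 1])
  expect_true(is.na(r2$values[1, 1]))
  expect_true(all(is.finite(r2$values[r2$mask])))
})

test_that("mean sulfur ratio is the ratio of sums", {
  s32 <- matrix(20L, 6, 6)
  acc <- make_test_acc(`34S` = s32 / 20L, `32S` = s32)  # exact 5% everywhere
  expect_equal(mean_sulfur_ratio(acc), 0.05)

  set.seed(9)
  s32 <- matrix(rpois(100, 200), 10, 10)
  s34 <- matrix(rpois(100, 9), 10, 10)
  acc <- make_test_acc(`34S` = s34, `32S` = s32)
  ## explicit-iteration oracle
  num <- 0; den <- 0
  for (i in 1:10) for (j in 1:10) { num <- num + s34[i, j]; den <- den + s32[i, j] }
  expect_equal(mean_sulfur_ratio(acc), num / den)
  ## mean-of-ratios is a different statistic on heteroscedastic images
  expect_false(isTRUE(all.equal(mean_sulfur_ratio(acc),
                                mean_sulfur_ratio(acc, "mean-of-ratios"))))

  acc0 <- make_test_acc(`34S` = s34, `32S` = matrix(0L, 10, 10))
  expect_error(mean_sulfur_ratio(acc0), "zero total")
})

test_that("excess-34S map vanishes exactly at the average ratio", {
  s32 <- matrix(20L * (1:16), 4, 4)
  s34 <- s32 / 20L            # exactly ratio 0.05 everywhere
  cc <- matrix(100L, 4, 4)
  acc <- make_test_acc(`34S` = s34, `32S` = s32, `13C12C` = cc)
  mol <- molecule_label_spec("ASO", n_s34_labels = 15L)
  m <- aso_signal_map(acc, mol, ratio_ave = 0.05)
  expect_true(all(m$values == 0))
})

test_that("ASO map scales as 1/N_labels and keeps negative values", {
  set.seed(31)
  acc <- make_test_acc(`34S` = matrix(rpois(64, 5), 8, 8),
                       `32S` = matrix(rpois(64, 100), 8, 8),
                       `13C12C` = matrix(rpois(64, 50) + 1L, 8, 8))
  maps <- lapply(c(1L, 15L, 19L), function(n)
    aso_signal_map(acc, molecule_label_spec("x", n_s34_labels = n),
                   ratio_ave = CDT_S34_S32))
  expect_equal(maps[[2]]$values, maps[[1]]$values / 15)
  expect_equal(maps[[3]]$values, maps[[1]]$values / 19)
  ## sampling below the average abundance must stay negative, not clipped
  acc_neg <- make_test_acc(`34S` = matrix(0L, 4, 4),
                           `32S` = matrix(100L, 4, 4),
                           `13C12C` = matrix(10L, 4, 4))
  m <- aso_signal_map(acc_neg, molecule_label_spec("x", 15L), ratio_ave = 0.045)
  expect_true(all(m$values < 0))
})

test_that("low carbon pixels are masked, not fabricated", {
  cc <- matrix(5L, 4, 4); cc[2, 2] <- 0L
  acc <- make_test_acc(`34S` = matrix(1L, 4, 4), `32S` = matrix(10L, 4, 4),
                       `13C12C` = cc, `127I` = matrix(2L, 4, 4))
  a <- aso_signal_map(acc, molecule_label_spec("x", 15L), ratio_ave = 0.045)
  l <- ligand_signal_map(acc, molecule_label_spec("x", 0L, 2L))
  expect_false(a$mask[2, 2]); expect_false(l$mask[2, 2])
  expect_equal(sum(!a$mask), 1L)
})

test_that("ligand map is the per-label 127I/carbon ratio", {
  acc <- make_test_acc(`127I` = matrix(0L, 4, 4), `13C12C` = matrix(10L, 4, 4))
  mol2 <- molecule_label_spec("eGLP1", 0L, 2L)
  expect_true(all(ligand_signal_map(acc, mol2)$values == 0))

  set.seed(12)
  i127 <- matrix(rpois(16, 8), 4, 4)
  acc <- make_test_acc(`127I` = i127, `13C12C` = matrix(10L, 4, 4))
  m1 <- ligand_signal_map(acc, molecule_label_spec("x", 0L, 1L))
  m2 <- ligand_signal_map(acc, mol2)
  expect_equal(m2$values, m1$values / 2)
  expect_true(all(m2$values >= 0))
  expect_error(ligand_signal_map(acc, molecule_label_spec("x", 15L, 0L)),
               "n_i127_labels")
})

test_that("per-molecule signal gain arithmetic", {
  expect_equal(per_molecule_signal_gain(15, 19), 100 * 4 / 15)
  expect_equal(round(per_molecule_signal_gain(15, 19)), 27)
  expect_equal(per_molecule_signal_gain(15, 15), 0)
  expect_equal(per_molecule_signal_gain(10, 25), 150)
  expect_error(per_molecule_signal_gain(0, 5), ">= 1")
})

test_that("unlabelled simulations recover the natural abundance ratio", {
  p <- tiny_params(endosome_conc_uM = 0, n_planes = 8L, seed = 101)
  acc <- accumulate(simulate_stack(make_scene(p)))
  tot32 <- sum(channel_image(acc, "32S"))
  expect_gt(tot32, 1e6)
  r <- mean_sulfur_ratio(acc)
  ## binomial error on a ratio of sums
  se <- sqrt(p$natural_s34_ratio / tot32)
  expect_lt(abs(r - p$natural_s34_ratio), 3 * se)
})

test_that("signal maps round-trip through the TIFF + sidecar export", {
  set.seed(44)
  acc <- make_test_acc(`34S` = matrix(rpois(256, 10), 16, 16),
                       `32S` = matrix(rpois(256, 200), 16, 16),
                       `13C12C` = matrix(rpois(256, 50), 16, 16))
  m <- aso_signal_map(acc, molecule_label_spec("x", 15L), ratio_ave = CDT_S34_S32)
  path <- file.path(withr::local_tempdir(), "map.tif")
  write_signal_map(m, path)
  r <- read_signal_map(path)
  expect_identical(r$mask, m$mask)
  expect_equal(r$values[r$mask], m$values[m$mask], tolerance = 1e-6)
  expect_equal(r$kind, "ASO")
})
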