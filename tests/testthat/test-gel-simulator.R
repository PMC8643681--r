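test_that("topoisomer sampling is Gaussian over integers and seeded", {
  p <- ptptk2()
  d <- sample_topoisomers(p, center_writhe = -17, spread = 0.01,
                          n_molecules = 1000, seed = 1)
  expect_equal(nrow(d$entries), 1L)
  expect_equal(d$entries$writhe_native, -17)
  expect_equal(d$entries$abundance, 1000)

  d1 <- sample_topoisomers(p, 0, 1.5, 1e4, seed = 99)
  d2 <- sample_topoisomers(p, 0, 1.5, 1e4, seed = 99)
  expect_identical(d1, d2)
  expect_equal(sum(d1$entries$abundance), 1e4)

  # empirical mean within 3 standard errors of the centre
  big <- sample_topoisomers(p, 0, 1.5, 1e5, seed = 7)
  m <- with(big$entries, sum(writhe_native * abundance) / sum(abundance))
  expect_lt(abs(m), 3 * 1.5 / sqrt(1e5))
})

test_that("sampling rejects invalid populations", {
  p <- ptptk2()
  expect_error(sample_topoisomers(p, 0, 1.5, 0, seed = 1), "n_molecules")
  expect_error(sample_topoisomers(p, 0, 0, 10, seed = 1), "spread")
})

test_that("chloroquine coefficient calibration and its round trip", {
  p <- ptptk2()
  u <- calibrate_chloroquine_coefficient(19, 1.5, p)
  expect_equal(u, 19 / (1.5 * 5455), tolerance = 1e-12)
  expect_equal(u, 2.322e-3, tolerance = 1e-3)
  expect_equal(calibrate_chloroquine_coefficient(0, 1.5, p), 0)
  expect_error(calibrate_chloroquine_coefficient(19, 0, p),
               "concentration")
  # the calibrated coefficient adds back exactly +19 supercoils
  gel <- gel_conditions(chloroquine_dim1_ug_ml = 1.5)
  params <- correction_parameters(chloroquine_unwinding = u)
  expect_equal(
    effective_writhe(0, p, gel, growth_temp_C = 24, params = params),
    19)
})

test_that("effective writhe chains the temperature and intercalator shifts", {
  p <- ptptk2()
  gel <- gel_conditions(temperature_C = 24, chloroquine_dim1_ug_ml = 1.5)
  expect_equal(effective_writhe(5, p, gel, growth_temp_C = 85), 14)
  expect_equal(effective_writhe(-17, p, gel, growth_temp_C = 85), -8)
  no_chl_same_temp <- gel_conditions(temperature_C = 85,
                                     chloroquine_dim1_ug_ml = 0)
  w <- -10:10
  expect_equal(effective_writhe(w, p, no_chl_same_temp, growth_temp_C = 85),
               w)
  # affine in native writhe
  a <- effective_writhe(w, p, gel, growth_temp_C = 85)
  expect_equal(diff(a), rep(1, length(w) - 1))
})

test_that("migration is saturating, monotone in |effective writhe|", {
  gel <- gel_conditions(mobility_saturation_wr = 30, max_position = 100)
  expect_equal(migrate(0, gel), 0)
  expect_equal(migrate(30, gel), 100)
  expect_equal(migrate(-45, gel), 100)
  set.seed(2)
  for (i in 1:50) {
    ab <- sort(runif(2, 0, 30))
    if (ab[1] == ab[2]) next
    expect_lt(migrate(sample(c(-1, 1), 1) * ab[1], gel),
              migrate(sample(c(-1, 1), 1) * ab[2], gel))
  }
})

test_that("1D rendering conserves band area and is seeded-deterministic", {
  p <- ptptk2()
  d <- sample_topoisomers(p, -17, 1.5, 5000, seed = 3)
  gel <- gel_conditions(temperature_C = 24, chloroquine_dim1_ug_ml = 1.5,
                        noise_sd = 0, seed = 5)
  prof <- render_gel(d, gel, growth_temp_C = 85, mode = "1D")
  dx <- diff(prof$position[1:2])
  area <- (sum(prof$intensity) -
             (prof$intensity[1] + prof$intensity[nrow(prof)]) / 2) * dx
  expect_equal(area, sum(d$entries$abundance), tolerance = 1e-6)

  prof2 <- render_gel(d, gel, growth_temp_C = 85, mode = "1D")
  expect_identical(prof, prof2)

  noisy <- gel_conditions(temperature_C = 24, chloroquine_dim1_ug_ml = 1.5,
                          noise_sd = 0.5, seed = 5)
  n1 <- render_gel(d, noisy, growth_temp_C = 85, mode = "1D")
  n2 <- render_gel(d, noisy, growth_temp_C = 85, mode = "1D")
  expect_identical(n1, n2)
})

test_that("a single topoisomer renders one band at its migration position", {
  p <- ptptk2()
  d <- sample_topoisomers(p, -17, 0.01, 1000, seed = 1)
  gel <- gel_conditions(temperature_C = 85, chloroquine_dim1_ug_ml = 0)
  prof <- render_gel(d, gel, growth_temp_C = 85, mode = "1D")
  expect_equal(prof$position[which.max(prof$intensity)],
               migrate(-17, gel), tolerance = 0.1)
})

test_that("2D rendering separates opposite-sign topoisomers into mirror arcs", {
  p <- ptptk2()
  # symmetric population around 0; chloroquine only in dimension 2
  d <- sample_topoisomers(p, 0, 2, 1e5, seed = 13)
  gel <- gel_conditions(temperature_C = 85, chloroquine_dim1_ug_ml = 0,
                        chloroquine_dim2_ug_ml = 0.5,
                        mobility_saturation_wr = 60)
  tab <- render_gel(d, gel, growth_temp_C = 85, mode = "2D")
  y_of <- function(w) tab$dimension2_position[tab$true_writhe == w]
  x_of <- function(w) tab$dimension1_position[tab$true_writhe == w]
  shift <- round(19 / (1.5 * 5455) * 0.5 * 5455) # dim-2 chloroquine supercoils
  for (k in 1:4) {
    if (length(y_of(k)) == 0 || length(y_of(-k)) == 0) next
    expect_equal(x_of(k), x_of(-k), tolerance = 1e-12)
    if (k < shift) {
      expect_equal(y_of(k) + y_of(-k), 2 * y_of(0), tolerance = 1e-9)
      expect_false(isTRUE(all.equal(y_of(k), y_of(-k))))
    }
  }
})

test_that("nicked molecules form a zero-mobility reference band", {
  p <- ptptk2()
  d <- sample_topoisomers(p, -10, 1, 1000, seed = 1, nicked_fraction = 0.2)
  gel <- gel_conditions(temperature_C = 85, chloroquine_dim1_ug_ml = 0)
  tab <- render_gel(d, gel, growth_temp_C = 85, mode = "2D")
  nicked <- tab[is.na(tab$true_writhe), ]
  expect_equal(nrow(nicked), 1L)
  expect_equal(nicked$dimension1_position, 0)
  expect_equal(nicked$intensity, 1000 * 0.2 / 0.8, tolerance = 1e-9)
})
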