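# Synthetic phantom generator: density model, truth record, XRF and rater
# simulators.

test_that("sound phantom: lesion band is voxel-identical to the mirrored normal band", {
  ph <- generate_phantom(tiny_spec(lesion_class = "sound", noise_sd = 0))
  b <- paleoenamel:::phantom_bands(ph$truth$spec)
  expect_identical(ph$volume$values[, b$lesion, ],
                   ph$volume$values[, rev(b$normal), ])
})

test_that("hypomineralised phantom carries the programmed mid-enamel deficit", {
  ph <- generate_phantom(tiny_spec(deficit_mid = 0.07, noise_sd = 0))
  b <- paleoenamel:::phantom_bands(ph$truth$spec)
  nx <- dim(ph$volume)[3]
  mid <- (nx + 1) / 2  # u = 0.5 voxel (odd nx by construction)
  lesion_mid <- ph$volume$values[1, b$lesion[1], mid]
  normal_mid <- ph$volume$values[1, b$normal[1], mid]
  expect_equal(lesion_mid, 0.93 * normal_mid)
  # deficit field is exactly deficit_mid at u = 0.5 inside the lesion
  expect_equal(ph$truth$deficit_field[1, b$lesion[1], mid], 0.07)
  expect_true(all(ph$truth$deficit_field[, -b$lesion, ] == 0))
})

test_that("noiseless profiles are strictly monotone in the documented directions", {
  ph <- generate_phantom(tiny_spec(deficit_mid = 0.07, noise_sd = 0))
  b <- paleoenamel:::phantom_bands(ph$truth$spec)
  normal_line <- ph$volume$values[1, b$normal[1], ]   # DEJ (x=1) -> surface
  lesion_line <- ph$volume$values[1, b$lesion[1], ]
  expect_true(all(diff(normal_line) > 0))
  expect_true(all(diff(lesion_line) < 0))
  expect_true(all(lesion_line < normal_line))
})

test_that("taphonomic staining leaves the density unchanged", {
  ph <- generate_phantom(tiny_spec(lesion_class = "taphonomic_stain",
                                   noise_sd = 200, seed = 4))
  b <- paleoenamel:::phantom_bands(ph$truth$spec)
  m_lesion <- mean(ph$volume$values[, b$lesion, ])
  m_normal <- mean(ph$volume$values[, b$normal, ])
  expect_lt(abs(m_lesion - m_normal), 0.1 * 200)
  expect_true(all(ph$truth$deficit_field == 0))
})

test_that("acid dissolution affects only the outer shell", {
  ph <- generate_phantom(tiny_spec(lesion_class = "acid_dissolution",
                                   deficit_mid = 0.1, noise_sd = 0,
                                   dissolution_depth_fraction = 0.25))
  b <- paleoenamel:::phantom_bands(ph$truth$spec)
  nx <- dim(ph$volume)[3]
  u <- (seq_len(nx) - 1) / (nx - 1)
  deficit_line <- ph$truth$deficit_field[1, b$lesion[1], ]
  expect_true(all(deficit_line[u <= 0.75] == 0))
  expect_true(all(abs(deficit_line[u > 0.75 + 1e-9] - 0.1) < 1e-12))
})

test_that("phantom generation is deterministic and leaves global RNG alone", {
  s <- tiny_spec(noise_sd = 300, seed = 42)
  set.seed(777); before <- .Random.seed
  a <- generate_phantom(s)
  expect_identical(.Random.seed, before)
  b <- generate_phantom(s)
  expect_identical(a$volume$values, b$volume$values)
})

test_that("degenerate geometry is rejected with the minimum named", {
  expect_error(phantom_spec(enamel_thickness = 200), "245")
  expect_error(phantom_spec(deficit_mid = 0.6), "0.5")
  expect_error(phantom_spec(dej_grey = 100, surface_grey = 90), "rises")
})

test_that("simulate_xrf honours its mean/multiplier contract", {
  truth <- list(element_multipliers = c(Mn = 1, Fe = 1, Cu = 1, Pb = 1))
  tab0 <- simulate_xrf(truth, cv = 0, seed = 1)
  dc <- tab0$value[tab0$condition == "DC"]
  no <- tab0$value[tab0$condition == "NO"]
  expect_equal(dc, no)  # no contamination, no noise -> identical
  # Monte-Carlo: Mn multiplier 10, cv 0.1, 10 000 repeats
  truth10 <- list(element_multipliers = c(Mn = 10, Fe = 1, Cu = 1, Pb = 1))
  tab <- simulate_xrf(truth10, cv = 0.1, n_repeats = 10000, seed = 2)
  mn <- tab[tab$element == "Mn", ]
  ratio <- mean(mn$value[mn$condition == "DC"]) / mean(mn$value[mn$condition == "NO"])
  expect_lt(abs(ratio - 10) / 10, 0.05)
  # determinism
  expect_identical(simulate_xrf(truth10, cv = 0.3, seed = 7),
                   simulate_xrf(truth10, cv = 0.3, seed = 7))
})

test_that("simulate_xrf validates elements and repeats", {
  truth <- list(element_multipliers = c(Mn = 1, Au = 2))
  expect_error(simulate_xrf(truth), "Mn, Fe, Cu, Pb")
  good <- list(element_multipliers = c(Mn = 1))
  expect_error(simulate_xrf(good, n_repeats = 1), "at least 2")
  expect_error(simulate_xrf(good, baseline = c(Mn = 1, Fe = 1, Cu = 1, Pb = 0)),
               "positive")
})

test_that("rater simulation: perfect agreement, chance agreement, determinism", {
  categories <- c("yes", "no", "unsure")
  ident <- diag(3); rownames(ident) <- categories
  model <- rater_model(n_raters = 19, confusion = ident, seed = 3)
  ratings <- simulate_ratings(c("yes", "no", "unsure", "yes"), model)
  expect_true(all(rowSums(ratings) == 19))
  expect_true(all(apply(ratings, 1, max) == 19))  # unanimity per item
  expect_equal(fleiss_kappa(ratings)$kappa, 1)
  # uniform confusion: kappa ~ 0 at 500 items
  unif <- matrix(1 / 3, 1, 3, dimnames = list("any", NULL))
  m500 <- rater_model(n_raters = 19, confusion = unif, seed = 5)
  r500 <- simulate_ratings(rep("any", 500), m500)
  expect_lt(abs(fleiss_kappa(r500)$kappa), 0.05)
  # determinism, and input validation
  expect_identical(simulate_ratings(rep("any", 10), m500),
                   simulate_ratings(rep("any", 10), m500))
  expect_error(simulate_ratings("any", m500), "at least 2 items")
})
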