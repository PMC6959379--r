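test_that("component models carry the canonical centers and structure", {
  cm <- default_component_model("C1s")
  expect_equal(nrow(cm), 10)
  expect_equal(sum(cm$kind == "gaussian_pi"), 7)
  expect_equal(cm$center[cm$kind == "gaussian_pi"],
               c(284.3, 285.3, 286.0, 286.6, 287.4, 288.4, 289.3))
  nm <- default_component_model("N1s")
  expect_equal(nm$center[nm$kind == "gaussian_pi"],
               c(398.8, 400, 401.4, 402.7, 405.4))
  # nitrate-N lies above the 403.2 eV step yet is classified pi* by kind
  expect_equal(nm$kind[nm$center == 405.4], "gaussian_pi")
  for (m in list(cm, nm)) {
    expect_equal(sum(m$kind == "edge_step"), 1)
    expect_true(all(m$fwhm[m$kind == "gaussian_pi"] == 1.2))
  }
  expect_error(default_component_model("K1s"))
})

test_that("edge-jump normalization pins pre-edge to 0 and post-edge to 1", {
  g <- gen_nexafs_spectrum(nexafs_truth("C1s", c("carboxyl-C" = 1),
                                        edge_jump_height = 2.5, seed = 1))
  s <- normalize_edge_jump(g$spectrum)
  pre <- s$axis >= 275 & s$axis <= 282
  post <- s$axis >= 310 & s$axis <= 320
  expect_equal(mean(s$intensity[pre]), 0, tolerance = 1e-12)
  expect_equal(mean(s$intensity[post]), 1, tolerance = 1e-12)
  # the applied scale equals the generated step height (sigma tails are
  # negligible at the window edges but not exactly zero)
  expect_equal(s$meta$normalization$jump, 2.5, tolerance = 0.02)
  # idempotence
  s2 <- normalize_edge_jump(s)
  expect_equal(s2$intensity, s$intensity, tolerance = 1e-12)
})

test_that("normalization is affine-equivariant: normalize(a*s + b) == normalize(s)", {
  g <- gen_nexafs_spectrum(nexafs_truth("C1s", c("aromatic-C" = 0.5,
                                                 "carboxyl-C" = 0.5),
                                        noise_sd = 0.01, seed = 4))
  s <- g$spectrum
  for (ab in list(c(2, 0), c(0.3, 5), c(7, -1))) {
    scaled <- spectrum(s$axis, ab[1] * s$intensity + ab[2],
                       axis_kind = s$axis_kind, meta = s$meta)
    expect_equal(normalize_edge_jump(scaled)$intensity,
                 normalize_edge_jump(s)$intensity, tolerance = 1e-10)
  }
  # inverted spectrum rejected
  inv <- spectrum(s$axis, -s$intensity, axis_kind = s$axis_kind,
                  meta = s$meta)
  expect_error(normalize_edge_jump(inv), "inverted")
})

test_that("fit recovers noise-free ground truth within 0.01 per component", {
  ab <- c("carboxyl-C" = 0.5, "aromatic-C" = 0.3, "O-alkyl-C" = 0.2)
  g <- gen_nexafs_spectrum(nexafs_truth("C1s", ab, noise_sd = 0, seed = 1))
  fit <- fit_spectrum(normalize_edge_jump(g$spectrum),
                      default_component_model("C1s"))
  expect_true(fit$converged)
  rec <- relative_pi_abundances(fit)
  expect_true(all(abs(rec[names(ab)] - ab) < 0.01))
  expect_true(all(abs(rec[setdiff(names(rec), names(ab))]) < 0.01))
  expect_equal(sum(rec), 1, tolerance = 1e-6)
})

test_that("a single pi* component yields relative abundance 1", {
  g <- gen_nexafs_spectrum(nexafs_truth("N1s", c("amidic-N" = 1), seed = 2))
  fit <- fit_spectrum(normalize_edge_jump(g$spectrum),
                      default_component_model("N1s"))
  expect_equal(unname(relative_pi_abundances(fit)[["amidic-N"]]), 1,
               tolerance = 1e-3)
})

test_that("relative pi* abundances ignore sigma/step and input scaling", {
  # handcrafted fit: equal pi* areas give 1/3 each regardless of sigma area
  model <- default_component_model("C1s")
  mk_fit <- function(sigma_area) {
    areas <- setNames(rep(0, sum(model$kind != "edge_step")),
                      model$label[model$kind != "edge_step"])
    areas[c("aromatic-C", "carboxyl-C", "O-alkyl-C")] <- 5
    areas[c("sigma1", "sigma2")] <- sigma_area
    structure(list(areas = areas, model = model), class = "nexafs_fit")
  }
  r1 <- relative_pi_abundances(mk_fit(1))
  r2 <- relative_pi_abundances(mk_fit(100))
  expect_equal(r1, r2)
  expect_equal(unname(r1[c("aromatic-C", "carboxyl-C", "O-alkyl-C")]),
               rep(1 / 3, 3))
  f0 <- mk_fit(1)
  f0$areas[] <- 0
  expect_error(relative_pi_abundances(f0), "pi\\* signal")

  # global intensity rescaling of the spectrum leaves fractions unchanged
  g <- gen_nexafs_spectrum(nexafs_truth("C1s", c("carboxyl-C" = 0.6,
                                                 "phenolic-C" = 0.4),
                                        noise_sd = 0.005, seed = 11))
  s <- g$spectrum
  s7 <- spectrum(s$axis, 7 * s$intensity, axis_kind = s$axis_kind,
                 meta = s$meta)
  f1 <- fit_spectrum(normalize_edge_jump(s), model)
  f7 <- fit_spectrum(normalize_edge_jump(s7), model)
  expect_equal(relative_pi_abundances(f1), relative_pi_abundances(f7),
               tolerance = 1e-6)
})

test_that("optimizer matches a brute-force amplitude grid on a 2-component toy", {
  toy <- toy_two_gauss(a1 = 0.8, a2 = 0.4)
  s <- normalize_edge_jump(toy$spectrum)
  # brute force: profile RSS over the two pi* amplitudes with the true step
  # fixed; grid step 0.001 on the amplitudes
  g1 <- exp(-(toy$x - 285.3)^2 / (2 * (1.2 / (2 * sqrt(2 * log(2))))^2))
  g2 <- exp(-(toy$x - 288.4)^2 / (2 * (1.2 / (2 * sqrt(2 * log(2))))^2))
  resid0 <- s$intensity - edge_step_height_curve(toy$x)
  grid <- seq(0, 1.2, by = 0.001)
  # RSS(a1, a2) expanded: quadratic in the amplitudes
  G11 <- sum(g1^2); G22 <- sum(g2^2); G12 <- sum(g1 * g2)
  b1 <- sum(resid0 * g1); b2 <- sum(resid0 * g2)
  rss <- outer(grid, grid, function(a1, a2) {
    -2 * a1 * b1 - 2 * a2 * b2 + a1^2 * G11 + a2^2 * G22 + 2 * a1 * a2 * G12
  })
  best <- which(rss == min(rss), arr.ind = TRUE)[1, ]
  brute <- c(grid[best[1]], grid[best[2]])

  fit <- fit_spectrum(s, toy$model)
  sig <- 1.2 / (2 * sqrt(2 * log(2)))
  opt <- c(fit$areas[["substituted-aromatic-C"]],
           fit$areas[["carboxyl-C"]]) / (sig * sqrt(2 * pi))
  expect_equal(opt, brute, tolerance = 2e-3)
  expect_equal(brute, c(0.8, 0.4), tolerance = 2e-3)
})

test_that("fit rejects degenerate inputs", {
  x <- seq(275, 320, by = 0.5)
  zero <- spectrum(x, rep(0, length(x)), "energy_eV")
  expect_error(fit_spectrum(zero, default_component_model("C1s")),
               "all-zero")
  # axis starting above the first pi* center (284.3 eV) cannot host the model
  short <- spectrum(seq(286, 320, by = 0.5),
                    rep(1, 69), "energy_eV")
  expect_error(fit_spectrum(short, default_component_model("C1s")),
               "axis range")
})
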