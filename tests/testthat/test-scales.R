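test_that("shipped scales have 20 residues and the expected orientation", {
  for (nm in c("MZ", "KD")) {
    s <- load_scale(nm)
    expect_length(s$values, 20L)
    expect_setequal(names(s$values), hydrolevels:::AA_CODES)
    expect_true(all(is.finite(s$values)))
    expect_true(s$hydrophobic_is_max)
  }
  # KD: isoleucine is the most hydrophobic, arginine the least
  kd <- load_scale("KD")
  expect_identical(names(which.max(kd$values)), "I")
  expect_identical(names(which.min(kd$values)), "R")
  # MZ exponents: lysine smallest, hydrophobics (C, V, I) at the top
  mz <- load_scale("MZ")
  expect_identical(names(which.min(mz$values)), "K")
  expect_true(all(mz$values[c("C", "V", "I")] > mz$values[c("K", "E", "D")]))
  expect_error(load_scale("XX"), "unknown scale")
})

test_that("rescale is affine, flips orientation on negative slope, and is equivariant", {
  s <- load_scale("KD")
  expect_equal(rescale(s, 1, 0)$values, s$values)
  expect_false(rescale(s, -1, 0)$hydrophobic_is_max)
  expect_error(rescale(s, 0, 1), "nonzero")
  s2 <- rescale(s, 2, 1)
  expect_equal(unname(s2$values), unname(2 * s$values + 1))

  # level deviation of a fixed peak set scales by exactly |a|
  set.seed(11)
  rec <- seq_record("r1", random_protein(80))
  f1 <- levelfit(rec, scale = s, window = 5, k = 3, min_separation = 3)
  f2 <- levelfit(rec, scale = s2, window = 5, k = 3, min_separation = 3)
  expect_equal(f2$stat$deviation, 2 * f1$stat$deviation, tolerance = 1e-12)
  expect_equal(f2$peaks$peaks$position, f1$peaks$peaks$position)
})

test_that("custom scales load from two-column text files", {
  path <- tempfile(fileext = ".txt")
  v <- load_scale("KD")$values
  writeLines(c("# test scale", paste(names(v), v)), path)
  s <- read_scale(path, name = "copy")
  expect_equal(s$values, v)
  # missing residues rejected
  writeLines(paste(names(v)[1:19], v[1:19]), path)
  expect_error(read_scale(path), "20 standard")
})

test_that("fit_psi_exponent recovers exact power laws and the flat case", {
  L <- seq(3, 45, 2)
  for (psi in seq(0, 1, by = 0.1)) {
    fit <- fit_psi_exponent(data.frame(L = L, sasa = 100 * L^(-psi)))
    expect_equal(fit$psi, psi, tolerance = 1e-10)
    expect_equal(fit$intercept, log(100), tolerance = 1e-10)
  }
  flat <- fit_psi_exponent(data.frame(L = L, sasa = rep(55, length(L))))
  expect_equal(flat$psi, 0, tolerance = 1e-12)
})

test_that("fit_psi_exponent matches a hand-coded least-squares oracle on noisy data", {
  set.seed(42)
  L <- seq(9, 35, 2)
  sasa <- 80 * L^(-0.35) * exp(rnorm(length(L), 0, 0.05))
  fit <- fit_psi_exponent(data.frame(L = L, sasa = sasa))
  ora <- oracle_slope_intercept(log(L), log(sasa))
  expect_equal(fit$psi, -unname(ora["slope"]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(ora["intercept"]), tolerance = 1e-12)
  # psi within the fit's own confidence interval of the truth
  se <- summary(fit$lm)$coefficients[2, 2]
  expect_lt(abs(fit$psi - 0.35), 3 * se)
})

test_that("fit_psi_exponent honours the fitting range and rejects bad tables", {
  L <- seq(3, 45, 2)
  # exponent differs inside and outside [9, 35]; only the inside counts
  sasa <- ifelse(L >= 9 & L <= 35, 100 * L^(-0.4), 100 * L^(-0.9))
  fit <- fit_psi_exponent(data.frame(L = L, sasa = sasa))
  expect_equal(fit$psi, 0.4, tolerance = 1e-10)
  expect_error(fit_psi_exponent(data.frame(L = c(9, 11), sasa = c(1, 1))),
               "at least 3 rows")
  expect_error(fit_psi_exponent(data.frame(L = seq(9, 21, 2),
                                           sasa = c(-1, 1, 1, 1, 1, 1, 1))),
               "positive")
  expect_error(fit_psi_exponent(data.frame(L = c(8, 10, 12),
                                           sasa = c(1, 1, 1))),
               "odd")
})

test_that("scaling all sasa by a positive constant only shifts the intercept", {
  L <- seq(9, 35, 2)
  set.seed(5)
  sasa <- 60 * L^(-0.22) * exp(rnorm(length(L), 0, 0.03))
  f1 <- fit_psi_exponent(data.frame(L = L, sasa = sasa))
  f2 <- fit_psi_exponent(data.frame(L = L, sasa = 7.5 * sasa))
  expect_equal(f1$psi, f2$psi, tolerance = 1e-12)
  expect_equal(f2$intercept - f1$intercept, log(7.5), tolerance = 1e-10)
})

test_that("a full scale can be fitted from a multi-residue SASA table", {
  mz <- load_scale("MZ")
  L <- seq(9, 35, 2)
  tab <- do.call(rbind, lapply(names(mz$values), function(aa)
    data.frame(residue = aa, L = L, sasa = 200 * L^(-mz$values[[aa]]))))
  fitted <- fit_psi_scale(tab, name = "refit")
  expect_equal(fitted$values, mz$values, tolerance = 1e-8)

  # TSV round trip through read_sasa_table
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  tab2 <- read_sasa_table(path)
  expect_equal(fit_psi_scale(tab2)$values, mz$values, tolerance = 1e-8)
})

test_that("unknown residues follow the configured policy", {
  rec <- seq_record("u1", "AAAAXAAAA")
  expect_error(compute_profile(rec, "KD", 3), "position")
  p <- compute_profile(rec, "KD", 1, na_action = "impute")
  expect_equal(p$values[5], mean(load_scale("KD")$values))
})
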