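# FPRs, Gaussian white-noise perturbation, pooled statistics, closed forms.

test_that("FPRs are l over the intergenic distance", {
  m <- hoxFixture("mouse_hoxd")
  fpr <- computeFPR(m, l = 100)
  expect_equal(fpr@factors[8], 100 / 6, tolerance = 1e-12)  # 12-13 segment
  expect_equal(fpr@factors, 100 / distancesKbp(m))
  # product reconstructs l for every segment
  expect_equal(fpr@factors * distancesKbp(m), rep(100, 8))

  a <- computeFPR(hoxFixture("amphioxus"), l = 100)
  expect_equal(a@factors[9], 1)            # 9-10 segment, d = 100
  expect_equal(computeFPR(HoxCluster("t", 1:2, 50), l = 50)@factors, 1)
  expect_error(computeFPR(m, l = 0), "> 0")
})

test_that("zero noise reproduces the ideal body plan exactly, any model", {
  m <- hoxFixture("mouse_hoxd")
  fpr <- computeFPR(m)
  for (model in c("additive-mean-relative", "additive-absolute",
                  "multiplicative", "brownian")) {
    ps <- perturbAndRealize(fpr, m, NoiseSpec(model, 0, 10, seed = 1))
    expect_true(all(ps@lengths == 100))
    st <- segmentStats(ps)
    expect_equal(st$pooled_mean, 100)
    expect_equal(st$pooled_variance, 0)
  }
})

test_that("identical seeds give bit-identical realizations", {
  m <- hoxFixture("amphioxus")
  fpr <- computeFPR(m)
  ns <- NoiseSpec(level = 0.05, realizations = 50, seed = 123)
  p1 <- perturbAndRealize(fpr, m, ns)
  p2 <- perturbAndRealize(fpr, m, ns)
  expect_identical(p1@lengths, p2@lengths)
  p3 <- perturbAndRealize(fpr, m, NoiseSpec(level = 0.05, realizations = 50,
                                            seed = 124))
  expect_false(identical(p1@lengths, p3@lengths))
})

test_that("unknown noise models are rejected", {
  expect_error(NoiseSpec("pink", 0.05), "must be one of")
  m <- hoxFixture("mouse_hoxd")
  ns <- NoiseSpec(level = 0.05)
  ns@model <- "pink"   # bypass constructor validation
  expect_error(perturbAndRealize(computeFPR(m), m, ns), "unknown noise model")
  expect_error(theoreticalVariance(m, 100, ns), "unknown noise model")
})

test_that("segment statistics pool over all R x n values", {
  ps <- new("PerturbedSegments",
            lengths = matrix(c(1, 2, 3, 4, 5, 6), nrow = 2),
            idealLength = 100, noise = NoiseSpec())
  st <- segmentStats(ps)
  expect_equal(st$pooled_mean, 3.5)
  expect_equal(st$pooled_variance, oraclePopVar(1:6))
  expect_equal(st$n_values, 6L)
  # constant matrix
  psc <- new("PerturbedSegments", lengths = matrix(7, 3, 4),
             idealLength = 100, noise = NoiseSpec())
  expect_equal(segmentStats(psc)$pooled_variance, 0)
})

test_that("single-segment additive-absolute variance matches eps^2 d^2", {
  d <- 12
  cl <- HoxCluster("seg", 1:2, d)
  eps <- 0.05
  ns <- NoiseSpec("additive-absolute", eps, 20000L, seed = 5)
  st <- segmentStats(perturbAndRealize(computeFPR(cl), cl, ns))
  se <- oraclePooledVarSE(d, 100, "additive-absolute", eps, 20000L)
  expect_lt(abs(st$pooled_variance - eps^2 * d^2), 3 * se)
})

test_that("theoreticalVariance equals the first-principles closed forms", {
  for (nm in c("mouse_hoxd", "amphioxus", "amphioxus_modified")) {
    cl <- hoxFixture(nm)
    d <- distancesKbp(cl)
    for (model in c("additive-mean-relative", "additive-absolute",
                    "multiplicative", "brownian")) {
      expect_equal(theoreticalVariance(cl, 100, NoiseSpec(model, 0.05)),
                   oraclePooledVar(d, 100, model, 0.05), tolerance = 1e-12)
    }
  }
  # additive-absolute on the compact fixture: eps^2 * mean(d^2)
  expect_equal(theoreticalVariance(hoxFixture("mouse_hoxd"), 100,
                                   NoiseSpec("additive-absolute", 0.1)),
               0.1^2 * 181.75, tolerance = 1e-12)
  # multiplicative is blind to the distance geometry
  expect_equal(theoreticalVariance(hoxFixture("mouse_hoxd"), 100,
                                   NoiseSpec("multiplicative", 0.05)),
               theoreticalVariance(hoxFixture("amphioxus"), 100,
                                   NoiseSpec("multiplicative", 0.05)))
  # zero level, zero variance
  expect_equal(theoreticalVariance(hoxFixture("amphioxus"), 100,
                                   NoiseSpec(level = 0)), 0)
})

test_that("negative perturbed lengths are retained with a warning", {
  cl <- HoxCluster("wild", 1:2, 100)
  ns <- NoiseSpec("multiplicative", 2, 200L, seed = 9)
  expect_warning(ps <- perturbAndRealize(computeFPR(cl), cl, ns),
                 "negative perturbed")
  expect_true(any(ps@lengths < 0))
})

test_that("compareOrganisms ranks variances and is order-independent", {
  cls <- list(hoxFixture("mouse_hoxd"), hoxFixture("amphioxus"),
              hoxFixture("amphioxus_modified"))
  ns <- NoiseSpec(level = 0.05, realizations = 250, seed = 31)
  df <- suppressWarnings(compareOrganisms(cls, noise = ns))
  expect_equal(df$variance_rank, 1:3)
  df2 <- suppressWarnings(compareOrganisms(rev(cls), noise = ns))
  expect_equal(df2$pooled_variance[match(df$organism, df2$organism)],
               df$pooled_variance)
  # a cluster compared with itself has equal theoretical variances
  twin <- suppressWarnings(
    compareOrganisms(list(cls[[1]], cls[[1]]), noise = ns))
  expect_equal(twin$theoretical_variance[1], twin$theoretical_variance[2])
  expect_error(compareOrganisms(cls[1]), "at least 2")
})

test_that("equal mean squared distance gives equal additive-absolute variance", {
  c1 <- HoxCluster("flat", 1:3, c(10, 10))
  c2 <- HoxCluster("spread", 1:3, c(sqrt(200 - 64), 8))  # mean(d^2) = 100
  ns <- NoiseSpec("additive-absolute", 0.05)
  expect_equal(theoreticalVariance(c1, 100, ns),
               theoreticalVariance(c2, 100, ns), tolerance = 1e-12)
})

test_that("Monte-Carlo variance converges to the closed form (all models, all fixtures)", {
  R <- 10000L
  for (nm in c("mouse_hoxd", "amphioxus", "amphioxus_modified")) {
    cl <- hoxFixture(nm)
    d <- distancesKbp(cl)
    fpr <- computeFPR(cl)
    for (model in c("additive-mean-relative", "additive-absolute",
                    "multiplicative", "brownian")) {
      ns <- NoiseSpec(model, 0.05, R, seed = 77)
      st <- segmentStats(suppressWarnings(perturbAndRealize(fpr, cl, ns)))
      expected <- oraclePooledVar(d, 100, model, 0.05)
      se <- oraclePooledVarSE(d, 100, model, 0.05, R)
      expect_lt(abs(st$pooled_variance - expected), 3 * se)
      seMean <- oraclePooledMeanSE(d, 100, model, 0.05, R)
      expect_lt(abs(st$pooled_mean - 100), 3 * seMean)
    }
  }
})
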