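# Morphogen gradient, thresholds/domains, force, extrusion, activation,
# and the collinearity regression surface.

test_that("morphogen gradient peaks at the posterior end and is monotone", {
  fld <- MorphogenField(axisLength = 10, decayLambda = 3, peakValue = 2)
  expect_equal(morphogenAt(fld, 10), 2)
  xs <- seq(0, 10, length.out = 50)
  expect_true(all(diff(morphogenAt(fld, xs)) > 0))
  # flat-gradient limit
  flat <- MorphogenField(10, 1e9, 2)
  expect_equal(morphogenAt(flat, c(0, 5, 10)), rep(2, 3), tolerance = 1e-7)
  expect_error(morphogenAt(fld, 11), "within")
  expect_error(morphogenAt(fld, -0.1), "within")
})

test_that("expression domains are nested and share the posterior end", {
  fld <- MorphogenField()
  sch <- defaultSchedule(fld, 6)
  doms <- t(sapply(1:6, function(k) expressionDomain(fld, sch, k)))
  expect_true(all(diff(doms[, "anterior"]) >= 0))
  expect_true(all(doms[, "posterior"] == fld@axisLength))
  # lowest threshold = concentration at the anterior end -> whole axis
  expect_equal(unname(doms[1, "anterior"]), 0, tolerance = 1e-9)
  # threshold above the peak -> empty domain
  sch2 <- ThresholdSchedule(c(0.5, 1.5), 1:2)
  expect_true(all(is.na(expressionDomain(fld, sch2, 2))))
  expect_error(expressionDomain(fld, sch, 7), "out of range")
  # nesting holds across random parameterizations
  set.seed(11)
  for (i in 1:20) {
    f <- MorphogenField(runif(1, 1, 20), runif(1, 0.5, 10), runif(1, 0.5, 5))
    s <- defaultSchedule(f, sample(2:12, 1))
    ants <- sapply(seq_along(s@thresholds),
                   function(k) expressionDomain(f, s, k)["anterior"])
    expect_false(is.unsorted(ants))
  }
})

test_that("the pulling force is P * N with linear accumulation", {
  m <- hoxFixture("mouse_hoxd")
  fld <- MorphogenField()
  ch <- ChargeModel(m, alpha = 2, kappaN = 1)
  expect_equal(ch@N, 94)
  expect_equal(pullForce(ch, fld, 10, 0), 0)          # ground state
  expect_error(pullForce(ch, fld, 10, -1), ">= 0")
  # linear in N: doubling the span doubles F
  big <- HoxCluster("double", 1:2, 188)
  expect_equal(pullForce(ChargeModel(big, alpha = 2), fld, 5, 3),
               2 * pullForce(ch, fld, 5, 3))
  # posterior cells feel a stronger force at equal time
  expect_gt(pullForce(ch, fld, 9, 2), pullForce(ch, fld, 3, 2))
  # linear in t
  expect_equal(pullForce(ch, fld, 7, 4), 2 * pullForce(ch, fld, 7, 2))
})

test_that("extrusion is a work balance against the stiffness profile", {
  expect_equal(extrusionLength(0, uniformProfile(1)), 0)
  expect_equal(extrusionLength(10, uniformProfile(1)), 10)
  expect_equal(extrusionLength(10, uniformProfile(2)), 5)
  # piecewise: work 10 over [0,10) at s=1, then s=4
  p <- ElasticityProfile(10, c(1, 4))
  expect_equal(extrusionLength(18, p), 12)
  expect_equal(extrusionLength(10, p), 10)
  expect_equal(extrusionLength(4, p), 4)
  # removing the 5' anchor lowers resistance: E doubles at rho = 0.5
  expect_equal(extrusionLength(10, uniformProfile(1), FALSE, 0.5), 20)
  expect_error(extrusionLength(10, uniformProfile(1), FALSE, 1.2),
               "in \\(0, 1\\)")
  expect_error(extrusionLength(-1, uniformProfile(1)), ">= 0")
})

test_that("extrusion matches the Riemann oracle and is monotone in force", {
  Fs <- seq(0, 150, by = 3.7)
  for (seed in 1:12) {
    prof <- generateProfile(6, "lognormal", seed = seed, dispersion = 0.8)
    Es <- extrusionLength(Fs, prof)
    expect_true(all(diff(Es) >= 0))
    for (F in c(7.3, 55, 120))
      expect_equal(extrusionLength(F, prof), oracleExtrusion(F, prof),
                   tolerance = 0.01)
    # anchor removal never decreases E
    expect_true(all(extrusionLength(Fs, prof, FALSE, 0.7) >= Es))
  }
})

test_that("activation needs extrusion and peaks at the factory", {
  k <- ActivationKernel(tfOffset = 5, width = 20, peakIntensity = 2)
  expect_equal(activationIntensity(-3, k), 0)   # still inside the CT
  expect_equal(activationIntensity(0, k), 0)
  expect_equal(activationIntensity(5, k), 2)    # at the factory
  expect_lt(activationIntensity(18, k), 2)      # moved off the factory
  expect_equal(activationIntensity(30, k), 0)   # beyond the kernel support
  expect_true(all(diff(activationIntensity(seq(5, 25, 1), k)) < 0))
  # default kernel: factory at the CT/ICD border, strictly decreasing
  kd <- ActivationKernel()
  d <- activationIntensity(c(1, 10, 50, 150), kd)
  expect_true(all(diff(d) < 0))
})

test_that("simulated expression composes force, extrusion and activation", {
  m <- hoxFixture("mouse_hoxd")
  parts <- defaultSimParts(m)
  # ground state: no force, nothing expressed
  st0 <- simulateExpression(m, parts$field, parts$schedule, parts$charges,
                            parts$profile, parts$kernel, x = 5, t = 0)
  expect_equal(unname(intensities(st0)), rep(0, 9))
  # early time, anterior cell: only the most anterior gene is out
  stA <- simulateExpression(m, parts$field, parts$schedule, parts$charges,
                            parts$profile, parts$kernel, x = 1, t = 0.5)
  on <- which(intensities(stA) > 0)
  expect_equal(unname(on), 1L)
  # late time, posterior cell: all genes out, most posterior strongest
  stP <- simulateExpression(m, parts$field, parts$schedule, parts$charges,
                            parts$profile, parts$kernel, x = 10, t = 1.2)
  iv <- intensities(stP)
  expect_true(all(iv > 0))
  expect_equal(unname(which.max(iv)), 9L)
})

test_that("posterior cells activate every gene no later than anterior cells", {
  m <- hoxFixture("mouse_hoxd")
  parts <- defaultSimParts(m)
  firstT <- function(x) {
    ts <- seq(0, 3, length.out = 121)
    sapply(seq_len(nGenes(m)), function(g) {
      for (t in ts) {
        st <- simulateExpression(m, parts$field, parts$schedule,
                                 parts$charges, parts$profile, parts$kernel,
                                 x = x, t = t)
        if (intensities(st)[g] > 0) return(t)
      }
      Inf
    })
  }
  expect_true(all(firstT(9) <= firstT(4)))
})

test_that("wild-type simulation passes all three collinearity checks", {
  m <- hoxFixture("mouse_hoxd")
  parts <- defaultSimParts(m)
  rep <- collinearityReport(m, parts$field, parts$schedule, parts$charges,
                            parts$profile, parts$kernel)
  expect_true(rep$spatial)
  expect_true(rep$temporal)
  expect_true(rep$quantitative)
  expect_true(rep$all_pass)
  expect_false(is.unsorted(rep$boundaries))
  expect_false(is.unsorted(rep$first_times))
  expect_error(collinearityReport(m, parts$field, parts$schedule,
                                  parts$charges, parts$profile, parts$kernel,
                                  nx = 1), "degenerate grid")
})

test_that("an inverted kernel is flagged by the quantitative check", {
  m <- hoxFixture("mouse_hoxd")
  parts <- defaultSimParts(m)
  # peak deep inside the ICD: anterior genes sit nearer the peak than the
  # most recently extruded gene, breaking quantitative collinearity
  bad <- ActivationKernel(tfOffset = 80, width = 300)
  rep <- collinearityReport(m, parts$field, parts$schedule, parts$charges,
                            parts$profile, bad)
  expect_false(rep$quantitative)
  expect_false(rep$all_pass)
  expect_true(!is.null(rep$witness))
})

test_that("a single-gene cluster passes vacuously", {
  solo <- HoxCluster("solo", 5L, numeric(0))
  fld <- MorphogenField()
  rep <- collinearityReport(solo, fld, ThresholdSchedule(0.5, 1),
                            new("ChargeModel", alpha = 1, kappaN = 1, N = 10),
                            uniformProfile(), ActivationKernel())
  expect_true(rep$all_pass)
})
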