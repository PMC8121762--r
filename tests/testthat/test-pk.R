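# One-compartment simulation, fitting, NCA, bioavailability and
# steady-state planning.

test_that("closed forms honour the boundary values", {
  expect_equal(pk_simulate(list(ke = 0.05, V = 0.2), 1, "iv", 0), 5)
  expect_equal(pk_simulate(list(ke = 0.05, V = 0.2, ka = 0.25, F = 1),
                           1, "sc", 0), 0)
})

test_that("the ka == ke limiting form is continuous", {
  tt <- c(1, 5, 20, 60)
  exact <- pk_simulate(list(ke = 0.05, V = 0.2, ka = 0.05, F = 0.8),
                       1, "sc", tt)
  near <- pk_simulate(list(ke = 0.05, V = 0.2, ka = 0.05 * (1 + 1e-7),
                           F = 0.8), 1, "sc", tt)
  expect_equal(exact, near, tolerance = 1e-5)
})

test_that("closed forms match numerical integration of the two-state ODE", {
  skip_if_not_installed("deSolve")
  set.seed(51)
  for (i in 1:10) {
    ke <- runif(1, 0.005, 0.1); ka <- ke * runif(1, 1.5, 10)
    V <- runif(1, 0.05, 1); Fb <- runif(1, 0.2, 1); D <- runif(1, 0.5, 5)
    tt <- seq(0, 120, by = 5)
    rhs <- function(t, y, p)
      list(c(-p$ka * y[1], p$ka * y[1] / p$V - p$ke * y[2]))
    sol <- deSolve::ode(c(A = Fb * D, C = 0), tt, rhs,
                        list(ka = ka, ke = ke, V = V),
                        rtol = 1e-10, atol = 1e-12)
    got <- pk_simulate(list(ke = ke, V = V, ka = ka, F = Fb), D, "sc", tt)
    expect_equal(got[-1], sol[-1, "C"], tolerance = 1e-6,
                 ignore_attr = TRUE)
    sol_iv <- D / V * exp(-ke * tt)
    expect_equal(pk_simulate(list(ke = ke, V = V), D, "iv", tt), sol_iv)
  }
})

test_that("fitting noise-free data recovers the generating parameters", {
  tt <- c(2, 5, 10, 15, 30, 45, 60, 90)
  iv <- pk_dataset(tt, pk_simulate(list(ke = 0.04, V = 0.25), 1, "iv", tt),
                   "iv", 1)
  f <- pk_fit(iv)
  expect_equal(f$ke, 0.04, tolerance = 1e-6)
  expect_equal(f$V_over_F, 0.25, tolerance = 1e-6)

  sc <- pk_dataset(tt, pk_simulate(list(ke = 0.02, V = 0.3, ka = 0.1, F = 1),
                                   1, "sc", tt), "sc", 1)
  g <- pk_fit(sc)
  expect_equal(g$ke, 0.02, tolerance = 1e-5)
  expect_equal(g$ka, 0.1, tolerance = 1e-5)
  expect_equal(g$V_over_F, 0.3, tolerance = 1e-5)
})

test_that("flip-flop inputs are reported with the ka > ke labelling", {
  tt <- c(2, 5, 10, 15, 30, 45, 60, 90)
  # generate with ka < ke: same curve as the swapped labelling
  sc <- pk_dataset(tt, pk_simulate(list(ke = 0.1, V = 0.3, ka = 0.02, F = 1),
                                   1, "sc", tt), "sc", 1)
  f <- suppressWarnings(pk_fit(sc))
  expect_gt(f$ka, f$ke)
  expect_equal(sort(c(f$ka, f$ke)), c(0.02, 0.1), tolerance = 1e-4)
  expect_equal(predict(f), sc$concentrations, tolerance = 1e-5)
})

test_that("half-life and clearance identities hold exactly", {
  cfg <- synthetic_config(seed = 3)
  f <- suppressWarnings(pk_fit(generate_pk(cfg, "Gast p59-79")$sc))
  expect_identical(f$t_half * f$ke, log(2))
  expect_equal(f$CL_over_F, f$ke * f$V_over_F, tolerance = 1e-12)
})

test_that("seeded noisy subcutaneous data recover the half-life within 15%", {
  cfg <- synthetic_config(seed = 2)
  pk <- generate_pk(cfg, "Gast p59-79")
  f <- suppressWarnings(pk_fit(pk$sc))
  expect_lt(abs(f$t_half - 18.1) / 18.1, 0.15)
})

test_that("median recovered half-life over 100 noisy replicates is within 5%", {
  cfg <- synthetic_config(seed = 8)
  th <- vapply(1:100, function(r)
    suppressWarnings(pk_fit(generate_pk(cfg, "Gast p59-79",
                                        replicate = r)$sc)$t_half), 0)
  expect_lt(abs(stats::median(th) - 18.1) / 18.1, 0.05)
})

test_that("fitting errors on insufficient data", {
  expect_error(pk_fit(pk_dataset(c(1, 2, 3), c(5, 0, 0), "iv", 1)),
               "at least 3")
})

test_that("NCA AUC handles rectangles, exponentials and zeros", {
  expect_equal(nca_auc(pk_dataset(c(0, 4), c(3, 3), "iv", 1))$auc_0_last, 12)

  ke <- 0.03; V <- 0.2
  tt <- seq(0, 240, by = 2)
  dense <- pk_dataset(tt, pk_simulate(list(ke = ke, V = V), 1, "iv", tt),
                      "iv", 1)
  a <- nca_auc(dense)
  expect_equal(a$auc_0_inf, 1 / (V * ke), tolerance = 0.01)
  expect_equal(a$lambda_z, ke, tolerance = 1e-6)

  zeros <- pk_dataset(c(0, 10, 20), c(0, 0, 0), "iv", 1)
  z <- nca_auc(zeros)
  expect_equal(z$auc_0_last, 0)
  expect_true(is.na(z$auc_0_inf))
})

test_that("NCA AUC converges to the model AUC with sampling density", {
  ke <- 0.02; V <- 0.3; ka <- 0.1; Tmax <- 300
  # closed-form integral of the absorption curve over [0, Tmax]
  truth <- ka / (V * (ka - ke)) *
    ((1 - exp(-ke * Tmax)) / ke - (1 - exp(-ka * Tmax)) / ka)
  errs <- vapply(c(10, 40, 160), function(n) {
    tt <- seq(0, Tmax, length.out = n)
    ds <- pk_dataset(tt, pk_simulate(list(ke = ke, V = V, ka = ka, F = 1),
                                     1, "sc", tt), "sc", 1)
    abs(nca_auc(ds)$auc_0_last - truth) / truth
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("bioavailability is the dose-normalised AUC ratio", {
  tt <- c(2, 5, 10, 15, 30, 45, 60, 90)
  iv <- pk_dataset(tt, pk_simulate(list(ke = 0.04, V = 0.2), 1, "iv", tt),
                   "iv", 1)
  iv2 <- pk_dataset(tt, pk_simulate(list(ke = 0.04, V = 0.2), 2, "iv", tt),
                    "iv", 2)
  expect_equal(bioavailability(iv, iv2)$F, 1, tolerance = 1e-9)

  cfg0 <- synthetic_config(seed = 4, noise_cv = 0)
  pk <- generate_pk(cfg0, "ChgA p435-462a")  # generated with F = 0.5
  f <- bioavailability(pk$iv, pk$sc)
  expect_lt(abs(f$F - 0.5) / 0.5, 0.10)

  none <- pk_dataset(tt, rep(0, 8), "sc", 1)
  expect_equal(bioavailability(iv, none)$F, 0)
  expect_error(bioavailability(none, iv), "undefined")
})

test_that("steady-state rates scale linearly and convert units correctly", {
  cfg <- synthetic_config(seed = 5)
  f <- suppressWarnings(pk_fit(generate_pk(cfg, "ChgA p435-462a")$sc))
  expect_equal(steady_state_rate(0, f), 0)
  r1 <- steady_state_rate(1, f)
  expect_equal(steady_state_rate(2, f), 2 * r1, tolerance = 1e-12)
  expect_equal(r1, 1 * f$CL_over_F * 1440, tolerance = 1e-12)

  # mass-unit branch: independent unit-conversion arithmetic
  set.seed(52)
  for (i in 1:20) {
    css <- runif(1, 0.1, 10); mw <- runif(1, 1000, 5000)
    cl <- runif(1, 1e-4, 1e-1)
    g <- f
    g$CL_over_F <- cl
    g$data$unit <- "ng/mL"
    expected <- css * mw * 1e-9 * 1e6 * cl * 1440  # nmol/L -> ng/mL, then /min -> /day
    expect_equal(steady_state_rate(css, g, mw = mw), expected,
                 tolerance = 1e-9)
  }
  g <- f; g$data$unit <- "ng/mL"; g$data$mw <- NA
  expect_error(steady_state_rate(1, g), "molecular weight")
})

test_that("the pk_fit object supports the standard model methods", {
  cfg <- synthetic_config(seed = 6)
  f <- suppressWarnings(pk_fit(generate_pk(cfg, "Gast p59-79")$sc))
  expect_named(coef(f), c("ke", "ka", "V_over_F"))
  expect_output(print(f), "t1/2")
  expect_output(print(summary(f)), "observations")
  expect_length(predict(f, c(10, 20)), 2L)
  r <- residuals(f)
  expect_length(r, length(f$data$times))
  expect_lt(max(abs(r), na.rm = TRUE), 1)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(length(f$data$times), 3L))
  expect_true(all(sims > 0))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})

test_that("PK datasets round-trip through TSV", {
  cfg <- synthetic_config(seed = 7)
  pk <- generate_pk(cfg, "Gast p59-79")
  path <- tempfile(fileext = ".tsv")
  write_pk_dataset(pk$sc, path)
  back <- read_pk_dataset(path)
  expect_equal(back$concentrations, pk$sc$concentrations, tolerance = 1e-6)
  expect_equal(back$route, "sc")
  expect_equal(back$dose, 1)
})
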