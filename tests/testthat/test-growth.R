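test_that("the growth curve has the asymptotic form and its limits", {
  g <- growth_params(female_h_inf_cm = 260, female_k_per_yr = 0.15,
                     female_t0_yr = -2)
  expect_equal(height_at_age(0, "female", g), 260 * (1 - exp(-0.3)))
  expect_lt(abs(height_at_age(1000, "female", g) - 260), 1e-10)
  # ages at or before the curve root give zero height
  g2 <- growth_params(female_h_inf_cm = 260, female_k_per_yr = 0.15,
                      female_t0_yr = 2)
  expect_equal(height_at_age(2, "female", g2), 0)
  expect_error(height_at_age(-1, "female", g), "non-negative")
  expect_error(growth_params(female_k_per_yr = -0.1))
})

test_that("height is strictly increasing in age and bounded by the asymptote", {
  g <- growth_params()
  a <- sort(runif(100, 0, 80))
  for (sex in c("male", "female")) {
    h <- height_at_age(a, sex, g)
    expect_true(all(diff(h) > 0))
    expect_true(all(h < g[[sex]]["h_inf"]))
  }
})

test_that("forward-inverse composition is the identity below the plateau", {
  set.seed(42)
  for (i in 1:200) {
    g <- growth_params(female_h_inf_cm = runif(1, 150, 350),
                       female_k_per_yr = runif(1, 0.05, 0.4),
                       female_t0_yr = runif(1, -6, 0))
    age <- runif(1, 0, 60)
    h <- height_at_age(age, "female", g)
    if (h < 0.95 * g$female["h_inf"] && h > 0) {
      est <- age_at_height(h, "female", g)
      expect_equal(est$qualifier, "point")
      expect_lt(abs(est$age_years - age), 1e-9)
    }
  }
})

test_that("heights near or above the asymptote are censored as minimum ages", {
  g <- growth_params()
  for (h in c(0.951 * 260, 260, 300)) {
    est <- age_at_height(h, "female", g)
    expect_equal(est$qualifier, "minimum")
    expect_equal(est$age_years, -5.1 - log(0.05) / 0.072)
  }
  expect_error(age_at_height(-5, "female", g), "positive")
})

test_that("heights below the newborn height clamp to age 0 as a maximum", {
  g <- growth_params()
  h0 <- height_at_age(0, "female", g)
  est <- age_at_height(h0 - 5, "female", g)
  expect_equal(est$age_years, 0)
  expect_equal(est$qualifier, "maximum")
})

test_that("a lifespan cap censors old ages as maxima", {
  g <- growth_params()
  h <- height_at_age(30, "female", g)
  est <- age_at_height(h, "female", g, max_age_years = 20)
  expect_equal(est$age_years, 20)
  expect_equal(est$qualifier, "maximum")
})

test_that("age at a height is monotone in height below the plateau", {
  g <- growth_params()
  h <- seq(85, 0.94 * 260, length.out = 50)
  a <- age_at_height(h, "female", g)$age_years
  expect_true(all(diff(a) > 0))
})

test_that("a taller asymptote reaches the same height younger", {
  tall <- growth_params(male_h_inf_cm = 330, male_k_per_yr = 0.1,
                        male_t0_yr = -3,
                        female_h_inf_cm = 260, female_k_per_yr = 0.1,
                        female_t0_yr = -3)
  h <- seq(90, 0.9 * 260, length.out = 20)
  am <- age_at_height(h, "male", tall)$age_years
  af <- age_at_height(h, "female", tall)$age_years
  expect_true(all(am <= af))
})

test_that("curve fitting recovers noiseless parameters to 1e-6 relative", {
  a <- seq(0, 45, length.out = 40)
  truth <- c(h_inf = 260, k = 0.15, t0 = -2)
  d <- data.frame(age = a,
                  height = 260 * (1 - exp(-0.15 * (a + 2))))
  fit <- fit_growth_curve(height ~ age, d)
  expect_lt(max(abs(coef(fit) - truth) / abs(truth)), 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_s3_class(fit, "vb_growth")
  expect_equal(length(residuals(fit)), 40)
  expect_equal(predict(fit, data.frame(age = 10)),
               260 * (1 - exp(-0.15 * 12)))
  expect_output(print(fit), "Von Bertalanffy")
  expect_output(print(summary(fit)), "RSS")
})

test_that("curve fitting tolerates 2% multiplicative noise", {
  set.seed(19)
  a <- runif(50, 0, 50)
  h <- 260 * (1 - exp(-0.12 * (a + 3))) * exp(rnorm(50, 0, 0.02))
  fit <- fit_growth_curve(height ~ age, data.frame(age = a, height = h))
  expect_lt(abs(coef(fit)["h_inf"] - 260) / 260, 0.05)
})

test_that("under-determined or degenerate data refuse to fit", {
  expect_error(fit_growth_curve(height ~ age,
    data.frame(age = c(1, 5, 10), height = c(90, 140, 180))),
    "at least 4")
  expect_error(fit_growth_curve(height ~ age,
    data.frame(age = rep(5, 6), height = rnorm(6, 140))),
    "degenerate")
})

test_that("fitted curves can be installed as growth parameters", {
  a <- seq(0, 45, length.out = 30)
  d <- data.frame(age = a, height = 240 * (1 - exp(-0.2 * (a + 1.5))))
  g <- as_growth_params(fit_growth_curve(height ~ age, d), "female")
  expect_equal(unname(g$female["h_inf"]), 240, tolerance = 1e-6)
  expect_lt(abs(height_at_age(7, "female", g) -
                  240 * (1 - exp(-0.2 * 8.5))), 1e-5)
})
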