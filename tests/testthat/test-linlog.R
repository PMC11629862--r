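test_that("parameter derivation matches element-wise recomputation", {
  mod <- random_linlog(m = 3, r = 4, seed = 11)
  pars <- derive_parameters(mod)
  scl <- mod$J0 / mod$E0
  # independent element-wise oracle
  for (i in seq_along(mod$reactions)) {
    expect_equal(pars$Ap[[i]],
                 unname(scl[i]) * (1 - sum(mod$Bx[i, ] * log(mod$x0)) -
                                     sum(mod$Bc[i, ] * log(mod$c0))))
    expect_equal(unname(pars$Bp[i, ]), unname(scl[i] * mod$Bx[i, ]))
    expect_equal(unname(pars$Cp[i, ]), unname(scl[i] * mod$Bc[i, ]))
  }
  # with x0 = c0 = 1 the log terms vanish
  expect_equal(unname(pars$Ap), unname(scl))
})

test_that("rates at the reference state reproduce J0 and E = 0 silences a reaction", {
  mod <- carbon_fixture()
  pars <- derive_parameters(mod)
  expect_equal(linlog_rates(mod, pars), unname(mod$J0))
  E <- mod$E0; E[5] <- 0
  expect_equal(linlog_rates(mod, pars, E = E)[5], 0)
  expect_error(linlog_rates(mod, pars, x = rep(-1, 26)), "> 0")
  # random state matches a term-by-term oracle
  set.seed(3)
  E <- runif(34, 0.5, 2); x <- runif(26, 0.5, 2); c <- runif(2, 0.5, 2)
  v <- linlog_rates(mod, pars, E = E, x = x, c = c)
  v_oracle <- sapply(seq_len(34), function(i) {
    E[i] * (pars$Ap[[i]] + sum(pars$Bp[i, ] * log(x)) + sum(pars$Cp[i, ] * log(c)))
  })
  expect_equal(v, v_oracle)
})

test_that("steady state recovers the reference and is a true steady state", {
  mod <- carbon_fixture()
  expect_equal(linlog_steady_state(mod), mod$x0, tolerance = 1e-12)
  set.seed(5)
  pars <- derive_parameters(mod)
  for (i in 1:5) {
    E <- mod$E0 * exp(rnorm(34, 0, 0.3))
    x <- linlog_steady_state(mod, pars, E = E)
    v <- linlog_rates(mod, pars, E = E, x = x)
    expect_lt(max(abs(mod$N %*% v)) / max(abs(v)), 1e-8)
  }
})

test_that("uniform enzyme scaling gives perfect homeostasis on random models", {
  for (seed in 1:20) {
    mod <- random_linlog(m = sample(2:6, 1), r = sample(7:10, 1), seed = seed)
    pars <- derive_parameters(mod)
    r <- runif(1, 0.3, 3)
    x <- linlog_steady_state(mod, pars, E = r * mod$E0)
    expect_lt(max(abs(x - mod$x0)), 1e-10)
    v <- linlog_rates(mod, pars, E = r * mod$E0, x = x)
    expect_equal(v, unname(r * mod$J0), tolerance = 1e-10)
  }
})

test_that("steady state is scale-invariant in concentration units", {
  mod <- random_linlog(m = 3, r = 5, seed = 21)
  f <- 10
  mod2 <- linlog_model(mod$N, mod$E0, mod$J0, f * mod$x0, f * mod$c0,
                       mod$Bx, mod$Bc, output_reaction = mod$output_reaction)
  set.seed(9)
  E <- mod$E0 * exp(rnorm(length(mod$E0), 0, 0.2))
  x1 <- linlog_steady_state(mod, E = E)
  x2 <- linlog_steady_state(mod2, E = E, c = mod2$c0)
  expect_equal(unname(x2), unname(f * x1), tolerance = 1e-10)
})

test_that("model IO round-trips in both dialects and rejects invalid files", {
  mod <- carbon_fixture()
  js <- tempfile(fileext = ".json")
  write_linlog_model(mod, js, format = "json")
  back <- read_linlog_model(js, format = "json")
  expect_equal(back$N, mod$N)
  expect_equal(back$J0, mod$J0)
  expect_equal(back$Bx, mod$Bx)
  expect_equal(back$Bc, mod$Bc)
  expect_equal(back$output_reaction, mod$output_reaction)

  pref <- tempfile()
  write_linlog_model(mod, pref, format = "tsv")
  back2 <- read_linlog_model(pref, format = "tsv")
  expect_equal(back2$N, mod$N)
  expect_equal(back2$Bx, mod$Bx)
  expect_equal(back2$J0, mod$J0)

  # the two dialects are equivalent
  expect_equal(back2$N, back$N)
  expect_equal(back2$Bc, back$Bc)

  # a file whose reference fluxes are off balance is rejected
  bad <- mod
  bad$J0[1] <- bad$J0[1] + 1
  js_bad <- tempfile(fileext = ".json")
  doc <- jsonlite::read_json(js, simplifyVector = TRUE)
  doc$state$J0[doc$state$name == "pts" & doc$state$kind == "reaction"] <- 99
  jsonlite::write_json(doc, js_bad, digits = NA, auto_unbox = TRUE)
  expect_error(read_linlog_model(js_bad, format = "json"), "steady state")
})

test_that("packaged carbon model has the advertised dimensions and externals", {
  mod <- carbon_fixture()
  expect_identical(length(mod$reactions), 34L)
  expect_identical(length(mod$metabolites), 26L)
  expect_identical(sort(mod$externals), c("acetate", "glucose"))
})

test_that("shipped model files load and match the generators", {
  f <- system.file("extdata", "carbon_model.json", package = "replimet")
  mod <- read_linlog_model(f)
  expect_identical(length(mod$reactions), 34L)
  expect_identical(length(mod$metabolites), 26L)
  expect_equal(mod$N, carbon_fixture()$N)
  f2 <- system.file("extdata", "chain2_model.json", package = "replimet")
  chain <- read_linlog_model(f2)
  expect_identical(length(chain$reactions), 2L)
  expect_gt(linlog_steady_state(chain, E = c(2, 1)), chain$x0)
})

test_that("two-reaction chain reproduces source/sink intermediate behaviour", {
  mod <- chain2_model()
  pars <- derive_parameters(mod)
  # s increases with E1/E2 and is at reference when E1 = E2
  x_ref <- linlog_steady_state(mod, pars, E = c(1, 1))
  x_hi <- linlog_steady_state(mod, pars, E = c(2, 1))
  x_lo <- linlog_steady_state(mod, pars, E = c(1, 2))
  expect_equal(unname(x_ref), 1)
  expect_gt(x_hi, x_ref)
  expect_lt(x_lo, x_ref)
  # uniform scaling leaves s unchanged (same ratio)
  expect_equal(linlog_steady_state(mod, pars, E = c(3, 3)), x_ref)
})
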