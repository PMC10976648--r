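single_rules <- c(10, 11, 12, 14, 15, 17, 18, 19, 20, 21)

ctx_for <- function(eq) {
  if (eq == 13) {
    list(epsilon1 = 1.2, epsilon2 = 0.4, gamma1 = 12, gamma2 = 14,
         epsilon12 = sqrt(1.2 * 0.4), gamma12 = 13)
  } else if (eq == 16) {
    list(sigma1 = 3.2, sigma2 = 4.1)
  }
}

test_that("hand-evaluated combination relations", {
  expect_equal(apply_rule(10, 4, 9), 6)
  expect_equal(apply_rule(11, 1, 3), 2)
  expect_equal(apply_rule(12, 5, 5), 5)
  expect_equal(apply_rule(20, 1, 1), 1)
  expect_equal(apply_rule(20, 1, 2), ((1 + 8) / 2)^(1 / 3))
  expect_equal(apply_rule(20, 1, 2), 1.650964, tolerance = 1e-6)
  expect_equal(apply_rule(18, 2, 4), (8 + 64) / (4 + 16))
  expect_equal(apply_rule(19, 1, 4), 16 / 9)
})

test_that("every relation is symmetric and idempotent", {
  withr::with_seed(7, {
    for (rep in 1:200) {
      x1 <- runif(1, 0.01, 50); x2 <- runif(1, 0.01, 50)
      for (eq in single_rules) {
        expect_equal(apply_rule(eq, x1, x2), apply_rule(eq, x2, x1),
                     tolerance = 1e-12, info = paste("sym", eq))
        expect_equal(apply_rule(eq, x1, x1), x1,
                     tolerance = 1e-12, info = paste("idem", eq))
      }
      # context-dependent relations: idempotence with matching context
      s <- x1; e <- x2; g <- runif(1, 7, 20)
      expect_equal(apply_rule(13, s, s,
                              list(epsilon1 = e, epsilon2 = e, gamma1 = g, gamma2 = g,
                                   epsilon12 = e, gamma12 = g)), s, tolerance = 1e-12)
      expect_equal(apply_rule(16, e, e, list(sigma1 = s, sigma2 = s)), e,
                   tolerance = 1e-12)
      # symmetry of 13 and 16 under swapping the two atoms
      s2 <- runif(1, 2, 5); e2 <- runif(1, 0.05, 3); g2 <- runif(1, 7, 20)
      e12 <- sqrt(e * e2); g12 <- (g + g2) / 2
      expect_equal(
        apply_rule(13, s, s2, list(epsilon1 = e, epsilon2 = e2, gamma1 = g,
                                   gamma2 = g2, epsilon12 = e12, gamma12 = g12)),
        apply_rule(13, s2, s, list(epsilon1 = e2, epsilon2 = e, gamma1 = g2,
                                   gamma2 = g, epsilon12 = e12, gamma12 = g12)),
        tolerance = 1e-12)
      expect_equal(apply_rule(16, e, e2, list(sigma1 = s, sigma2 = s2)),
                   apply_rule(16, e2, e, list(sigma1 = s2, sigma2 = s)),
                   tolerance = 1e-12)
    }
  })
})

test_that("mean ordering: harmonic <= geometric <= arithmetic <= power means", {
  withr::with_seed(11, {
    for (rep in 1:500) {
      x1 <- runif(1, 0.01, 20); x2 <- runif(1, 0.01, 20)
      h <- apply_rule(12, x1, x2); g <- apply_rule(10, x1, x2)
      a <- apply_rule(11, x1, x2)
      p17 <- apply_rule(17, x1, x2); p20 <- apply_rule(20, x1, x2)
      expect_true(h <= g + 1e-12 && g <= a + 1e-12 &&
                    a <= p20 + 1e-12 && p20 <= p17 + 1e-12)
      if (abs(x1 - x2) > 1e-6) {
        expect_lt(apply_rule(21, x1, x2), g)
      }
    }
  })
})

test_that("singularities raise errors", {
  expect_error(apply_rule(12, 0, 0), "singular")
  expect_error(apply_rule(13, 3, 4, modifyList(ctx_for(13), list(epsilon12 = 0))),
               "singular")
  expect_error(apply_rule(13, 3, 4, modifyList(ctx_for(13), list(gamma12 = 0))),
               "singular")
  expect_error(apply_rule(13, 3, 4), "context")
  expect_error(apply_rule(16, 1, 2), "context")
  expect_error(apply_rule(22, 1, 2), "unknown")
})

test_that("ruleset construction validates admissibility and notation", {
  rs <- ruleset("GBH", "10 20 14 11")
  expect_equal(ruleset_label(rs), "10 20 14 11")
  expect_equal(names(rs$assignment), c("epsilon", "sigma", "gamma", "delta"))
  expect_error(ruleset("GBH", "13 10 11 11"), "sigma")   # 13 not for epsilon
  expect_error(ruleset("GBH", "10 16 11 11"), "epsilon") # 16 not for sigma
  expect_error(ruleset("GBH", "10 11 11 15"), "gamma")   # 15 not for delta
  expect_error(ruleset("LJ12-6", "10"), "needs 2 rules")
  expect_error(ruleset("TT", "10 10 13 10 10"), "sigma")
})

test_that("combine_params is the identity on equal homodimers", {
  m <- potential_model("GBH", c(epsilon = 1.3, sigma = 3.9, gamma = 12.5, delta = 6.1))
  for (lab in c("10 20 14 11", "16 13 15 21", "12 17 11 19")) {
    cm <- combine_params(ruleset("GBH", lab), m, m)
    expect_equal(cm$params, m$params, tolerance = 1e-12, info = lab)
  }
})

test_that("combine_params applies rules parameter-by-parameter", {
  m1 <- potential_model("LJ12-6", c(sigma = 3, epsilon = 1))
  m2 <- potential_model("LJ12-6", c(sigma = 4, epsilon = 4))
  cm <- combine_params(ruleset("LJ12-6", c(epsilon = 10, sigma = 10)), m1, m2)
  expect_equal(cm$params[["sigma"]], sqrt(12))
  expect_equal(cm$params[["epsilon"]], 2)

  # Waldman-Hagler pair on equal atoms is the identity
  wh <- ruleset("LJ12-6", c(epsilon = 16, sigma = 17))
  cm <- combine_params(wh, m1, m1)
  expect_equal(cm$params, m1$params[c("epsilon", "sigma")], tolerance = 1e-12)

  # dependency order: rule 13 consumes the already-combined epsilon and gamma
  a <- potential_model("MBH", c(epsilon = 1.2, sigma = 3.7, gamma = 12))
  b <- potential_model("MBH", c(epsilon = 0.4, sigma = 4.2, gamma = 15))
  cm <- combine_params(ruleset("MBH", c(epsilon = 12, sigma = 13, gamma = 11)), a, b)
  e12 <- 2 * 1.2 * 0.4 / 1.6; g12 <- 13.5
  s12 <- (sqrt(1.2 * 12 * 3.7^6 * 0.4 * 15 * 4.2^6) / (e12 * g12))^(1 / 6)
  expect_equal(cm$params[["epsilon"]], e12)
  expect_equal(cm$params[["gamma"]], g12)
  expect_equal(cm$params[["sigma"]], s12, tolerance = 1e-12)

  expect_error(combine_params(ruleset("MBH", "10 10 10"), m1, m2), "family")
})

test_that("ruleset enumeration counts and ordering are deterministic", {
  adm <- list(epsilon = c(11L, 10L), sigma = c(20L, 17L))
  grid <- enumerate_rulesets("LJ12-6", adm)
  expect_equal(nrow(grid), 4)
  expect_equal(grid$epsilon, c(10L, 10L, 11L, 11L))
  expect_equal(grid$sigma, c(17L, 20L, 17L, 20L))

  grid8 <- enumerate_rulesets("LJ12-6",
                              list(epsilon = single_rules[1:8], sigma = single_rules[1:8]))
  expect_equal(nrow(grid8), 64)

  d <- default_admissibility("LJ14-7")
  expect_equal(nrow(enumerate_rulesets("LJ14-7", d)),
               prod(vapply(d, length, 1L)))
  expect_error(enumerate_rulesets("LJ12-6", list(epsilon = integer(), sigma = 10L)),
               "empty")
})

test_that("a planted combination rule is recovered by the exhaustive scan", {
  planted <- "10 20 14"
  wc <- synthetic_world_curves("MRS", planted_rule = planted, noise_sd = 0)
  fits <- lapply(setNames(nm = synthetic_elements()$element), function(el) {
    fit_potential("MRS", wc$homodimers[[paste(el, el, sep = "-")]],
                  seed = 3, n_starts = 6)$model
  })
  rk <- rank_rulesets(fits, wc$heterodimers)
  expect_equal(rk$rule[1], planted)
  expect_lt(rk$mean_rmse[1], 1e-8)
  # ranking is invariant under permutation of the curve list
  rk2 <- rank_rulesets(fits, rev(wc$heterodimers))
  expect_equal(rk2$rule, rk$rule)
  expect_equal(rk2$mean_rmse, rk$mean_rmse)
})

test_that("rule sets that fail on any pair score Inf and sort last", {
  wc <- synthetic_world_curves("MRS", planted_rule = "10 11 11", noise_sd = 0)
  fits <- lapply(setNames(nm = synthetic_elements()$element), function(el) {
    fit_potential("MRS", wc$homodimers[[paste(el, el, sep = "-")]],
                  seed = 3, n_starts = 4)$model
  })
  # admissibility deliberately assigns the context-dependent relation 13 to
  # gamma, where no context can be built: those rule sets must score Inf
  adm <- list(epsilon = 10L, sigma = c(10L, 11L), gamma = c(11L, 13L))
  rk <- rank_rulesets(fits, wc$heterodimers[1:2], admissibility = adm)
  expect_equal(nrow(rk), 4)
  bad <- rk[rk$gamma == 13L, ]
  expect_true(all(is.infinite(bad$mean_rmse)))
  expect_true(all(bad$rank > max(rk$rank[rk$gamma != 13L])))
})

test_that("ties are broken by the sorted equation-id tuple", {
  # two rule sets produce identical parameters when the atoms are identical
  el <- synthetic_elements()$element[1]
  m <- synthetic_truth("MRS", el)
  cv <- generate_synthetic_curve(m, 2, 20, 0.1, element_a = el, element_b = "Zz")
  fits <- list(m, m); names(fits) <- c(el, "Zz")
  adm <- list(epsilon = c(10L, 11L), sigma = 10L, gamma = 10L)
  rk <- rank_rulesets(fits, list(cv), admissibility = adm)
  expect_equal(rk$mean_rmse[1], rk$mean_rmse[2], tolerance = 1e-12)
  expect_equal(rk$rule, c("10 10 10", "11 10 10"))
})
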