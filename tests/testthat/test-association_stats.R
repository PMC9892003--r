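# frozen small fixture: 4 tomograms x 2 states, binary outcome
fixture_obs <- function() {
  counts <- expand.grid(tomogram_id = paste0("t", 1:4),
                        state = c("elong", "hib"),
                        stringsAsFactors = FALSE)
  yes <- c(8, 6, 7, 9, 1, 2, 0, 1)
  no <- c(2, 4, 3, 1, 9, 8, 10, 9)
  do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    data.frame(tomogram_id = counts$tomogram_id[i], state = counts$state[i],
               outcome = rep(c("in-polysome", "none"), c(yes[i], no[i])))
  }))
}

test_that("the zero-variance limit equals pooled per-state frequencies", {
  obs <- fixture_obs()
  fit <- fit_association_model(obs, model_config(fix_random_variance = 0))
  pooled <- tapply(obs$outcome == "in-polysome", obs$state, mean)
  pred <- fit$predicted_probabilities
  pred <- pred[pred$outcome == "in-polysome", ]
  expect_equal(pred$mean[match(names(pooled), pred$state)],
               as.numeric(pooled), tolerance = 1e-6,
               ignore_attr = TRUE)
  # probabilities over outcomes sum to one per state
  sums <- tapply(fit$predicted_probabilities$mean,
                 fit$predicted_probabilities$state, sum)
  expect_equal(as.numeric(sums), rep(1, 2), tolerance = 1e-8)
  expect_true(all(fit$predicted_probabilities$ci_low <=
                    fit$predicted_probabilities$mean + 1e-12))
  expect_true(all(fit$predicted_probabilities$ci_high >=
                    fit$predicted_probabilities$mean - 1e-12))
})

test_that("the Laplace fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  cat2 <- data.frame(state_label = c("A", "B"), base_probability = c(.5, .5),
                     in_polysome_probability = c(.8, .2))
  obs <- generate_association_dataset(
    scene_config(n_tomograms = 120, seed = 61, state_catalog = cat2,
                 tomogram_effect_sd = 0.5), n_per_tomogram = 40)
  fit <- fit_association_model(obs)
  obs$y <- as.integer(obs$outcome == "in-polysome")
  g <- lme4::glmer(y ~ 0 + state + (1 | tomogram_id), data = obs,
                   family = binomial)
  fe <- lme4::fixef(g)
  expect_equal(unname(fit$coefficients["in-polysome", c("A", "B")]),
               unname(fe[c("stateA", "stateB")]), tolerance = 1e-4)
  expect_equal(unname(fit$random_intercept_sd),
               sqrt(unname(unlist(lme4::VarCorr(g)))), tolerance = 1e-3)
  se_ours <- sqrt(diag(fit$covariance))[c("in-polysome|A", "in-polysome|B")]
  se_lme4 <- sqrt(diag(as.matrix(stats::vcov(g))))
  expect_equal(unname(se_ours), unname(se_lme4), tolerance = 1e-3)
})

test_that("Laplace and adaptive quadrature agree within reported standard errors", {
  cat2 <- data.frame(state_label = c("A", "B"), base_probability = c(.5, .5),
                     in_polysome_probability = c(.7, .3))
  obs <- generate_association_dataset(
    scene_config(n_tomograms = 80, seed = 62, state_catalog = cat2,
                 tomogram_effect_sd = 0.7), n_per_tomogram = 25)
  f1 <- fit_association_model(obs, model_config(estimation_method = "laplace"))
  f2 <- fit_association_model(obs, model_config(estimation_method = "agq"))
  se <- sqrt(diag(f1$covariance))
  expect_true(all(abs(f1$coefficients - f2$coefficients) < se))
  expect_equal(unname(f1$random_intercept_sd),
               unname(f2$random_intercept_sd), tolerance = 0.05)
})

test_that("an intercept-only fit matches a direct numerical-integration oracle", {
  cat1 <- data.frame(state_label = "only", base_probability = 1,
                     in_polysome_probability = 0.6)
  obs <- generate_association_dataset(
    scene_config(n_tomograms = 60, seed = 63, tomogram_effect_sd = 0.6,
                 state_catalog = cat1), n_per_tomogram = 30)
  fit <- fit_association_model(obs, model_config(estimation_method = "agq",
                                                 n_quadrature = 25))
  # oracle: maximize the exactly integrated marginal likelihood
  y <- tapply(obs$outcome == "in-polysome", obs$tomogram_id, sum)
  n <- tapply(rep(1, nrow(obs)), obs$tomogram_id, sum)
  negll <- function(par) {
    b <- par[1]; s <- exp(par[2])
    # standardized substitution u = s * t keeps the integrand well scaled
    -sum(mapply(function(yi, ni) {
      p0 <- (yi + 0.5) / (ni + 1)   # scale factor against underflow
      c0 <- yi * log(p0) + (ni - yi) * log1p(-p0)
      log(stats::integrate(function(t) {
        p <- stats::plogis(b + s * t)
        exp(yi * log(p) + (ni - yi) * log1p(-p) - c0) * stats::dnorm(t)
      }, -12, 12, rel.tol = 1e-9)$value) + c0
    }, y, n))
  }
  o <- stats::optim(c(0, log(0.5)), negll, method = "BFGS")
  expect_equal(unname(fit$coefficients[1, 1]), o$par[1], tolerance = 1e-3)
  expect_equal(unname(fit$random_intercept_sd), exp(o$par[2]),
               tolerance = 1e-3)
  pred <- fit$predicted_probabilities
  expect_equal(pred$mean[pred$outcome == "in-polysome"],
               stats::plogis(o$par[1]), tolerance = 1e-3)
})

test_that("Wald contrasts match hand arithmetic and handle self-contrasts", {
  obs <- fixture_obs()
  fit <- fit_association_model(obs)
  self <- wald_contrast(fit, data.frame(state_a = "elong", state_b = "elong",
                                        outcome = "in-polysome"))
  expect_equal(self$estimate, 0)
  expect_equal(self$p_raw, 1)
  ct <- wald_contrast(fit, data.frame(state_a = "elong", state_b = "hib",
                                      outcome = "in-polysome"))
  ka <- "in-polysome|elong"; kb <- "in-polysome|hib"
  est <- fit$coefficients["in-polysome", "elong"] -
    fit$coefficients["in-polysome", "hib"]
  se <- sqrt(fit$covariance[ka, ka] + fit$covariance[kb, kb] -
               2 * fit$covariance[ka, kb])
  expect_equal(ct$estimate, unname(est))
  expect_equal(ct$z, unname(est / se))
  expect_equal(ct$p_raw, unname(2 * pnorm(-abs(est / se))))
  expect_error(wald_contrast(fit, data.frame(state_a = "nope",
                                             state_b = "hib",
                                             outcome = "in-polysome")),
               "unknown state")
})

test_that("a strong hibernating/elongating split yields a vanishing Wald p", {
  cat2 <- data.frame(state_label = c("elong", "hib"),
                     base_probability = c(.6, .4),
                     in_polysome_probability = c(.85, .05))
  obs <- generate_association_dataset(
    scene_config(n_tomograms = 150, seed = 64, state_catalog = cat2,
                 tomogram_effect_sd = 0.3), n_per_tomogram = 60)
  fit <- fit_association_model(obs)
  p <- fit$contrasts$p_raw[fit$contrasts$outcome == "in-polysome"]
  expect_lt(p, 2e-16)
})

test_that("Hochberg adjustment matches the step-up formula", {
  expect_equal(hochberg_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(hochberg_adjust(0.3), 0.3)               # m = 1 identity
  set.seed(65)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- hochberg_adjust(p)
    # independent hand implementation of the step-up rule
    m <- length(p)
    ord <- order(p)
    hand <- numeric(m)
    hand[ord[m]] <- p[ord[m]]
    for (k in (m - 1):1)
      hand[ord[k]] <- min(hand[ord[k + 1]], (m - k + 1) * p[ord[k]])
    hand <- pmin(hand, 1)
    expect_equal(adj, hand)
    expect_true(all(adj >= p))                          # dominance
    expect_true(all(diff(adj[ord]) >= -1e-12))          # monotone
  }
  expect_error(hochberg_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("fold increases divide modelled means by fractional abundance", {
  fake <- structure(list(predicted_probabilities = data.frame(
    state = "s", outcome = "in-polysome", mean = 0.4,
    ci_low = 0.3, ci_high = 0.5)), class = "association_fit")
  fi <- fold_increase(fake, c("in-polysome" = 0.2))
  expect_equal(fi$fold, 2)
  expect_equal(fi$fold_ci_low, 1.5)
  expect_equal(fi$fold_ci_high, 2.5)
  expect_error(fold_increase(fake, c("in-polysome" = 0)), "zero abundance")
  expect_error(fold_increase(fake, c(other = 0.5)), "in-polysome")
})

test_that("abundance_table returns fractions that sum to one", {
  tab <- ptab(list(state_label = "X"), list(state_label = "X", x = 200),
              list(state_label = "X", x = 400), list(state_label = "X", x = 600),
              list(state_label = "X", x = 800), list(state_label = "Y", x = 1000),
              list(state_label = "Y", x = 1200), list(state_label = "Z", x = 1400),
              list(state_label = "Z", x = 1600), list(state_label = "Z", x = 1800))
  ab <- abundance_table(tab, "state_label")
  expect_equal(sum(ab), 1)
  expect_equal(unname(ab["X"]), 0.5)
  single <- ptab(list(state_label = "only"))
  expect_equal(unname(abundance_table(single, "state_label")), 1)
})

test_that("estimates are invariant to relabelling tomograms", {
  obs <- fixture_obs()
  f1 <- fit_association_model(obs)
  obs2 <- obs
  obs2$tomogram_id <- chartr("1234", "9875", obs2$tomogram_id)
  f2 <- fit_association_model(obs2)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$random_intercept_sd, f2$random_intercept_sd,
               tolerance = 1e-8)
})

test_that("complete separation is flagged with a warning", {
  obs <- rbind(
    data.frame(tomogram_id = rep(c("t1", "t2"), each = 10),
               state = "always", outcome = "in-polysome"),
    data.frame(tomogram_id = rep(c("t1", "t2"), each = 10),
               state = "mixed",
               outcome = rep(c("in-polysome", "none"), 10)))
  expect_warning(fit <- fit_association_model(obs), "separation")
  expect_identical(fit$separated_states, "always")
})

test_that("degenerate inputs are rejected with clear messages", {
  obs <- fixture_obs()
  expect_error(fit_association_model(obs[obs$outcome == "none", ]),
               "outcome categories")
  expect_error(fit_association_model(obs[obs$tomogram_id == "t1", ]),
               "2 tomograms")
})
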