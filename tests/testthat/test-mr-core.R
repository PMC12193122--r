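# Wald ratios, IVW, MR-Egger, weighted median, Cochran's Q

test_that("Wald ratios follow the first-order delta method", {
  iset <- make_iset(gamma = c(0.2, -0.2), Gamma = c(0.1, 0.1),
                    se_Gamma = c(0.05, 0.05))
  r <- wald_ratios(iset)
  expect_equal(r$ratio, c(0.5, -0.5))
  expect_equal(r$se_ratio, c(0.25, 0.25))
  expect_equal(r$weight, rep(1 / 0.25^2, 2))

  with_zero <- make_iset(gamma = c(0.2, 0), Gamma = c(0.1, 0.1))
  expect_warning(rz <- wald_ratios(with_zero), "gamma = 0")
  expect_equal(nrow(rz), 1)
  all_zero <- make_iset(gamma = c(0, 0), Gamma = c(0.1, 0.1))
  expect_error(wald_ratios(all_zero), "no Wald ratio")
})

test_that("IVW on identical ratios returns that ratio with Q = 0", {
  iset <- make_iset(gamma = c(0.1, 0.2, 0.4), Gamma = c(0.05, 0.10, 0.20),
                    se_Gamma = rep(0.1, 3))
  fit <- ivw(iset, model = "fixed")
  expect_equal(fit$estimate$beta, 0.5)
  expect_equal(fit$heterogeneity$Q, 0, tolerance = 1e-12)
  expect_equal(fit$estimate$se, sqrt(1 / 21))
  expect_equal(fit$heterogeneity$df, 2)

  single <- make_iset(gamma = 0.1, Gamma = 0.05)
  expect_error(ivw(single), "at least 2")
})

test_that("IVW equals brute-force weighted regression through the origin", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    iset <- make_iset(gamma = rnorm(n, 0, 0.1) + 0.2, Gamma = rnorm(n, 0.02, 0.02),
                      se_Gamma = runif(n, 0.05, 0.2))
    fit <- ivw(iset, model = "fixed")
    oracle <- lm(Gamma ~ 0 + gamma, data = iset$records,
                 weights = 1 / iset$records$se_Gamma^2)
    expect_equal(fit$estimate$beta, unname(coef(oracle)), tolerance = 1e-12)
    # fixed-effect SE is the unscaled weighted-LS SE
    se_unscaled <- summary(oracle)$coefficients[1, 2] / summary(oracle)$sigma
    expect_equal(fit$estimate$se, unname(se_unscaled), tolerance = 1e-10)
  }
})

test_that("fixed-effect IVW SE never exceeds multiplicative-random SE", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    iset <- make_iset(gamma = rnorm(n, 0.2, 0.05), Gamma = rnorm(n, 0.02, 0.05),
                      se_Gamma = runif(n, 0.02, 0.2))
    expect_lte(ivw(iset, "fixed")$estimate$se, ivw(iset, "random")$estimate$se)
  }
})

test_that("IVW and Egger are invariant to jointly flipping any instrument's signs", {
  set.seed(13)
  n <- 8
  iset <- make_iset(gamma = rnorm(n, 0.2, 0.1), Gamma = rnorm(n, 0.05, 0.05),
                    se_Gamma = runif(n, 0.05, 0.2))
  flipped <- iset
  idx <- c(2, 5)
  flipped$records$gamma[idx] <- -flipped$records$gamma[idx]
  flipped$records$Gamma[idx] <- -flipped$records$Gamma[idx]
  expect_equal(ivw(iset)$estimate, ivw(flipped)$estimate)
  e1 <- mr_egger(iset); e2 <- mr_egger(flipped)
  expect_equal(e1$slope, e2$slope)
  expect_equal(e1$intercept, e2$intercept)
  expect_equal(e1$heterogeneity, e2$heterogeneity)
})

test_that("MR-Egger recovers an exact line with Q = 0 and t-based inference", {
  g <- c(0.1, 0.2, 0.3, 0.4)
  iset <- make_iset(gamma = g, Gamma = 0.1 + 0.5 * g, se_Gamma = rep(0.1, 4))
  e <- mr_egger(iset)
  expect_equal(e$intercept$beta, 0.1, tolerance = 1e-12)
  expect_equal(e$slope$beta, 0.5, tolerance = 1e-12)
  expect_equal(e$heterogeneity$Q, 0, tolerance = 1e-12)
  expect_equal(e$heterogeneity$df, 2)
  # p-values use t with n-2 df
  expect_equal(e$slope$pvalue, 2 * pt(-abs(e$slope$beta / e$slope$se), 2))
  expect_error(mr_egger(make_iset(gamma = c(0.1, 0.2), Gamma = c(0, 0))),
               "at least 3")
})

test_that("weighted median matches symmetric and dominance limits", {
  eq <- make_iset(gamma = rep(1, 3), Gamma = c(0.1, 0.5, 0.9),
                  se_Gamma = rep(1, 3))
  wm <- weighted_median(eq, n_boot = 200, seed = 1)
  expect_equal(wm$beta, 0.5)

  # one instrument carries > 50% of total weight: estimate goes to its ratio
  dom <- make_iset(gamma = rep(1, 3), Gamma = c(0.1, 0.9, 0.42),
                   se_Gamma = c(1, 1, 0.05))
  wm2 <- weighted_median(dom, n_boot = 200, seed = 1)
  expect_equal(wm2$beta, 0.42, tolerance = 0.02)
  expect_error(weighted_median(eq, seed = NULL), "seed")
})

test_that("weighted median equals the breakpoint-walk oracle on unequal weights", {
  iset <- make_iset(gamma = rep(1, 5), Gamma = c(0.3, 0.1, 0.7, 0.4, 0.9),
                    se_Gamma = c(0.5, 1, 0.25, 0.4, 0.8))
  est <- weighted_median(iset, n_boot = 100, seed = 3)$beta
  # independent oracle: explicit walk over cumulative-weight breakpoints
  ratio <- iset$records$Gamma / iset$records$gamma
  w <- iset$records$gamma^2 / iset$records$se_Gamma^2
  ord <- order(ratio); r <- ratio[ord]; ws <- w[ord]
  s <- (cumsum(ws) - ws / 2) / sum(ws)
  k <- max(which(s < 0.5))
  oracle <- r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
  expect_equal(est, oracle, tolerance = 1e-12)
})

test_that("weighted-median bootstrap is reproducible under a seed", {
  iset <- make_iset(gamma = runif(6, 0.1, 0.3), Gamma = runif(6, 0, 0.1))
  a <- weighted_median(iset, n_boot = 200, seed = 99)
  b <- weighted_median(iset, n_boot = 200, seed = 99)
  expect_identical(a, b)
})

test_that("Cochran's Q matches hand arithmetic and flags homogeneity", {
  same <- data.frame(ratio = rep(0.3, 4), weight = c(1, 2, 3, 4))
  q0 <- cochran_q(same, 0.3)
  expect_equal(q0$Q, 0)
  expect_equal(q0$pvalue, 1)
  expect_true(q0$no_heterogeneity)

  two <- data.frame(ratio = c(0, 1), weight = c(1, 1))
  expect_equal(cochran_q(two, 0.5)$Q, 0.5)
})

test_that("mr_fit bundles estimators with working accessor methods", {
  set.seed(21)
  iset <- make_iset(gamma = rnorm(10, 0.2, 0.05),
                    Gamma = rnorm(10, 0.04, 0.02),
                    se_Gamma = rep(0.05, 10))
  fit <- mr_fit(iset, seed = 5)
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$estimates$method, c("IVW", "Egger-slope", "Egger-intercept", "WM"))
  expect_equal(unname(coef(fit)["IVW"]), ivw(iset)$estimate$beta)
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  expect_equal(fit$estimates$odds_ratio, exp(fit$estimates$beta))
  expect_output(print(summary(fit)), "Egger intercept")
  expect_error(mr_fit(iset, methods = "weighted_median"), "seed")
})

test_that("all estimators recover the causal effect on clean simulated data", {
  reps <- 40
  truth <- 0.0525
  est <- t(sapply(seq_len(reps), function(s) {
    sim <- simulate_mediation_gwas(simulation_config(seed = 300 + s))
    set <- quiet_select(sim$exposure, sim$outcome, ld = sim$ld, radial = FALSE)
    fit <- mr_fit(set, n_boot = 200, seed = s)
    coef(fit)[c("IVW", "Egger-slope", "WM")]
  }))
  for (m in colnames(est)) {
    mcse <- sd(est[, m]) / sqrt(reps)
    expect_lt(abs(mean(est[, m]) - truth), 2 * mcse + 1e-8,
              label = sprintf("%s recovery |bias| (%.5f)", m, mean(est[, m]) - truth))
  }
})
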