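test_that("Dirichlet log-likelihood matches hand-computed values", {
  # Dir(1,1) is uniform on the simplex: log-density 0 per observation
  y <- matrix(c(0.3, 0.7, 0.6, 0.4), 2, 2, byrow = TRUE)
  expect_equal(dirichlet_loglik(y, matrix(1, 2, 2)), 0)
  # single observation, y=(.5,.5), a=(2,2): logG(4)-2logG(2)+log(.25)
  expect_equal(dirichlet_loglik(matrix(0.5, 1, 2), matrix(2, 1, 2)),
               log(6) - log(4))
  # additivity over observations
  a <- matrix(c(2, 3, 1.5, 0.8), 2, 2)
  expect_equal(dirichlet_loglik(y, a),
               dirichlet_loglik(y[1, , drop = FALSE],
                                a[1, , drop = FALSE]) +
                 dirichlet_loglik(y[2, , drop = FALSE],
                                  a[2, , drop = FALSE]))
  expect_error(dirichlet_loglik(matrix(c(0, 1), 1, 2), matrix(1, 1, 2)),
               "boundary")
})

test_that("squeeze transform moves compositions off the boundary", {
  y <- matrix(c(1, 0, rep(0.5, 16)), 9, 2, byrow = TRUE)
  sq <- squeeze_composition(y)
  expect_equal(unname(sq[1, ]), c(17 / 18, 1 / 18))
  expect_equal(rowSums(sq), rep(1, 9))
  expect_true(all(sq > 0 & sq < 1))
  # interior rows move by at most 1/n
  expect_lt(max(abs(sq[-1, ] - y[-1, ])), 1 / 9 + 1e-12)
})

test_that("Bonferroni helpers implement threshold and capping", {
  expect_equal(signif(bonferroni_threshold(0.05, 39), 3), 0.00128)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(adjust_p_bonferroni(0.1, 20), 1)
  expect_equal(adjust_p_bonferroni(0.001, 39), 0.039)
  expect_error(bonferroni_threshold(0, 5), "alpha")
  expect_error(adjust_p_bonferroni(1.2, 5), "p")
})

test_that("intercept-only fit recovers the mean composition", {
  set.seed(31)
  sim <- generate_covariate_linked_thetas(
    n_samples = 500, K = 3,
    covariate_specs = list(x = list(kind = "continuous")),
    precision = 25, seed = 31)
  # exposure with no planted effect acts as the near-null predictor;
  # fitted mean composition should match the sample mean
  fit <- fit_dirichlet_regression(sim$theta, sim$covariates, "x")
  expect_true(fit$converged)
  expect_lt(max(abs(colMeans(fit$fitted) - colMeans(sim$theta))), 0.02)
  # optimum at least as good as the moment-based start
  expect_gte(fit$log_likelihood, fit$start_log_likelihood)
  # fitted compositions live strictly inside the simplex
  expect_equal(rowSums(fit$fitted), rep(1, fit$n), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("planted per-SD coefficient is recovered across replicates", {
  g <- matrix(0, 1, 3, dimnames = list("x", NULL))
  g[1, 1] <- 0.5
  est <- sig <- numeric(5)
  for (r in 1:5) {
    sim <- generate_covariate_linked_thetas(
      n_samples = 500, K = 3,
      covariate_specs = list(x = list(kind = "continuous")),
      gamma = g, precision = 30, seed = 400 + r)
    fit <- fit_dirichlet_regression(sim$theta, sim$covariates, "x")
    cf <- fit$coefficients[fit$coefficients$is_exposure, ]
    est[r] <- cf$estimate[cf$subgroup == "subgroup_1"]
    sig[r] <- cf$p[cf$subgroup == "subgroup_1"] < 0.05
  }
  expect_lt(abs(mean(est) - 0.5), 0.1)
  expect_gte(sum(sig), 4)
})

test_that("per-SD standardization is scale equivariant", {
  g <- matrix(0.4, 1, 3, dimnames = list("x", NULL))
  sim <- generate_covariate_linked_thetas(
    n_samples = 300, K = 3,
    covariate_specs = list(x = list(kind = "continuous")),
    gamma = g, precision = 20, seed = 77)
  f1 <- fit_dirichlet_regression(sim$theta, sim$covariates, "x")
  cd <- sim$covariates$data
  cd$x <- cd$x * 37.5  # arbitrary rescale, e.g. unit change
  f2 <- fit_dirichlet_regression(sim$theta, covariate_table(cd), "x")
  c1 <- f1$coefficients[f1$coefficients$is_exposure, ]
  c2 <- f2$coefficients[f2$coefficients$is_exposure, ]
  expect_equal(c1$estimate, c2$estimate, tolerance = 1e-5)
  expect_equal(c1$p, c2$p, tolerance = 1e-4)
})

test_that("degenerate inputs raise informative errors", {
  sim <- generate_covariate_linked_thetas(
    n_samples = 60, K = 3,
    covariate_specs = list(x = list(kind = "continuous")), seed = 9)
  cd <- sim$covariates$data
  cd$const <- 1
  expect_error(fit_dirichlet_regression(sim$theta, covariate_table(cd),
                                        "const"), "zero-variance")
  expect_error(fit_dirichlet_regression(sim$theta, sim$covariates,
                                        "nope"), "absent")
  # boundary thetas are squeezed with a message, not an error
  th <- sim$theta
  th[1, ] <- c(1, 0, 0)
  expect_message(fit_dirichlet_regression(th, sim$covariates, "x"),
                 "squeeze")
})

test_that("missing covariate rows are dropped and counted", {
  sim <- generate_covariate_linked_thetas(
    n_samples = 80, K = 3,
    covariate_specs = list(x = list(kind = "continuous")), seed = 10)
  cd <- sim$covariates$data
  cd$x[1:5] <- NA
  fit <- fit_dirichlet_regression(sim$theta, covariate_table(cd), "x")
  expect_equal(fit$n_dropped, 5)
  expect_equal(fit$n, 75)
})

test_that("association battery shares the Bonferroni m across families", {
  g <- matrix(0, 1, 3, dimnames = list("x1", NULL))
  g[1, 1] <- 0.8
  sim <- generate_covariate_linked_thetas(
    n_samples = 400, K = 3,
    covariate_specs = list(x1 = list(kind = "continuous"),
                           x2 = list(kind = "continuous"),
                           age = list(kind = "continuous", mean = 60,
                                      sd = 12)),
    gamma = g, precision = 30, seed = 55)
  fam <- list(
    diet = list(exposures = c("x1", "x2"), adjustments = "age"),
    disease = list(exposures = "age", adjustments = character()))
  res <- run_association_battery(sim$theta, sim$covariates, fam)
  expect_equal(attr(res, "m_tests"), 3)
  expect_equal(res$p_adj, pmin(1, res$p * 3))
  expect_setequal(unique(res$exposure), c("x1", "x2", "age"))
  # only the planted (x1, subgroup_1) cell clears the shared threshold
  thr <- bonferroni_threshold(0.05, 3)
  hits <- res[res$p < thr & res$family == "diet", ]
  expect_true(all(hits$exposure == "x1" & hits$subgroup == "subgroup_1"))

  # degenerate battery equals a single fit
  one <- run_association_battery(
    sim$theta, sim$covariates,
    list(diet = list(exposures = "x1", adjustments = "age")))
  single <- fit_dirichlet_regression(sim$theta, sim$covariates, "x1",
                                     "age", m_tests = 1)
  expect_equal(one$estimate,
               single$coefficients$estimate[
                 single$coefficients$is_exposure])
  expect_error(run_association_battery(
    sim$theta, sim$covariates,
    list(diet = list(exposures = "ghost"))), "ghost")
})

test_that("family exclusion rules subset the samples before fitting", {
  sim <- generate_covariate_linked_thetas(
    n_samples = 120, K = 3,
    covariate_specs = list(x = list(kind = "continuous")), seed = 66)
  cd <- sim$covariates$data
  cd$not_fasted <- rep(c(TRUE, FALSE), length.out = 120)
  res <- run_association_battery(
    sim$theta, covariate_table(cd),
    list(lipids = list(exposures = "x", adjustments = character(),
                       exclude_if = "not_fasted")))
  expect_equal(unique(res$n), 60)
})

test_that("categorical exposures report each non-reference level", {
  set.seed(88)
  sim <- generate_covariate_linked_thetas(
    n_samples = 300, K = 3,
    covariate_specs = list(
      diabetes = list(kind = "categorical",
                      levels = c("normal", "pre", "t2dm"),
                      probs = c(0.6, 0.3, 0.1),
                      reference = "normal")),
    seed = 88)
  fit <- fit_dirichlet_regression(sim$theta, sim$covariates, "diabetes")
  cf <- fit$coefficients[fit$coefficients$is_exposure, ]
  expect_setequal(unique(cf$term),
                  c("diabetespre", "diabetest2dm"))
  expect_equal(nrow(cf), 2 * 3)  # 2 dummies x 3 subgroups
})
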