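test_that("effects of the screening design match hand-computed contrast means", {
  d <- factorial_design(doe1_table(), doe1_factors(), response = "dg")
  eff <- estimate_effects(d)
  get <- function(tm) eff$effect[eff$term == tm]
  # level means computed directly from the printed batch table
  expect_equal(get("n2_flow"), -0.40)
  expect_equal(get("feed_conc"), 0.00)
  expect_equal(get("aspiration"), -0.125)
  expect_equal(eff$coefficient, eff$effect / 2)
  # main-effect magnitude ordering: N2 flow > aspiration > feed concentration
  mains <- abs(c(get("n2_flow"), get("aspiration"), get("feed_conc")))
  expect_true(all(diff(mains) < 0))
})

test_that("refinement-design aspiration effect matches its contrast mean", {
  d <- factorial_design(doe2_table(), doe2_factors(), response = "dv")
  eff <- estimate_effects(d)
  expect_equal(eff$effect[eff$term == "aspiration"], -0.17)
  expect_equal(eff$coefficient[eff$term == "aspiration"], -0.085)
})

test_that("contrast-mean effects equal twice the least-squares coded coefficients", {
  fac <- data.frame(name = c("A", "B", "C"), low = c(0, 0, 0),
                    high = c(1, 1, 1))
  set.seed(31)
  for (rep in 1:5) {
    y <- stats::rnorm(8)
    runs <- as.data.frame(as.matrix(expand.grid(A = c(-1, 1), B = c(-1, 1),
                                                C = c(-1, 1))))
    runs$y <- y
    d <- factorial_design(runs, fac, "y")
    eff <- estimate_effects(d)
    fit <- stats::lm(y ~ A * B * C, data = runs)
    cf <- stats::coef(fit)
    names(cf) <- sub("(Intercept)", "int", names(cf), fixed = TRUE)
    for (i in seq_len(nrow(eff)))
      expect_equal(eff$effect[i], 2 * unname(cf[[eff$term[i]]]),
                   tolerance = 1e-9)
  }
})

test_that("full-factorial validation catches missing and unbalanced combinations", {
  fac <- data.frame(name = c("A", "B"), low = c(0, 0), high = c(1, 1))
  runs <- data.frame(A = c(-1, 1, -1), B = c(-1, -1, 1), y = 1:3)
  expect_error(factorial_design(runs, fac, "y"), "missing combination")
  runs2 <- data.frame(A = c(-1, 1, -1, 1, 1), B = c(-1, -1, 1, 1, 1),
                      y = 1:5)
  expect_error(factorial_design(runs2, fac, "y"), "replication")
  # off-level actual settings are rejected
  fac3 <- data.frame(name = "A", low = 10, high = 20)
  expect_error(factorial_design(data.frame(A = c(10, 15), y = 1:2),
                                fac3, "y"), "low/high")
})

test_that("half-normal ranking sorts by magnitude with (i-0.5)/m positions", {
  d <- simulate_doe_table(
    data.frame(name = c("A", "B"), low = c(0, 0), high = c(1, 1)),
    planted_effects = c(A = -0.40, B = 0.0, "A:B" = -0.125),
    intercept = 3, sigma = 0, seed = 1)
  eff <- estimate_effects(d)
  hn <- half_normal_ranking(eff)
  expect_equal(hn$abs_effect, c(0, 0.125, 0.40))
  expect_equal(hn$p, c(1, 3, 5) / 6)
  expect_equal(hn$half_normal_quantile, stats::qnorm((1 + c(1, 3, 5) / 6) / 2))
  expect_equal(hn$term[3L], "A")
})

test_that("ANOVA decomposition is orthogonal and detects planted effects", {
  d <- factorial_design(doe1_table(), doe1_factors(), response = "dg")
  eff <- estimate_effects(d)
  y <- doe1_table()$dg
  ss_total <- sum((y - mean(y))^2)
  ss_all <- 8 * eff$effect^2 / 4
  expect_equal(sum(ss_all), ss_total, tolerance = 1e-9 * ss_total)
  tab <- anova_selected(d, c("n2_flow", "aspiration"))
  expect_equal(sum(tab$sum_sq), ss_total, tolerance = 1e-9 * ss_total)
  # cross-check F and p against aov with the pooled-error model
  runs <- as.data.frame(d$coded); runs$y <- y
  ref <- summary(stats::aov(y ~ n2_flow + aspiration, data = runs))[[1]]
  expect_equal(tab$F[1:2], ref[["F value"]][1:2], tolerance = 1e-9)
  expect_equal(tab$p_value[1:2], ref[["Pr(>F)"]][1:2], tolerance = 1e-9)
  # noiseless planted simulation: selected terms explain everything
  fac <- data.frame(name = c("A", "B", "C"), low = c(0, 0, 0),
                    high = c(1, 1, 1))
  sim <- simulate_doe_table(fac, c(A = 1.2, "B:C" = 0.6), intercept = 10,
                            sigma = 0, seed = 2)
  tab2 <- anova_selected(sim, c("A", "B:C"))
  expect_equal(tab2$sum_sq[tab2$term == "residuals"], 0, tolerance = 1e-12)
  expect_equal(tab2$p_value[1:2], c(0, 0))
  expect_error(anova_selected(d, design_terms(colnames(d$coded))),
               "no error degrees of freedom")
  expect_error(anova_selected(d, "bogus"), "not estimable")
})

test_that("coded and actual prediction equations agree at every corner", {
  d <- factorial_design(doe1_table(), doe1_factors(), response = "dg")
  eq <- prediction_equation(d, c("n2_flow", "aspiration",
                                 "feed_conc:aspiration"))
  corners <- expand.grid(feed_conc = c(0.25, 0.35), n2_flow = c(600, 742),
                         aspiration = c(20, 30))
  actual_terms <- setdiff(names(eq$actual_coefficients), "(Intercept)")
  pred_actual <- drop(cbind(1, sapply(actual_terms, function(tm) {
    parts <- strsplit(tm, ":")[[1]]
    apply(corners[, parts, drop = FALSE], 1, prod)
  })) %*% eq$actual_coefficients)
  expect_equal(unname(eq$predict(corners)), unname(pred_actual),
               tolerance = 1e-9)
  # intercept-only model predicts the grand mean everywhere
  eq0 <- prediction_equation(d, character(0))
  expect_equal(unname(eq0$predict(corners)),
               rep(mean(doe1_table()$dg), nrow(corners)))
})

test_that("planted factorial effects are recovered without bias under noise", {
  fac <- data.frame(name = c("A", "B", "C"), low = c(0, 0, 0),
                    high = c(1, 1, 1))
  sigma <- 0.1
  est <- vapply(1:200, function(i) {
    d <- simulate_doe_table(fac, c(A = -0.4), intercept = 3, sigma = sigma,
                            seed = 1000 + i)
    eff <- estimate_effects(d)
    eff$effect[eff$term == "A"]
  }, numeric(1))
  # effect variance is 4 sigma^2 / N per table; 3 SE over 200 replicates
  se <- sqrt(4 * sigma^2 / 8) / sqrt(200)
  expect_lt(abs(mean(est) + 0.4), 3 * se)
})

test_that("Lenth selection flags a dominant effect among noise", {
  fac <- data.frame(name = c("A", "B", "C"), low = c(0, 0, 0),
                    high = c(1, 1, 1))
  d <- simulate_doe_table(fac, c(A = 2.0), intercept = 5, sigma = 0.05,
                          seed = 99)
  sel <- select_effects_lenth(estimate_effects(d))
  expect_true("A" %in% sel)
  expect_lt(length(sel), 4)
})
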