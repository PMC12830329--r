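test_that("outcome merging takes the maximum available grade", {
    m <- suppressMessages(
        mergeOutcomes(c(1, 0, 3, NA, NA), c(2, 0, NA, 1, NA)))
    expect_equal(m$grade, c(2, 0, 3, 1, NA))
    expect_equal(m$source,
                 c("pro", "tie", "cro_only", "pro_only", "missing"))
    expect_message(mergeOutcomes(NA_integer_, NA_integer_), "1 records")
    expect_error(mergeOutcomes(c(1, 5), c(0, 0)), "0..3")
})

test_that("collinearity filter drops exactly the redundant member of a
           pair", {
    set.seed(61)
    n <- 1000
    d <- data.frame(a = rnorm(n))
    d$b <- d$a                        # r = 1
    d$c <- d$a + rnorm(n, 0, 1e-4)   # r > 0.9999
    d$e <- rnorm(n)
    d$z <- 1                         # zero variance
    expect_gt(abs(cor(d$a, d$c)), 0.9)
    expect_warning(res <- collinearityFilter(d, c("a", "b", "c", "e", "z")),
                   "zero-variance")
    expect_true("e" %in% res$retained)
    expect_equal(sum(c("a", "b", "c") %in% res$retained), 1L)
    expect_true(all(c("b", "z") %in% res$dropped$dropped) ||
                all(c("a", "z") %in% res$dropped$dropped))
})

test_that("independent Gaussians survive the 0.9 screen", {
    set.seed(62)
    d <- as.data.frame(matrix(rnorm(1000 * 6), ncol = 6))
    res <- collinearityFilter(d, names(d))
    expect_equal(res$retained, names(d))
    expect_equal(nrow(res$dropped), 0L)
})

test_that("proportional-odds fits recover a known coefficient", {
    set.seed(63)
    beta <- 0.8
    est <- replicate(30, {
        n <- 2000
        x <- rnorm(n)
        latent <- beta * x + rlogis(n)
        y <- findInterval(latent, c(-1, 1, 2.5))
        f <- fitOrdinal(data.frame(y = y, x = x), "y", "x")
        c(f@coefficients$estimate, f@coefficients$se)
    })
    expect_lt(abs(mean(est[1, ]) - beta), 0.05)
    # Wald CIs cover at roughly the nominal rate
    cover <- mean(abs(est[1, ] - beta) < 1.96 * est[2, ])
    expect_gte(cover, 0.85)
})

test_that("AIC identity holds on every fit", {
    set.seed(64)
    d <- data.frame(y = sample(0:3, 300, replace = TRUE),
                    x1 = rnorm(300), x2 = rnorm(300))
    for (cov in list(character(), "x1", c("x1", "x2"))) {
        f <- fitOrdinal(d, "y", cov)
        k <- nrow(f@coefficients) + length(f@zeta)
        expect_equal(f@aic, 2 * k - 2 * f@logLik)
    }
    # known arithmetic: logL = -100 with 5 parameters gives AIC 210
    expect_equal(2 * 5 - 2 * (-100), 210)
})

test_that("degenerate outcomes are rejected", {
    d <- data.frame(y = rep(2L, 50), x = rnorm(50))
    expect_error(fitOrdinal(d, "y", "x"), "single observed level")
    expect_error(fitOrdinal(data.frame(y = c(0, 5), x = 1:2), "y", "x"),
                 "0..3")
})

test_that("forward selection finds a single true effect and stops", {
    set.seed(65)
    n <- 1500
    d <- as.data.frame(matrix(rnorm(n * 6), ncol = 6))
    names(d) <- c("true", paste0("null", 1:5))
    d$age <- rnorm(n, 60, 8)
    latent <- 1.0 * d$true + 0.02 * (d$age - 60) + rlogis(n)
    d$y <- findInterval(latent, c(-0.5, 1.5, 3))
    sw <- stepwiseAIC(d, "y", baseline = "age",
                      candidates = c("true", paste0("null", 1:5)))
    expect_true("true" %in% sw$selected)
    expect_lt(sw$finalAIC, sw$baselineAIC)
    # accepted steps strictly decrease AIC along the trace
    acc <- sw$trace[sw$trace$accepted, ]
    expect_true(all(acc$aic_after < acc$aic_before))
    # forward and backward agree on this well-separated design
    bw <- stepwiseAIC(d, "y", baseline = "age",
                      candidates = c("true", paste0("null", 1:5)),
                      direction = "backward")
    expect_true("true" %in% bw$selected)
})

test_that("selection with no candidates returns the baseline model
           exactly", {
    set.seed(66)
    d <- data.frame(y = sample(0:2, 200, replace = TRUE), age = rnorm(200))
    sw <- stepwiseAIC(d, "y", baseline = "age", candidates = character())
    base <- fitOrdinal(d, "y", "age")
    expect_equal(sw$finalAIC, base@aic)
    expect_equal(sw$fit@coefficients$estimate, base@coefficients$estimate)
    expect_equal(nrow(sw$trace), 0L)
    expect_equal(sw$selected, character())
})

test_that("selection path is deterministic given the data", {
    set.seed(67)
    coh <- generateCohort(300, seed = 8)
    rec <- mergeCohortOutcomes(coh$records)
    cand <- c("fat_mean_gy", "fg_mean_gy", "median_hu", "fg_volume_cm3")
    a <- stepwiseAIC(rec, "pain_post", c("age", "boost"), cand)
    b <- stepwiseAIC(rec, "pain_post", c("age", "boost"), cand)
    expect_identical(a$selected, b$selected)
    expect_identical(a$trace, b$trace)
})

test_that("the endpoint sweep skips degenerate cells with a reason", {
    coh <- generateCohort(120, seed = 31)
    rec <- mergeCohortOutcomes(coh$records)
    rec$pain_post <- 0L   # constant outcome
    es <- endpointSweep(rec, baseline = c("age", "boost"),
                        candidates = c("fat_mean_gy", "fg_mean_gy"),
                        endpoints = c("pain", "oedema"),
                        timepoints = "post")
    s <- es$summary
    expect_true(s$skipped[s$endpoint == "pain"])
    expect_match(s$reason[s$endpoint == "pain"], "single level")
    expect_false(s$skipped[s$endpoint == "oedema"])
    expect_true(all(c("n", "baseline_aic", "best_aic", "selected",
                      "agreement") %in% names(s)))
})

test_that("the sweep recovers the generator's dose-toxicity pattern", {
    betas <- list(pain = c(fat_mean_gy = 1.2),
                  induration = c(fg_mean_gy = 1.2))
    coh <- generateCohort(500, seed = 77, outcomeBetas = betas,
                          missingProb = 0)
    rec <- mergeCohortOutcomes(coh$records, endpoints = names(betas),
                               timepoints = "post")
    es <- endpointSweep(rec, baseline = c("age", "breast_volume_cm3",
                                          "boost"),
                        candidates = c("fat_mean_gy", "fg_mean_gy",
                                       "median_hu", "fat_uniformity"),
                        endpoints = names(betas), timepoints = "post")
    sel <- setNames(es$summary$selected, es$summary$endpoint)
    expect_match(sel[["pain"]], "fat_mean_gy")
    expect_match(sel[["induration"]], "fg_mean_gy")
})
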