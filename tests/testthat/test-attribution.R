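test_that("standardization centers, scales, and is idempotent", {
  pan <- random_panel(1)
  s1 <- standardize(pan)
  mu <- vapply(s1[c("response", MN_PREDICTORS)], mean, numeric(1))
  sd1 <- vapply(s1[c("response", MN_PREDICTORS)], stats::sd, numeric(1))
  expect_equal(unname(mu), rep(0, 5))
  expect_equal(unname(sd1), rep(1, 5))
  s2 <- standardize(s1)
  expect_equal(s2$fq, s1$fq)
  tr <- attr(s1, "transform")
  expect_named(tr, c("center", "scale"))

  pan$sst <- 7
  expect_error(standardize(pan), "zero-variance column: sst")
})

test_that("ordinary least squares recovers exact and null structure", {
  set.seed(10)
  n <- 400
  pan <- data.frame(fq = rnorm(n), prey_q = rnorm(n), sst = rnorm(n),
                    zoo_b = rnorm(n))
  pan$response <- 2 * pan$fq
  fit <- suppressWarnings(fit_glm(pan))  # "essentially perfect fit"
  expect_equal(unname(fit$coefficients),c(2, 0, 0, 0), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$sigma2, 0, tolerance = 1e-20)

  set.seed(11)
  pan2 <- data.frame(fq = rnorm(10000), prey_q = rnorm(10000),
                     sst = rnorm(10000), zoo_b = rnorm(10000),
                     response = rnorm(10000))
  expect_lt(fit_glm(pan2)$r_squared, 0.01)

  pan$prey_q <- pan$fq  # duplicated predictor
  expect_error(fit_glm(pan), "collinear")
})

test_that("the subset-weight LMG formula reproduces hand-enumerated orderings", {
  # two predictors with sub-model R^2 of 0.3 and 0.2 and a joint R^2 of 0.6:
  # averaging the two orderings by hand gives shares (0.35, 0.25)
  a <- sqrt(0.3); b <- sqrt(0.2)
  r <- stats::uniroot(function(r) (a^2 + b^2 - 2 * a * b * r) / (1 - r^2) - 0.6,
                      c(-0.9, 0.9), tol = 1e-14)$root
  C <- rbind(cbind(matrix(c(1, r, r, 1), 2), c(a, b)), c(a, b, 1))
  res <- mnrecycle:::.lmg_from_cov(C)
  expect_equal(res$r_squared, 0.6, tolerance = 1e-9)
  expect_equal(res$shares, c(0.35, 0.25), tolerance = 1e-9)
  # single predictor: the share is the whole R^2
  C1 <- rbind(c(1, a), c(a, 1))
  expect_equal(mnrecycle:::.lmg_from_cov(C1)$shares, 0.3, tolerance = 1e-12)
})

test_that("subset formula and 24-ordering enumeration agree exactly", {
  for (seed in 1:20) {
    pan <- random_panel(seed)
    s1 <- lmg_shares(pan)
    s2 <- lmg_shares_bruteforce(pan)
    expect_equal(s1$shares, s2$shares, tolerance = 1e-12)
    expect_equal(s1$r_squared, s2$r_squared, tolerance = 1e-12)
    expect_equal(sum(s1$shares), s1$r_squared, tolerance = 1e-10)
    expect_true(all(s1$shares >= -1e-12))
  }
})

test_that("orthogonal designs give squared simple correlations as shares", {
  set.seed(21)
  n <- 200
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n))))[, 2:5]
  colnames(Q) <- MN_PREDICTORS
  pan <- data.frame(Q)
  pan$response <- as.numeric(Q %*% c(1, -0.5, 0.25, 0)) + rnorm(n, 0, 0.5)
  s <- lmg_shares(pan)
  expected <- vapply(MN_PREDICTORS,
                     function(v) stats::cor(pan[[v]], pan$response)^2,
                     numeric(1))
  expect_equal(s$shares, expected, tolerance = 1e-10)
})

test_that("importance shares are invariant under affine rescaling", {
  pan <- random_panel(5, n = 120)
  ref <- lmg_shares(pan)
  resc <- pan
  resc$fq <- 3.7 * resc$fq - 12
  resc$zoo_b <- -0.02 * resc$zoo_b
  resc$response <- 250 * resc$response + 4
  s <- lmg_shares(resc)
  expect_equal(s$shares, ref$shares, tolerance = 1e-10)
  std <- lmg_shares(standardize(pan))
  expect_equal(std$shares, ref$shares, tolerance = 1e-10)
})

test_that("empirical shares converge to the analytic population shares", {
  sig <- matrix(0.4, 4, 4); diag(sig) <- 1
  spec <- panel_spec(n = 20000, coefficients = c(fq = 1, prey_q = -0.5,
                                                 sst = 0.3, zoo_b = 0.8),
                     target_r2 = 0.6, default_cov = sig, seed = 77)
  gp <- generate_driver_panel(spec)
  emp <- lmg_shares(gp$panel)
  expect_lt(max(abs(emp$shares - gp$truth$shares)), 0.02)
  expect_equal(sum(gp$truth$shares), gp$truth$r_squared, tolerance = 1e-12)
})

test_that("dominance classification renormalizes biotic shares only", {
  imp <- structure(list(shares = c(fq = 0.1, prey_q = 0.2, sst = 0.05,
                                   zoo_b = 0.6),
                        r_squared = 0.95, n = 100), class = "mn_importance")
  pt <- classify_dominance(imp)
  expect_equal(c(pt$qual, pt$quant, pt$zoo), c(1, 2, 6) / 9,
               tolerance = 1e-12)
  expect_equal(pt$sst_share, 0.05)
  expect_identical(pt$dominant, "zoo")
  expect_true(pt$included)
  expect_false(pt$tie)

  low <- structure(list(shares = imp$shares * 0.4, r_squared = 0.4, n = 100),
                   class = "mn_importance")
  expect_false(classify_dominance(low)$included)

  even <- structure(list(shares = c(fq = 0.2, prey_q = 0.2, sst = 0.1,
                                    zoo_b = 0.2),
                         r_squared = 0.7, n = 100), class = "mn_importance")
  pe <- classify_dominance(even)
  expect_equal(c(pe$qual, pe$quant, pe$zoo), rep(1 / 3, 3))
  expect_true(pe$tie)
  expect_identical(pe$dominant, "qual")  # fixed tie-break order

  none <- structure(list(shares = c(fq = 0, prey_q = 0, sst = 0.3,
                                    zoo_b = 0),
                         r_squared = 0.3, n = 100), class = "mn_importance")
  pn <- classify_dominance(none)
  expect_true(is.na(pn$qual))
  expect_false(pn$included)
})

test_that("ternary embedding places corners and centroid canonically", {
  expect_equal(unname(ternary_coordinates(c(1, 0, 0))), c(0, 0))
  expect_equal(unname(ternary_coordinates(c(0, 1, 0))), c(1, 0))
  expect_equal(unname(ternary_coordinates(c(0, 0, 1))), c(0.5, sqrt(3) / 2))
  expect_equal(unname(ternary_coordinates(c(1, 1, 1) / 3)),
               c(0.5, sqrt(3) / 6))
  # unnormalized input is projected onto the simplex
  expect_equal(unname(ternary_coordinates(c(2, 2, 2))), c(0.5, sqrt(3) / 6))
})

test_that("grouped attribution recovers distinct regional structure", {
  specA <- panel_spec(n = 1500, regions = list(A = list(cov = diag(c(6, 1, 1, 1)))),
                      target_r2 = 0.9, seed = 31)
  specB <- panel_spec(n = 1500, regions = list(B = list(cov = diag(c(1, 1, 1, 6)))),
                      target_r2 = 0.9, seed = 32)
  panel <- rbind(generate_driver_panel(specA)$panel,
                 generate_driver_panel(specB)$panel)
  tab <- attribute_by_group(panel, by = "region")
  expect_equal(nrow(tab), 2L)
  expect_identical(tab$status, c("ok", "ok"))
  expect_identical(tab$dominant[tab$region == "A"], "qual")
  expect_identical(tab$dominant[tab$region == "B"], "zoo")
  expect_true(all(tab$included))

  # single group matches the direct pipeline
  one <- panel[panel$region == "A", ]
  t1 <- attribute_by_group(one, by = "region")
  direct <- lmg_shares(standardize(one))
  expect_equal(t1$share_fq, unname(direct$shares[["fq"]]), tolerance = 1e-12)
  expect_equal(t1$r_squared, direct$r_squared, tolerance = 1e-12)

  # degenerate groups are reported, not dropped
  one$sst <- 12
  both <- rbind(one, panel[panel$region == "B", ])
  tb <- attribute_by_group(both, by = "region")
  expect_equal(nrow(tb), 2L)
  expect_match(tb$status[tb$region == "A"], "zero-variance column: sst")
  expect_identical(tb$status[tb$region == "B"], "ok")
})
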