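# The ODE right-hand side, branch integration, node combination and the
# full pruning likelihood, checked against hand expansions, a deSolve
# integration of the same equations, the dense matrix-exponential
# propagator (mu = 0) and the closed-form birth-death likelihood (one
# area).

test_that("zero rates freeze the partials; pure death pushes E at rate mu", {
  mod <- range_model(sp2, "DEC")
  E <- runif(3); D <- runif(3)
  z <- ode_rhs(E, D, rate_params(0, 0, 0, 0, 0), mod)
  expect_equal(z$dE, rep(0, 3))
  expect_equal(z$dD, rep(0, 3))
  p <- rate_params(0, 0, 0, 0, 0.37)
  z <- ode_rhs(rep(0, 3), D, p, mod)
  expect_equal(z$dE, rep(0.37, 3))
  expect_equal(z$dD, -0.37 * D)
})

test_that("RHS matches the hand-expanded two-area system", {
  ## states: 1 = {A}, 2 = {B}, 3 = {A,B}
  mod <- range_model(sp2, "DEC")
  set.seed(5)
  for (rep in 1:5) {
    p <- rand_params()
    E <- runif(3); D <- runif(3)
    lis <- p$lambda_is; lv <- p$lambda_vic; d <- p$d; e <- p$e; mu <- p$mu
    ## {A}: clado in-situ (A|A); dispersal to {A,B}
    tot1 <- lis + d
    dE1 <- mu - (tot1 + mu) * E[1] + d * E[3] + lis * E[1]^2
    dD1 <- -(tot1 + mu) * D[1] + d * D[3] + lis * 2 * D[1] * E[1]
    ## {A,B}: in-situ (A|AB), (B|AB); vicariance (A|B); extirpation to A, B
    tot3 <- 2 * lis + lv + 2 * e
    dE3 <- mu - (tot3 + mu) * E[3] + e * (E[1] + E[2]) +
      lis * (E[1] * E[3] + E[2] * E[3]) + lv * E[1] * E[2]
    dD3 <- -(tot3 + mu) * D[3] + e * (D[1] + D[2]) +
      lis * (D[1] * E[3] + D[3] * E[1]) +
      lis * (D[2] * E[3] + D[3] * E[2]) +
      lv * (D[1] * E[2] + D[2] * E[1])
    z <- ode_rhs(E, D, p, mod)
    expect_equal(z$dE[1], dE1, tolerance = 1e-12)
    expect_equal(z$dD[1], dD1, tolerance = 1e-12)
    expect_equal(z$dE[3], dE3, tolerance = 1e-12)
    expect_equal(z$dD[3], dD3, tolerance = 1e-12)
  }
})

test_that("compiled branch integration agrees with deSolve on ode_rhs", {
  skip_if_not_installed("deSolve")
  mod <- range_model(sp3, "DEC")
  set.seed(11)
  for (rep in 1:3) {
    p <- rand_params()
    n <- sp3$n_states
    E0 <- rep(0, n); D0 <- numeric(n); D0[sample(n, 1)] <- 1
    len <- runif(1, 0.5, 3)
    ref <- deSolve::ode(
      y = c(E0, D0), times = c(0, len),
      func = function(t, y, parms) {
        z <- ode_rhs(y[1:n], y[n + 1:n], p, mod)
        list(c(z$dE, z$dD))
      }, parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
    out <- integrate_branch(E0, D0, len, p, mod)
    expect_equal(out$E, unname(ref[2, 1 + 1:n]), tolerance = 1e-7)
    expect_equal(out$D * exp(out$dlog), unname(ref[2, 1 + n + 1:n]),
                 tolerance = 1e-7)
  }
})

test_that("zero-length branches are the identity", {
  mod <- range_model(sp2, "DIVA")
  E <- runif(3); D <- runif(3)
  out <- integrate_branch(E, D, 0, rand_params(), mod)
  expect_identical(out$E, E)
  expect_identical(out$D, D)
  expect_identical(out$dlog, 0)
})

test_that("E stays in [0,1], is non-decreasing, and stabilises on long branches", {
  set.seed(21)
  mod <- range_model(sp3, "DEC")
  for (rep in 1:10) {
    p <- rand_params(mu = runif(1, 0.05, 0.5))
    lens <- seq(0, 40, length.out = 9)
    vals <- matrix(NA_real_, length(lens), sp3$n_states)
    for (i in seq_along(lens)) {
      out <- integrate_branch(rep(0, sp3$n_states), rep(1, sp3$n_states),
                              lens[i], p, mod)
      vals[i, ] <- out$E
      expect_true(all(out$E >= 0 & out$E <= 1))
    }
    expect_true(all(diff(vals) >= -1e-8))
    ## monotone convergence toward a per-state fixed point: increments shrink
    expect_lt(max(abs(vals[9, ] - vals[8, ])),
              max(abs(vals[3, ] - vals[2, ])) + 1e-10)
  }
})

test_that("node combination sums over events; zero daughters absorb", {
  p <- rate_params(0.3, 0.2, 0.1, 0.05, 0)
  mod1 <- range_model(sp1, "DEC")
  out <- combine_at_node(0, 2, 0, 3, p, mod1)
  expect_equal(out$D, 0.3 * 2 * 3)
  ## DEC parent {A,B}: 2 in-situ + 1 vicariance events, 6 product terms
  mod <- range_model(sp2, "DEC")
  DL <- c(2, 3, 5); DR <- c(7, 11, 13)
  out <- combine_at_node(rep(0, 3), DL, rep(0, 3), DR, p, mod)
  hand3 <- 0.3 * (DL[1] * DR[3] + DL[3] * DR[1]) +
           0.3 * (DL[2] * DR[3] + DL[3] * DR[2]) +
           0.2 * (DL[1] * DR[2] + DL[2] * DR[1])
  expect_equal(out$D[3], hand3)
  expect_equal(out$D[1], 0.3 * DL[1] * DR[1])
  out0 <- combine_at_node(rep(0, 3), rep(0, 3), rep(0, 3), DR, p, mod)
  expect_equal(out0$D, rep(0, 3))
  ## E mismatch warns
  expect_warning(combine_at_node(c(0, 0, 0), DL, c(0.5, 0, 0), DR, p, mod),
                 "disagree")
})

test_that("one area reduces the likelihood to closed-form birth-death", {
  set.seed(31)
  tr <- ape::rphylo(25, 0.3, 0.1)
  tips <- setNames(rep(1L, 25), tr$tip.label)
  for (rep in 1:10) {
    lam <- runif(1, 0.05, 0.5); mu <- runif(1, 0, 0.9 * lam)
    for (cond in c(TRUE, FALSE)) {
      ll <- compute_loglik(tr, tips, sp1, rate_params(lam, 0, 0, 0, mu),
                           "DEC", keep_cache = FALSE,
                           options = likelihood_options(
                             condition_on_survival = cond))$loglik
      expect_equal(ll, bd_loglik(tr, lam, mu, cond), tolerance = 1e-6)
    }
  }
  ## Yule special case, exact closed form
  ll <- compute_loglik(tr, tips, sp1, rate_params(0.3, 0, 0, 0, 0), "DEC",
                       keep_cache = FALSE)$loglik
  expect_equal(ll, 24 * log(0.3) - 0.3 * sum(tr$edge.length),
               tolerance = 1e-8)
})

test_that("mu = 0 pruning matches the matrix-exponential oracle", {
  set.seed(41)
  for (rep in 1:6) {
    sp <- if (rep %% 2) sp2 else sp3
    tr <- if (rep %% 3) tree5 else ape::read.tree(
      text = "((a:1,b:1):1.5,(c:0.7,d:0.7):1.8);")
    tips <- rand_tips(tr, sp)
    p <- rand_params(mu = 0)
    for (m in c("DEC", "DIVA")) {
      ll <- compute_loglik(tr, tips, sp, p, m, keep_cache = FALSE)$loglik
      expect_equal(ll, loglik_matexp(tr, tips, sp, p, m), tolerance = 1e-7)
    }
  }
})

test_that("likelihood is invariant to tip permutation and child rotation", {
  set.seed(51)
  p <- rand_params()
  tips <- rand_tips(tree5, sp2)
  base <- compute_loglik(tree5, tips, sp2, p, "DEC", keep_cache = FALSE)$loglik
  ## permute labels together with the range table
  perm <- sample(5)
  tr2 <- tree5
  tr2$tip.label <- tree5$tip.label[perm]
  tips2 <- tips
  names(tips2) <- names(tips)[perm]
  ## identical map tip -> state, so same loglik
  expect_equal(
    compute_loglik(tr2, tips2[tr2$tip.label], sp2, p, "DEC",
                   keep_cache = FALSE)$loglik, base, tolerance = 1e-10)
  ## rotate children at an internal node
  tr3 <- ape::rotate(tree5, node = 7)
  expect_equal(
    compute_loglik(tr3, tips, sp2, p, "DEC", keep_cache = FALSE)$loglik,
    base, tolerance = 1e-10)
})

test_that("repeated evaluation is bitwise identical", {
  p <- rate_params(0.3, 0.2, 0.1, 0.05, 0.1)
  tips <- setNames(c(1L, 3L, 2L, 1L, 3L), tree5$tip.label)
  l1 <- compute_loglik(tree5, tips, sp2, p, "DEC", keep_cache = FALSE)$loglik
  l2 <- compute_loglik(tree5, tips, sp2, p, "DEC", keep_cache = FALSE)$loglik
  expect_identical(l1, l2)
})

test_that("loglik approaches the complete-sampling value as rho -> 1", {
  p <- rate_params(0.3, 0.2, 0.1, 0.05, 0.1)
  tips <- setNames(c(1L, 3L, 2L, 1L, 3L), tree5$tip.label)
  full <- compute_loglik(tree5, tips, sp2, p, "DEC", keep_cache = FALSE)$loglik
  rhos <- c(0.9, 0.99, 0.999, 0.9999)
  lls <- vapply(rhos, function(r)
    compute_loglik(tree5, tips, sp2, p, "DEC", keep_cache = FALSE,
                   options = likelihood_options(rho = r))$loglik, numeric(1))
  gaps <- abs(lls - full)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 1e-2)
})

test_that("input validation catches broken trees and missing ranges", {
  p <- rate_params(0.3, 0.2, 0.1, 0.05, 0)
  poly <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_error(compute_loglik(poly, tips3, sp2, p, "DEC"), "polytomy")
  neg <- tree3; neg$edge.length[2] <- -0.1
  expect_error(compute_loglik(neg, tips3, sp2, p, "DEC"), "negative")
  expect_error(compute_loglik(tree3, tips3[1:2], sp2, p, "DEC"), "missing")
  nonum <- ape::read.tree(text = "((a,b),c);")
  expect_error(compute_loglik(nonum, tips3, sp2, p, "DEC"), "branch lengths")
  ## near-ultrametric trees warn rather than fail
  wob <- tree3
  wob$edge.length[1] <- wob$edge.length[1] + 0.05
  expect_warning(compute_loglik(wob, tips3, sp2, p, "DEC",
                                keep_cache = FALSE), "ultrametric")
})
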