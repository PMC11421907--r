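# Marginal ancestral reconstruction (up/down pass vs clamp oracle),
# origin summaries and richness-through-time profiles.

test_that("up/down-pass marginals equal the clamp-and-renormalise oracle", {
  set.seed(81)
  for (rep in 1:4) {
    p <- rand_params()
    mg <- node_marginals(tree3, tips3, sp2, p, "DEC")
    or <- marginals_by_clamping(tree3, tips3, sp2, p, "DEC")
    expect_lt(max(abs(mg$prob[4:5, ] - or$prob)), 1e-8)
    ## clamped likelihoods sum to the unclamped likelihood
    expect_lt(max(abs(or$clamp_logsum - or$loglik)), 1e-9 * abs(or$loglik))
    ## rows normalised
    expect_equal(unname(rowSums(mg$prob)), rep(1, nrow(mg$prob)),
                 tolerance = 1e-9)
  }
})

test_that("marginals work identically through a DIVA model and 3 areas", {
  set.seed(82)
  tr <- tree5
  tips <- rand_tips(tr, sp3)
  p <- rand_params()
  mg <- node_marginals(tr, tips, sp3, p, "DIVA")
  or <- marginals_by_clamping(tr, tips, sp3, p, "DIVA")
  nodes <- 6:9
  expect_lt(max(abs(mg$prob[nodes, ] - or$prob)), 1e-8)
})

test_that("tips report their observed range with probability one", {
  p <- rand_params()
  mg <- node_marginals(tree3, tips3, sp2, p, "DEC")
  for (v in 1:3) {
    expect_equal(unname(mg$prob[v, tips3[tree3$tip.label[v]]]), 1)
  }
})

test_that("presence probabilities are sums over states containing the area", {
  p <- rate_params(0.3, 0.2, 0.1, 0.05, 0.1)
  mg <- node_marginals(tree3, tips3, sp2, p, "DEC")
  ## states: {A}, {B}, {A,B}
  expect_equal(unname(mg$presence[4, "A"]),
               unname(mg$prob[4, 1] + mg$prob[4, 3]))
  expect_equal(unname(mg$presence[4, "B"]),
               unname(mg$prob[4, 2] + mg$prob[4, 3]))
  expect_true(all(mg$presence >= 0 & mg$presence <= 1 + 1e-12))
})

test_that("strong dispersal flattens the root marginal", {
  tips <- setNames(c(1L, 1L, 2L), c("a", "b", "c"))
  maxp <- vapply(c(0.05, 0.5, 5), function(d) {
    p <- rate_params(0.3, 0.1, d, 0.01, 0)
    mg <- node_marginals(tree3, tips, sp2, p, "DEC")
    max(mg$prob[4, ])
  }, numeric(1))
  expect_true(all(diff(maxp) < 0))
})

test_that("origin thresholding and its modal fallback behave as documented", {
  p <- rand_params()
  mg <- node_marginals(tree3, tips3, sp2, p, "DEC")
  ## concentrated root
  mg1 <- mg
  mg1$prob[mg1$root, ] <- c(0.95, 0.03, 0.02)
  mg1$presence[mg1$root, ] <- c(0.97, 0.05)
  o <- ancestral_origin(mg1)
  expect_equal(o$origin, "A")
  expect_false(o$fallback)
  ## nothing passes: fall back to the modal state's areas
  mg2 <- mg
  mg2$prob[mg2$root, ] <- c(0.4, 0.35, 0.25)
  mg2$presence[mg2$root, ] <- c(0.45, 0.42)
  o2 <- ancestral_origin(mg2, threshold = 0.5)
  expect_true(o2$fallback)
  expect_equal(o2$origin, "A")
  expect_equal(o2$threshold, 0.5)
  ## threshold configurable
  o3 <- ancestral_origin(mg2, threshold = 0.4)
  expect_false(o3$fallback)
  expect_setequal(o3$origin, c("A", "B"))
})

test_that("the present-day richness slice equals observed tip tallies", {
  fx <- get_two_area_fixture()
  rich <- richness_through_time(fx$sim$tree, fx$sim$tip_states, fx$space,
                                fx$params, "DEC", n_slices = 40)
  obs <- tip_tallies(fx$space, fx$sim$tip_states)
  expect_equal(unname(rich$richness[40, ]), unname(as.numeric(obs)))
  expect_equal(rich$n_lineages[40], fx$sim$n_extant)
  expect_equal(rich$n_lineages[1], 2)   # the two crown lineages
  expect_true(all(rich$richness >= 0))
  ## every lineage occupies at least one area
  expect_true(all(rowSums(rich$richness) >= rich$n_lineages - 1e-9))
  ## and no more areas than it can hold
  expect_true(all(rich$richness <= rich$n_lineages + 1e-9))
})

test_that("mid-branch slice distributions match an inserted-node clamp", {
  ## 2-tip tree, one branch interval; clamp an inserted degree-2 node
  tr2 <- ape::read.tree(text = "(a:2,b:2);")
  tips2 <- setNames(c(1L, 3L), c("a", "b"))
  p <- rate_params(0.3, 0.2, 0.15, 0.08, 0.12)
  base <- compute_loglik(tr2, tips2, sp2, p, "DEC", keep_cache = FALSE)
  opts <- likelihood_options(root_weights = base$root_weights)
  at <- 0.85
  ins <- rangesse:::.insert_single(tr2, 1L, at)   # on the branch above tip a
  lls <- vapply(1:3, function(s)
    compute_loglik(ins$tree, tips2, sp2, p, "DEC", options = opts,
                   keep_cache = FALSE,
                   clamp = list(node = ins$node, state = s))$loglik,
    numeric(1))
  oracle <- exp(lls - max(lls)); oracle <- oracle / sum(oracle)

  rich <- richness_through_time(tr2, tips2, sp2, p, "DEC",
                                n_slices = 41)   # grid hits t = 0.85
  i <- which.min(abs(rich$times - at))
  expect_equal(rich$times[i], at, tolerance = 1e-9)
  ## slice expectation = sum over the two branches; recover branch "a" by
  ## subtracting the clamped distribution of branch "b"
  insb <- rangesse:::.insert_single(tr2, 2L, at)
  llsb <- vapply(1:3, function(s)
    compute_loglik(insb$tree, tips2, sp2, p, "DEC", options = opts,
                   keep_cache = FALSE,
                   clamp = list(node = insb$node, state = s))$loglik,
    numeric(1))
  orb <- exp(llsb - max(llsb)); orb <- orb / sum(orb)
  memb <- rbind(c(1, 0), c(0, 1), c(1, 1))
  expected <- as.vector(oracle %*% memb) + as.vector(orb %*% memb)
  expect_equal(unname(rich$richness[i, ]), expected, tolerance = 1e-6)
})

test_that("richness profiles change smoothly except at node times", {
  fx <- get_two_area_fixture()
  rich <- richness_through_time(fx$sim$tree, fx$sim$tip_states, fx$space,
                                fx$params, "DEC", n_slices = 60)
  tot <- rowSums(rich$richness)
  jumps <- abs(diff(tot))
  same_count <- diff(rich$n_lineages) == 0
  ## where the branch count does not change, the expectation moves little
  expect_lt(max(jumps[same_count]), 1)
  expect_error(richness_through_time(fx$sim$tree, fx$sim$tip_states,
                                     fx$space, fx$params, "DEC",
                                     n_slices = 1), "slices")
})

test_that("speciation-mode summary flattens the grid with rate ratios", {
  grid <- .cache$two_grid
  skip_if(is.null(grid), "grid fixture not built")
  tab <- speciation_mode_summary(grid)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$ratio_is_vic, tab$lambda_is / tab$lambda_vic)
  expect_true(is.logical(tab$ratio_unbounded))
  ## lossless TSV round trip
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(f)
  expect_equal(back$loglik, tab$loglik, tolerance = 1e-12)
  expect_equal(back$lambda_is, tab$lambda_is, tolerance = 1e-12)
  unlink(f)
})
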