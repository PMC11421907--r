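# Shared small fixtures, built in code. Heavier shared objects (the
# packaged synthetic dataset, the scenario pipeline on it) are memoised so
# several test files can reuse one computation.

sp1 <- state_space("A", 1)
sp2 <- state_space(c("A", "B"), 2)
sp3 <- state_space(c("A", "B", "C"), 3)

tree3 <- ape::read.tree(text = "((a:1,b:1):0.8,c:1.8);")
tips3 <- setNames(c(1L, 2L, 3L), c("a", "b", "c"))

tree5 <- ape::read.tree(text = "(((a:0.6,b:0.6):0.9,c:1.5):0.7,(d:1.1,e:1.1):1.1);")

rand_params <- function(mu = NULL) {
  rate_params(runif(1, 0.05, 0.5), runif(1, 0.05, 0.4),
              runif(1, 0.01, 0.3), runif(1, 0.01, 0.3),
              mu = if (is.null(mu)) runif(1, 0, 0.3) else mu)
}

rand_tips <- function(tree, space) {
  setNames(sample(space$n_states, length(tree$tip.label), replace = TRUE),
           tree$tip.label)
}

## memoised heavy fixtures
.cache <- new.env(parent = emptyenv())

get_iaa_fixture <- function() {
  if (is.null(.cache$iaa)) .cache$iaa <- make_fixture("iaa7_small")
  .cache$iaa
}

get_two_area_fixture <- function() {
  if (is.null(.cache$two)) .cache$two <- make_fixture("two_area_geosse")
  .cache$two
}

get_bd_fixture <- function() {
  if (is.null(.cache$bd1)) .cache$bd1 <- make_fixture("single_area_bd")
  .cache$bd1
}

## one scenario pipeline on the packaged dataset, shared by the protocol
## and structural tests (modest optimiser budget; tolerances at the
## documented robustness level)
get_iaa_pipeline <- function() {
  if (is.null(.cache$pipe)) {
    fx <- get_iaa_fixture()
    .cache$pipe <- run_pipeline(
      fx$sim$tree, fx$sim$tip_states, areas = fx$space$areas,
      max_range_size = fx$space$max_range_size, models = c("DEC", "DIVA"),
      seed = 11L, n_slices = 12L,
      settings = optimizer_settings(n_starts = 1L, seed = 11L),
      options = likelihood_options(rtol = 1e-6, atol = 1e-8))
  }
  .cache$pipe
}

## per-area observed tip tallies
tip_tallies <- function(space, tip_states) {
  memb <- sapply(seq_len(space$n_areas), function(a)
    vapply(space$sets, function(s) a %in% s, logical(1)))
  colSums(memb[tip_states, , drop = FALSE])
}
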