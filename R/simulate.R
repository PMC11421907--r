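.sim_memo <- new.env(parent = emptyenv())

# Forward simulation of the range-diversification process with exact
# competing exponential clocks (one hazard per lineage, recomputed after
# every event, implemented in the compiled core). The simulator shares the
# event tables with the likelihood, which is what makes it usable as a
# Monte-Carlo oracle for the likelihood itself.

#' Simulation configuration
#'
#' @param space A \code{range_space}.
#' @param params A \code{range_rates} (including the lineage extinction
#'   rate \code{mu}).
#' @param model \code{"DEC"} or \code{"DIVA"}.
#' @param root_state Integer state index of the crown/root ancestor, or
#'   \code{NULL} to draw uniformly among single-area states at each
#'   attempt (a widespread root should be a finding, not an assumption).
#' @param root_mode \code{"crown"} starts with a cladogenetic split of the
#'   root state at time 0 (two lineages); \code{"stem"} starts with a
#'   single lineage.
#' @param max_t Time horizon (Myr). The simulation stops at \code{max_t};
#'   extant lineages are cut there, giving an ultrametric tree.
#' @param max_extant Stop rule on standing diversity: the simulation stops
#'   just before the speciation that would exceed this count, and that
#'   event's time becomes the horizon. At least one of \code{max_t},
#'   \code{max_extant} must be finite.
#' @param min_survivors Condition (by rejection) on at least this many
#'   extant lineages at the horizon; the number of retries is reported.
#' @param max_tries Rejection budget.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(space, params, model = c("DEC", "DIVA"),
                       root_state = NULL, root_mode = c("crown", "stem"),
                       max_t = Inf, max_extant = Inf, min_survivors = 2L,
                       max_tries = 1000L) {
  model <- match.arg(model)
  root_mode <- match.arg(root_mode)
  if (!is.finite(max_t) && !is.finite(max_extant))
    stop("at least one of max_t and max_extant must be finite")
  if (!is.null(root_state)) {
    root_state <- as.integer(root_state)
    if (root_state < 1L || root_state > space$n_states)
      stop("root_state out of bounds")
  }
  structure(list(space = space, params = params, model = model,
                 root_state = root_state, root_mode = root_mode,
                 max_t = max_t, max_extant = max_extant,
                 min_survivors = as.integer(min_survivors),
                 max_tries = as.integer(max_tries)),
            class = "sim_config")
}

## per-state CSR event layout shared with the compiled Gillespie core;
## codes: 1 dispersal, 2 extirpation, 3 in-situ, 4 vicariance, 5 extinction
.sim_tables <- function(mod, params) {
  rt <- .model_rates(mod, params)
  n <- mod$space$n_states
  st <- c(mod$clado$parent, mod$ana$from, if (params$mu > 0) seq_len(n))
  code <- c(ifelse(mod$e_is, 3L, 4L),
            ifelse(mod$a_disp, 1L, 2L),
            if (params$mu > 0) rep(5L, n))
  rate <- c(rt$erate, rt$arate, if (params$mu > 0) rep(params$mu, n))
  a <- c(mod$clado$left, mod$ana$to, if (params$mu > 0) rep(NA_integer_, n))
  b <- c(mod$clado$right, rep(NA_integer_, nrow(mod$ana)),
         if (params$mu > 0) rep(NA_integer_, n))
  o <- order(st)
  sptr <- c(0L, cumsum(tabulate(st, nbins = n)))
  list(sptr = as.integer(sptr), code = code[o], rate = rate[o],
       a = ifelse(is.na(a[o]), 0L, a[o]), b = ifelse(is.na(b[o]), 0L, b[o]),
       rt = rt)
}

#' Forward-simulate the range diversification process
#'
#' Exact stochastic simulation: every lineage carries competing exponential
#' clocks for each in-situ event, vicariance event, dispersal move,
#' extirpation move (from the same tables as the likelihood) and for
#' whole-lineage extinction at rate \code{mu}. The attempt is retried until
#' the survivor condition holds. Returns the complete tree (including
#' extinct lineages), the pruned reconstructed tree of survivors, tip
#' ranges and a full event log.
#'
#' @param config A \code{sim_config}.
#' @param assemble If \code{FALSE}, skip building \code{phylo} trees and
#'   the event-log data frame and return the raw lineage records only --
#'   useful for high-volume Monte-Carlo calibration where only tip states
#'   and the genealogy are needed.
#' @return An object of class \code{sim_result} with elements
#'   \code{full_tree} (phylo; extinct tips end before the horizon),
#'   \code{tree} (reconstructed, survivors only; \code{NULL} if fewer than
#'   two), \code{tip_states} (named state indices of extant tips),
#'   \code{extinct_tips}, \code{events} (data frame log),
#'   \code{event_counts}, \code{lineages} (raw records),
#'   \code{root_state}, \code{crown_states}, \code{horizon},
#'   \code{truncated}, \code{retries} and the \code{config}.
#' @export
simulate_forward <- function(config, assemble = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  ## high-volume Monte-Carlo calibration calls this in a tight loop with a
  ## constant configuration; memoise the event tables for that case
  key <- paste(c(config$space$areas, config$space$max_range_size,
                 config$model, unlist(config$params)), collapse = "\r")
  if (identical(.sim_memo$key, key)) {
    mod <- .sim_memo$mod
    tb <- .sim_memo$tb
  } else {
    mod <- range_model(config$space, config$model)
    tb <- .sim_tables(mod, config$params)
    .sim_memo$key <- key
    .sim_memo$mod <- mod
    .sim_memo$tb <- tb
  }
  n <- config$space$n_states
  singles <- which(config$space$size == 1L)
  max_ext <- if (is.finite(config$max_extant))
    as.integer(config$max_extant) else .Machine$integer.max

  for (try in seq_len(config$max_tries)) {
    s0 <- if (is.null(config$root_state)) {
      if (length(singles) > 1L) sample(singles, 1L) else singles
    } else config$root_state
    if (config$root_mode == "crown") {
      rows <- which(mod$clado$parent == s0)
      pr <- tb$rt$erate[rows]
      ev <- if (length(rows) > 1L) sample(rows, 1L, prob = pr) else rows
      init <- c(mod$clado$left[ev], mod$clado$right[ev])
      crown_states <- init
    } else {
      init <- s0
      crown_states <- NULL
    }
    raw <- sim_core_cpp(n, tb$sptr, tb$code, tb$rate, tb$a, tb$b,
                        as.integer(init), config$max_t, max_ext, 500000L)
    if (raw$overflow) stop("simulation exceeded the record budget")
    if (raw$n_extant >= config$min_survivors) {
      if (!assemble)
        return(structure(list(raw = raw, root_state = s0,
                              crown_states = crown_states,
                              n_extant = raw$n_extant, retries = try,
                              horizon = raw$horizon, config = config),
                         class = "sim_result_raw"))
      res <- .assemble_sim(raw, config, s0, crown_states, try)
      return(res)
    }
  }
  stop("retry budget exhausted: the survivor condition was never met in ",
       config$max_tries, " attempts")
}

## build phylo trees, tip states and the event log from the raw records
.assemble_sim <- function(raw, config, root_state, crown_states, retries) {
  nrec <- length(raw$parent)
  status <- raw$status
  horizon <- raw$horizon
  if (!is.finite(horizon)) stop("simulation never advanced (all rates zero?)")
  is_internal <- status == 2L
  leaves <- which(!is_internal)
  ntip <- length(leaves)
  crown_mode <- config$root_mode == "crown"

  tip_id <- integer(nrec)
  tip_id[leaves] <- seq_len(ntip)
  labels <- paste0("t", leaves)

  ## internal junctions: records that speciated, plus (crown mode) the
  ## virtual record 0 at time 0; ordered by time so the root comes first
  internals <- which(is_internal)
  jt <- raw$t_end[internals]
  if (crown_mode) {
    jorder <- c(0L, internals[order(jt)])
  } else {
    jorder <- internals[order(jt)]
  }
  jid <- integer(nrec + 1L)                 # index 1 = virtual record 0
  for (i in seq_along(jorder)) jid[jorder[i] + 1L] <- ntip + i

  edge <- matrix(0L, 0, 2)
  elen <- numeric(0)
  root_edge <- NULL
  for (r in seq_len(nrec)) {
    par <- raw$parent[r]
    child_node <- if (is_internal[r]) jid[r + 1L] else tip_id[r]
    len <- raw$t_end[r] - raw$t_birth[r]
    if (par == 0L && !crown_mode) {
      ## stem edge: hangs below the root node (this record's junction)
      if (is_internal[r]) root_edge <- len
      next
    }
    pnode <- jid[par + 1L]
    edge <- rbind(edge, c(pnode, child_node))
    elen <- c(elen, len)
  }
  nnode <- length(jorder)
  storage.mode(edge) <- "integer"
  full <- structure(list(edge = edge, edge.length = elen,
                         tip.label = labels, Nnode = nnode),
                    class = "phylo")
  if (!is.null(root_edge)) full$root.edge <- root_edge
  full <- stats::reorder(full, "postorder")

  extant <- leaves[status[leaves] == 1L]
  tip_states <- setNames(raw$state_end[extant], paste0("t", extant))
  extinct_lab <- setdiff(labels, names(tip_states))

  recon <- NULL
  if (length(extant) >= 2L) {
    recon <- if (length(extinct_lab)) ape::drop.tip(full, extinct_lab)
             else full
    recon$root.edge <- NULL
  }

  kinds <- c("dispersal", "extirpation", "in_situ", "vicariance", "extinction")
  events <- data.frame(
    time = raw$log_t, lineage = raw$log_lineage,
    kind = kinds[raw$log_code],
    from_state = raw$log_from, left_state = raw$log_left,
    right_state = raw$log_right, stringsAsFactors = FALSE)
  counts <- table(factor(events$kind, levels = kinds))

  structure(list(
    full_tree = full, tree = recon, tip_states = tip_states,
    extinct_tips = extinct_lab, events = events,
    event_counts = as.integer(counts) |> setNames(kinds),
    lineages = data.frame(id = seq_len(nrec), parent = raw$parent,
                          t_birth = raw$t_birth, t_end = raw$t_end,
                          status = status, state_birth = raw$state_birth,
                          state_end = raw$state_end),
    root_state = root_state, crown_states = crown_states,
    horizon = horizon, truncated = raw$truncated, retries = retries,
    n_extant = length(extant), config = config),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "Forward simulation: %d lineages total, %d extant, horizon %.3g Myr (%d attempt%s)\n",
    nrow(x$lineages), x$n_extant, x$horizon, x$retries,
    if (x$retries > 1) "s" else ""))
  cat("Events:", paste(names(x$event_counts), x$event_counts,
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Prune extinct lineages from a complete tree
#'
#' Removes extinct leaves and suppresses the resulting unbranched nodes,
#' merging branch lengths, to yield the reconstructed tree of survivors.
#' Extant tip labels and all pairwise divergence times among survivors are
#' preserved.
#'
#' @param tree A \code{phylo}, or a \code{sim_result} (in which case the
#'   extinct tip set is taken from it).
#' @param extinct Character vector of extinct tip labels (ignored for a
#'   \code{sim_result}).
#' @return The pruned \code{phylo} (crown-rooted; any stem edge is
#'   dropped).
#' @export
prune_extinct <- function(tree, extinct = NULL) {
  if (inherits(tree, "sim_result")) {
    extinct <- tree$extinct_tips
    tree <- tree$full_tree
  }
  n_left <- length(setdiff(tree$tip.label, extinct))
  if (n_left == 0L) stop("all lineages are extinct; nothing to reconstruct")
  if (n_left == 1L) stop("fewer than two survivors; no reconstructed tree")
  out <- if (length(extinct)) ape::drop.tip(tree, extinct) else tree
  out$root.edge <- NULL
  out
}

## true state at each internal node of the reconstructed tree, from the
## simulation's genealogy (the state of the ancestral lineage at the
## moment of the corresponding speciation). The reconstructed root maps to
## the crown split; in crown mode its parent state is the configured root
## state.
.true_node_states <- function(sim, nodes = NULL) {
  if (is.null(sim$tree)) stop("no reconstructed tree in this simulation")
  if (inherits(sim, "sim_result_raw"))
    stop("true node states need an assembled simulation result")
  lin <- sim$lineages
  ## ancestor path (record ids, ending in 0) for each record
  path <- function(r) {
    out <- integer(0)
    while (r != 0L) { out <- c(out, r); r <- lin$parent[r] }
    c(out, 0L)
  }
  t_end <- c(0, lin$t_end)            # index shifted by 1; record 0 at t=0
  state_end <- c(sim$root_state, lin$state_end)
  tre <- sim$tree
  ntip <- length(tre$tip.label)
  tip_rec <- as.integer(sub("^t", "", tre$tip.label))
  tip_paths <- lapply(tip_rec, path)
  if (is.null(nodes)) nodes <- ntip + seq_len(tre$Nnode)
  st <- setNames(integer(length(nodes)), nodes)
  tm <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    ## the MRCA of two tips spanning both daughter clades is the MRCA of
    ## the whole clade, so one representative per side suffices
    kids <- tre$edge[tre$edge[, 1] == v, 2]
    rep_tips <- c(.tips_below(tre, kids[1])[1], .tips_below(tre, kids[2])[1])
    common <- intersect(tip_paths[[rep_tips[1]]], tip_paths[[rep_tips[2]]])
    mrca <- common[which.max(t_end[common + 1L])]
    st[i] <- state_end[mrca + 1L]
    tm[i] <- t_end[mrca + 1L]
  }
  list(state = st, time = tm)
}

## tip indices descending from node v
.tips_below <- function(tree, v) {
  ntip <- length(tree$tip.label)
  if (v <= ntip) return(v)
  kids <- tree$edge[tree$edge[, 1] == v, 2]
  unlist(lapply(kids, .tips_below, tree = tree))
}

#' Packaged synthetic datasets
#'
#' Deterministic synthetic datasets generated by the forward simulator
#' under fixed seeds, used throughout the tests and examples. Available
#' presets:
#' \describe{
#'   \item{\code{"iaa7_small"}}{7 areas named after the Indo-Australian
#'     Archipelago landmasses, range-size cap 3, a clade of a few dozen
#'     extant species over a 45-Myr horizon, simulated with non-zero
#'     lineage extinction; tip ranges are mostly of size 1-2, emulating
#'     the empirical datasets this kind of analysis targets.}
#'   \item{\code{"two_area_geosse"}}{two areas, cap 2 -- the classic
#'     three-state geographic SSE setting.}
#'   \item{\code{"single_area_bd"}}{one area: the process collapses to a
#'     constant-rate birth-death tree.}
#' }
#'
#' @param preset Preset name.
#' @param dir Optional directory; if given, writes \code{tree.nwk},
#'   \code{full_tree.nwk}, \code{ranges.tsv} and \code{truth.json} there.
#' @return List with \code{sim} (the \code{sim_result}), \code{space},
#'   \code{params}, \code{model} and \code{truth} (generating parameters,
#'   seed, root state and true states at the reconstructed tree's internal
#'   nodes).
#' @export
make_fixture <- function(preset = c("iaa7_small", "two_area_geosse",
                                    "single_area_bd"),
                         dir = NULL) {
  preset <- match.arg(preset)
  iaa <- c("Borneo", "Sulawesi", "Sumatra", "Java", "Philippines",
           "NewGuinea", "SEAsia")
  spec <- switch(preset,
    iaa7_small = list(
      space = state_space(iaa, 3L),
      params = rate_params(0.12, 0.03, 0.01, 0.03, mu = 0.06),
      model = "DEC", max_t = 45, max_extant = 300, min_survivors = 40,
      max_survivors = 90, seed = 104729L),
    two_area_geosse = list(
      space = state_space(c("A", "B"), 2L),
      params = rate_params(0.3, 0.2, 0.1, 0.05, mu = 0.1),
      model = "DEC", max_t = 10, max_extant = 200, min_survivors = 10,
      seed = 9173L),
    single_area_bd = list(
      space = state_space("A", 1L),
      params = rate_params(0.2, 0, 0, 0, mu = 0.05),
      model = "DEC", max_t = 25, max_extant = 400, min_survivors = 10,
      seed = 5501L))

  cfg <- sim_config(spec$space, spec$params, model = spec$model,
                    max_t = spec$max_t, max_extant = spec$max_extant,
                    min_survivors = spec$min_survivors, max_tries = 2000L)
  max_surv <- spec$max_survivors %||% Inf
  sim <- .with_seed(spec$seed, function() {
    for (i in 1:200) {
      s <- simulate_forward(cfg)
      if (s$n_extant <= max_surv) return(s)
    }
    stop("could not meet the clade-size window for this preset")
  })
  truth_nodes <- .true_node_states(sim)
  truth <- list(preset = preset, seed = spec$seed,
                params = unclass(spec$params), model = spec$model,
                areas = spec$space$areas,
                max_range_size = spec$space$max_range_size,
                root_state = sim$root_state,
                root_state_label = spec$space$labels[sim$root_state],
                horizon = sim$horizon,
                node_states = as.list(truth_nodes$state),
                node_times = as.list(truth_nodes$time),
                tip_states = as.list(sim$tip_states))
  out <- list(sim = sim, space = spec$space, params = spec$params,
              model = spec$model, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
    ape::write.tree(sim$full_tree, file.path(dir, "full_tree.nwk"))
    write_range_table(sim$tip_states, spec$space,
                      file.path(dir, "ranges.tsv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
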