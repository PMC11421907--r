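`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal model and tree caches shared by the likelihood, the optimizer,
# the reconstruction machinery and the simulator. Tables are built once per
# model; only the per-entry rate vectors are recomputed when parameters
# change.

#' Precompiled model structure
#'
#' Bundles a state space with its anagenetic and cladogenetic tables plus
#' 0-based index vectors ready for the compiled ODE core. Building this
#' once and passing it to repeated likelihood evaluations avoids
#' re-enumerating the tables.
#'
#' @param space A \code{range_space}.
#' @param model \code{"DEC"} or \code{"DIVA"}.
#' @return An object of class \code{range_model}.
#' @export
range_model <- function(space, model = c("DEC", "DIVA")) {
  model <- match.arg(model)
  ana <- anagenetic_table(space)
  cla <- clado_table(space, model)
  structure(list(
    space = space,
    model = model,
    ana = ana,
    clado = cla,
    a_from0 = ana$from - 1L,
    a_to0 = ana$to - 1L,
    a_disp = ana$kind == "dispersal",
    a_mult = ana$multiplicity,
    e_p0 = cla$parent - 1L,
    e_j0 = cla$left - 1L,
    e_k0 = cla$right - 1L,
    e_is = cla$kind == "in_situ",
    e_mult = cla$multiplicity
  ), class = "range_model")
}

## per-entry rates and per-state totals for a parameter set
.model_rates <- function(mod, params) {
  n <- mod$space$n_states
  arate <- ifelse(mod$a_disp, params$d, params$e) * mod$a_mult
  erate <- ifelse(mod$e_is, params$lambda_is, params$lambda_vic) * mod$e_mult
  qtot <- numeric(n)
  if (length(arate)) {
    agg <- rowsum(arate, mod$a_from0)
    qtot[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  lamtot <- numeric(n)
  if (length(erate)) {
    agg <- rowsum(erate, mod$e_p0)
    lamtot[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  list(arate = arate, erate = erate, qtot = qtot, lamtot = lamtot,
       tot = qtot + lamtot, mu = params$mu)
}

## validated, postorder-sorted tree structure with node times
## (t = 0 at the youngest tip, increasing toward the root)
.tree_data <- function(tree, allow_singles = FALSE) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths are not allowed")
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 tips")
  deg <- tabulate(tree$edge[, 1], nbins = ntip + tree$Nnode)
  if (any(deg > 2L)) {
    bad <- which(deg > 2L)
    stop("tree is not binary: polytomy at internal node(s) ",
         paste(bad, collapse = ", "))
  }
  if (!allow_singles && any(deg == 1L)) {
    bad <- which(deg == 1L)
    stop("tree has unbranched (degree-2) internal node(s) ",
         paste(bad, collapse = ", "))
  }
  tree <- stats::reorder(tree, "postorder")
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(ntip)])
  tnode <- height - depth
  dev <- max(abs(tnode[seq_len(ntip)]))
  if (height > 0 && dev > 1e-3 * height)
    warning(sprintf(
      "tree deviates from ultrametric by %.3g (%.2f%% of tree height)",
      dev, 100 * dev / height))
  kids <- vector("list", ntip + tree$Nnode)
  for (r in seq_len(nrow(tree$edge)))
    kids[[tree$edge[r, 1]]] <- c(kids[[tree$edge[r, 1]]], tree$edge[r, 2])
  list(tree = tree, ntip = ntip, n_nodes = ntip + tree$Nnode,
       root = ntip + 1L, t_node = tnode, height = height, kids = kids,
       edge = tree$edge, edge_length = tree$edge.length)
}

## resolve tip ranges into a named integer state vector covering the tree
.tip_state_vector <- function(tip_ranges, tree, space) {
  labs <- tree$tip.label
  if (is.character(tip_ranges) && !is.null(names(tip_ranges))) {
    tip_ranges <- vapply(tip_ranges, parse_range, integer(1), space = space)
  }
  if (is.null(names(tip_ranges))) stop("tip ranges must be named by tip label")
  miss <- setdiff(labs, names(tip_ranges))
  if (length(miss))
    stop("missing range for tip(s): ", paste(miss, collapse = ", "))
  st <- as.integer(tip_ranges[labs])
  if (any(is.na(st) | st < 1L | st > space$n_states))
    stop("tip ranges contain invalid state indices")
  names(st) <- labs
  st
}
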