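# Marginal ancestral reconstruction via an up-pass (pruning) and a
# down-pass (adjoint propagation of the rest-of-tree partials G). For any
# point on the tree, the marginal state distribution is proportional to
# D(t) * G(t): D carries the subtree below the point, G the remainder of
# the tree plus the (fixed) root weighting. Clamping a node to a state and
# renormalising gives exactly the same quantity because the likelihood is
# linear in the node's D vector; the brute-force clamp implementation in
# marginals_by_clamping() is the reference oracle for this machinery.

## resolve (tree, tip_ranges, space, params, model) from either explicit
## arguments or a fitted range_fit object
.recon_args <- function(tree, tip_ranges, space, params, model) {
  if (inherits(tree, "range_fit")) {
    fit <- tree
    list(tree = fit$tree, tip_ranges = fit$tip_states, space = fit$space,
         params = fit$params, model = fit$model)
  } else {
    list(tree = tree, tip_ranges = tip_ranges, space = space,
         params = params, model = model)
  }
}

## full up+down pass; returns all per-node partials
.flow <- function(td, mod, params, options, tip_states) {
  n <- mod$space$n_states
  up <- .pruning_pass(td, mod, params, options, keep_cache = TRUE,
                      tip_states = tip_states)
  if (!is.finite(up$loglik))
    stop("likelihood vanished at the supplied parameters; cannot reconstruct")
  rt <- up$cache$rt
  nn <- td$n_nodes
  G_node <- matrix(NA_real_, n, nn)   # G at the young end (node itself)
  G_top <- matrix(NA_real_, n, nn)    # G at the old end of the node's branch
  w <- up$root_weights
  G_node[, td$root] <- w

  ev_p <- mod$e_p0 + 1L; ev_j <- mod$e_j0 + 1L; ev_k <- mod$e_k0 + 1L
  sym <- ev_j == ev_k
  ne <- nrow(td$edge)
  for (r in rev(seq_len(ne))) {       # parents before children
    p <- td$edge[r, 1]; child <- td$edge[r, 2]
    ch <- td$kids[[p]]
    gp <- G_node[, p]
    if (length(ch) == 2L) {
      sib <- ch[ch != child]
      Ds <- up$cache$D_top[, sib]
      contrib <- rt$erate * gp[ev_p]
      gt <- as.vector(rowsum(c(contrib * Ds[ev_k], numeric(n)), c(ev_j, 1:n)))
      extra <- contrib * Ds[ev_j]
      extra[sym] <- 0
      gt <- gt + as.vector(rowsum(c(extra, numeric(n)), c(ev_k, 1:n)))
    } else {
      gt <- gp                        # pass-through node
    }
    m <- max(gt)
    if (m > 0) gt <- gt / m
    G_top[, child] <- gt
    out <- branch_ode_cpp(c(up$cache$E_top[, child], gt), td$edge_length[r],
                          rt$mu, mod$a_from0, mod$a_to0, rt$arate,
                          mod$e_p0, mod$e_j0, mod$e_k0, rt$erate,
                          rt$tot, options$rtol, options$atol, TRUE)
    g <- out$y[n + seq_len(n)]
    m <- max(g)
    if (m > 0) g <- g / m
    G_node[, child] <- g
  }
  list(up = up, G_node = G_node, G_top = G_top, rt = rt, w = w)
}

## states x areas membership indicator of a space
.membership <- function(space) {
  M <- matrix(0, space$n_states, space$n_areas,
              dimnames = list(space$labels, space$areas))
  for (i in seq_len(space$n_states)) M[i, space$sets[[i]]] <- 1
  M
}

#' Marginal ancestral-range probabilities at every node
#'
#' For each node, the marginal posterior probability of every range state,
#' defined as the renormalised likelihood obtained by clamping the node to
#' that state (with root weights held fixed at the values of the unclamped
#' run). Computed efficiently with a single up-pass and a single adjoint
#' down-pass rather than by repeated clamping. Tips report their observed
#' range with probability 1.
#'
#' @param tree A \code{phylo} tree, or a fitted \code{range_fit} (in which
#'   case the remaining arguments are taken from the fit).
#' @inheritParams compute_loglik
#' @return An object of class \code{range_marginals}: \code{prob} (nodes x
#'   states matrix; all nodes in ape numbering, tips first), \code{presence}
#'   (nodes x areas matrix of per-area presence probabilities),
#'   \code{nodes} data frame mapping ape node ids to the documented
#'   post-order numbering, plus the inputs.
#' @export
node_marginals <- function(tree, tip_ranges = NULL, space = NULL,
                           params = NULL, model = c("DEC", "DIVA"),
                           options = likelihood_options()) {
  a <- .recon_args(tree, tip_ranges, space, params, model)
  mod <- if (inherits(a$model, "range_model")) a$model
         else range_model(a$space, match.arg(a$model, c("DEC", "DIVA")))
  td <- .tree_data(a$tree)
  st <- .tip_state_vector(a$tip_ranges, td$tree, a$space)
  fl <- .flow(td, mod, a$params, options, st)
  n <- a$space$n_states
  nn <- td$n_nodes
  prob <- matrix(0, nn, n, dimnames = list(seq_len(nn), a$space$labels))
  for (v in seq_len(td$ntip)) prob[v, st[v]] <- 1
  for (v in (td$ntip + 1L):nn) {
    pv <- fl$up$cache$D_base[, v] * fl$G_node[, v]
    s <- sum(pv)
    if (s <= 0) stop("degenerate marginal at node ", v)
    prob[v, ] <- pv / s
  }
  post <- data.frame(node = td$edge[, 2], postorder = seq_len(nrow(td$edge)))
  post <- rbind(post, data.frame(node = td$root,
                                 postorder = nrow(td$edge) + 1L))
  structure(list(prob = prob, presence = prob %*% .membership(a$space),
                 nodes = post[order(post$node), ],
                 loglik = fl$up$loglik, root = td$root, n_tips = td$ntip,
                 space = a$space, model = mod$model, params = a$params,
                 tree = td$tree),
            class = "range_marginals")
}

#' @export
print.range_marginals <- function(x, ...) {
  cat(sprintf("Marginal ancestral ranges: %d nodes, %d states (%s model)\n",
              nrow(x$prob), ncol(x$prob), x$model))
  r <- x$prob[x$root, ]
  top <- order(r, decreasing = TRUE)[1:min(3, length(r))]
  cat("Root: ", paste(sprintf("%s=%.3f", colnames(x$prob)[top], r[top]),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Geographic origin of the clade
#'
#' Summarises the root node's marginal distribution: the inferred origin is
#' the set of areas whose presence probability reaches the threshold; if no
#' area passes, the areas of the single most probable root state are
#' reported instead (flagged as a fallback). The full root distribution is
#' always retained alongside, since any thresholding rule is a reporting
#' convention, not part of the model.
#'
#' @param marginals A \code{range_marginals}.
#' @param threshold Presence-probability threshold (default 0.5).
#' @return An object of class \code{range_origin}.
#' @export
ancestral_origin <- function(marginals, threshold = 0.5) {
  if (!inherits(marginals, "range_marginals")) stop("need range_marginals")
  pres <- marginals$presence[marginals$root, ]
  rootp <- marginals$prob[marginals$root, ]
  origin <- names(pres)[pres >= threshold]
  fallback <- length(origin) == 0L
  if (fallback) {
    best <- which.max(rootp)
    origin <- marginals$space$areas[marginals$space$sets[[best]]]
  }
  structure(list(origin = origin, fallback = fallback,
                 threshold = threshold, presence = pres,
                 root_state_probs = rootp,
                 modal_state = which.max(rootp)),
            class = "range_origin")
}

#' @export
print.range_origin <- function(x, ...) {
  cat("Inferred ancestral origin:", paste(x$origin, collapse = " + "),
      if (x$fallback) "(modal-state fallback; no area passed the threshold)"
      else sprintf("(presence probability >= %.2f)", x$threshold), "\n")
  invisible(x)
}

#' Expected per-area species richness through time
#'
#' For a uniform grid of time slices from the root age to the present, and
#' for every branch of the reconstructed tree crossing a slice, computes
#' the branch's conditional range distribution at that time (by evaluating
#' D(t) * G(t) at an implicit degree-2 point, exactly equivalent to
#' clamping an inserted node there) and accumulates per-area presence
#' probabilities. The slice at the present equals the observed per-area tip
#' tallies; richness at older slices is an expectation over reconstructed
#' (sampled, surviving) lineages only -- extinct unsampled lineages shape
#' the probabilities through the model but are not tallied.
#'
#' @inheritParams node_marginals
#' @param n_slices Number of time slices (>= 2, default 100).
#' @return An object of class \code{range_richness}: \code{times} (ages,
#'   root to present), \code{richness} (slices x areas matrix of expected
#'   lineage counts), \code{n_lineages} (branches alive per slice).
#' @export
richness_through_time <- function(tree, tip_ranges = NULL, space = NULL,
                                  params = NULL, model = c("DEC", "DIVA"),
                                  options = likelihood_options(),
                                  n_slices = 100L) {
  if (n_slices < 2L) stop("need at least 2 time slices")
  a <- .recon_args(tree, tip_ranges, space, params, model)
  mod <- if (inherits(a$model, "range_model")) a$model
         else range_model(a$space, match.arg(a$model, c("DEC", "DIVA")))
  td <- .tree_data(a$tree)
  st <- .tip_state_vector(a$tip_ranges, td$tree, a$space)
  fl <- .flow(td, mod, a$params, options, st)
  n <- a$space$n_states
  memb <- .membership(a$space)
  times <- seq(td$height, 0, length.out = n_slices)
  rich <- matrix(0, n_slices, a$space$n_areas,
                 dimnames = list(signif(times, 8), a$space$areas))
  count <- integer(n_slices)
  eps <- 1e-9 * max(td$height, 1)
  rt <- fl$rt

  step <- function(y, len, adjoint) {
    out <- branch_ode_cpp(y, len, rt$mu, mod$a_from0, mod$a_to0, rt$arate,
                          mod$e_p0, mod$e_j0, mod$e_k0, rt$erate, rt$tot,
                          options$rtol, options$atol, adjoint)
    y <- out$y
    m <- max(abs(y[n + seq_len(n)]))
    if (m > 0) y[n + seq_len(n)] <- y[n + seq_len(n)] / m
    y
  }

  for (r in seq_len(nrow(td$edge))) {
    p <- td$edge[r, 1]; child <- td$edge[r, 2]
    ty <- td$t_node[child]; to <- td$t_node[p]
    sel <- which(times >= ty - eps & times < to - eps)
    if (p == td$root) sel <- union(sel, which(abs(times - to) <= eps))
    if (!length(sel)) next
    ts <- times[sel]
    ord <- order(ts)
    ## D(t): integrate upward from the branch base, visiting times ascending
    Dt <- matrix(NA_real_, n, length(ts))
    y <- c(fl$up$cache$E_base[, child], fl$up$cache$D_base[, child])
    cur <- ty
    for (ii in ord) {
      y <- step(y, ts[ii] - cur, FALSE)
      cur <- ts[ii]
      Dt[, ii] <- y[n + seq_len(n)]
    }
    ## G(t): adjoint integrate downward from the branch top, descending
    Gt <- matrix(NA_real_, n, length(ts))
    y <- c(fl$up$cache$E_top[, child], fl$G_top[, child])
    cur <- to
    for (ii in rev(ord)) {
      y <- step(y, cur - ts[ii], TRUE)
      cur <- ts[ii]
      Gt[, ii] <- y[n + seq_len(n)]
    }
    for (ii in seq_along(ts)) {
      i_slice <- sel[ii]
      if (child <= td$ntip && abs(ts[ii] - 0) <= eps) {
        pv <- numeric(n); pv[st[child]] <- 1       # observed tip range
      } else {
        pv <- Dt[, ii] * Gt[, ii]
        s <- sum(pv)
        if (s <= 0) stop("degenerate slice distribution on edge ", r)
        pv <- pv / s
      }
      rich[i_slice, ] <- rich[i_slice, ] + as.vector(pv %*% memb)
      count[i_slice] <- count[i_slice] + 1L
    }
  }
  structure(list(times = times, richness = rich, n_lineages = count,
                 space = a$space, model = mod$model, params = a$params),
            class = "range_richness")
}

#' @export
print.range_richness <- function(x, ...) {
  cat(sprintf(
    "Expected per-area richness: %d slices from %.3g to 0, %d areas\n",
    length(x$times), max(x$times), ncol(x$richness)))
  invisible(x)
}

#' Speciation-mode and range-evolution rate summary across scenarios
#'
#' Flattens a scenario grid into one row per (extinction level, model
#' variant) cell with the fitted rates and the in-situ/vicariance rate
#' ratio -- the quantity behind the observation that the contribution of
#' in-situ speciation grows with the assumed extinction rate. The ratio is
#' flagged (not asserted) as unbounded when the vicariance rate sits at the
#' optimiser's lower bound.
#'
#' @param grid A \code{range_scenarios}.
#' @return Data frame, one row per grid cell.
#' @export
speciation_mode_summary <- function(grid) {
  if (!inherits(grid, "range_scenarios")) stop("need a range_scenarios object")
  rows <- list()
  for (lev in names(grid$mu_levels)) {
    for (m in grid$models) {
      f <- grid$fits[[lev]][[m]]
      vic_at_bound <- isTRUE(f$at_lower[2])
      rows[[length(rows) + 1L]] <- data.frame(
        mu_level = lev, mu = grid$mu_levels[[lev]], model = m,
        loglik = f$loglik,
        lambda_is = f$params$lambda_is, lambda_vic = f$params$lambda_vic,
        d = f$params$d, e = f$params$e,
        ratio_is_vic = f$params$lambda_is / f$params$lambda_vic,
        ratio_unbounded = vic_at_bound,
        converged = f$convergence,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
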