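#' Likelihood computation options
#'
#' @param root_weighting How root states are weighted when assembling the
#'   likelihood: \code{"data"} uses data-proportional (FitzJohn) weights
#'   \code{w_i = D_i / sum_j D_j}; \code{"uniform"} weights all states
#'   equally. Ignored when \code{root_weights} is supplied.
#' @param condition_on_survival If \code{TRUE} (default) the root likelihood
#'   is divided by \code{sum_i w_i (1 - E_i)^2}, conditioning on both root
#'   daughter lineages leaving sampled descendants.
#' @param rho Sampling fraction of extant species in (0, 1]. Tips are
#'   initialised with \code{D = rho} on the observed state and
#'   \code{E = 1 - rho} everywhere.
#' @param rtol,atol Relative and absolute tolerances of the adaptive branch
#'   integrator.
#' @param root_weights Optional fixed numeric weight vector over states,
#'   overriding \code{root_weighting}. Used by the marginal-reconstruction
#'   machinery, which must hold root weights fixed across clamped
#'   evaluations.
#' @return An object of class \code{range_lik_options}.
#' @export
likelihood_options <- function(root_weighting = c("data", "uniform"),
                               condition_on_survival = TRUE,
                               rho = 1,
                               rtol = 1e-8, atol = 1e-10,
                               root_weights = NULL) {
  root_weighting <- match.arg(root_weighting)
  if (!(rho > 0 && rho <= 1)) stop("rho must be in (0, 1]")
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0")
  structure(list(root_weighting = root_weighting,
                 condition_on_survival = isTRUE(condition_on_survival),
                 rho = rho, rtol = rtol, atol = atol,
                 root_weights = root_weights),
            class = "range_lik_options")
}

#' Time derivatives of the extinction and data partial vectors
#'
#' Reference (pure R) implementation of the right-hand side of the coupled
#' ODE system propagated along branches: per state i with total
#' cladogenesis rate L_i, total anagenetic out-rate Q_i and lineage
#' extinction rate mu,
#' \deqn{dE_i/dt = \mu - (L_i + Q_i + \mu) E_i + \sum_j q_{ij} E_j +
#'   \sum_{(i \to j,k)} \lambda_e E_j E_k}
#' \deqn{dD_i/dt = -(L_i + Q_i + \mu) D_i + \sum_j q_{ij} D_j +
#'   \sum_{(i \to j,k)} \lambda_e (D_j E_k + D_k E_j)}
#' Extinction enters every state identically: a lineage dies across its
#' whole range at rate mu regardless of range size. The compiled branch
#' integrator implements the same equations; this function is exposed for
#' inspection and cross-checking.
#'
#' @param E,D Numeric vectors of per-state extinction and data partials.
#' @param params A \code{range_rates} object.
#' @param model A \code{range_model} (from [range_model()]).
#' @return List with components \code{dE} and \code{dD}.
#' @export
ode_rhs <- function(E, D, params, model) {
  n <- model$space$n_states
  if (length(E) != n || length(D) != n) stop("partial vectors have wrong length")
  rt <- .model_rates(model, params)
  a <- rt$tot + rt$mu
  dE <- rt$mu - a * E
  dD <- -a * D
  f <- model$a_from0 + 1L; tt <- model$a_to0 + 1L
  if (length(f)) {
    dE <- dE + as.vector(rowsum(c(rt$arate * E[tt], numeric(n)), c(f, 1:n)))
    dD <- dD + as.vector(rowsum(c(rt$arate * D[tt], numeric(n)), c(f, 1:n)))
  }
  p <- model$e_p0 + 1L; j <- model$e_j0 + 1L; k <- model$e_k0 + 1L
  if (length(p)) {
    dE <- dE + as.vector(rowsum(c(rt$erate * E[j] * E[k], numeric(n)), c(p, 1:n)))
    dD <- dD + as.vector(rowsum(c(rt$erate * (D[j] * E[k] + D[k] * E[j]),
                                  numeric(n)), c(p, 1:n)))
  }
  list(dE = dE, dD = dD)
}

#' Integrate the partial vectors along one branch
#'
#' Propagates \code{(E, D)} from the young end of a branch to its old end
#' with the adaptive compiled integrator. The D block is rescaled during
#' integration if it threatens to under- or overflow; the accumulated
#' natural-log scaler is returned so that \code{exp(dlog) * D} recovers the
#' unscaled partials.
#'
#' @param E,D Partial vectors at the young end.
#' @param length Branch duration (>= 0); 0 returns the input unchanged.
#' @param params A \code{range_rates}.
#' @param model A \code{range_model}.
#' @param options A \code{range_lik_options} (tolerances are used).
#' @return List with \code{E}, \code{D}, \code{dlog}.
#' @export
integrate_branch <- function(E, D, length, params, model,
                             options = likelihood_options()) {
  if (length < 0) stop("branch length must be >= 0")
  rt <- .model_rates(model, params)
  out <- branch_ode_cpp(c(E, D), length, rt$mu,
                        model$a_from0, model$a_to0, rt$arate,
                        model$e_p0, model$e_j0, model$e_k0, rt$erate,
                        rt$tot, options$rtol, options$atol, FALSE)
  n <- model$space$n_states
  list(E = out$y[seq_len(n)], D = out$y[n + seq_len(n)], dlog = out$dlog)
}

#' Combine daughter partials at an internal node
#'
#' Applies the cladogenetic event table at a speciation node:
#' \deqn{D_{parent,i} = \sum_{(i \to j,k)} \lambda_e (D_{L,j} D_{R,k} +
#'   D_{L,k} D_{R,j})}
#' with the symmetric case j = k counted once as
#' \code{lambda_e * D_L,j * D_R,j}. E passes through unchanged (averaged);
#' the daughters' E vectors must agree, as they describe the same time
#' slice.
#'
#' @param E_left,D_left,E_right,D_right Daughter partials at the node.
#' @param params A \code{range_rates}.
#' @param model A \code{range_model}.
#' @param e_tol Warn if daughter E vectors disagree by more than this.
#' @return List with \code{E} and \code{D} for the base of the parent
#'   branch.
#' @export
combine_at_node <- function(E_left, D_left, E_right, D_right, params, model,
                            e_tol = 1e-4) {
  dev <- max(abs(E_left - E_right))
  if (dev > e_tol)
    warning(sprintf("daughter E vectors disagree by %.3g at a node", dev))
  rt <- .model_rates(model, params)
  D <- .combine_D(D_left, D_right, model, rt)
  list(E = (E_left + E_right) / 2, D = D)
}

## node combination of D only (internal, rates precomputed)
.combine_D <- function(DL, DR, mod, rt) {
  n <- mod$space$n_states
  j <- mod$e_j0 + 1L; k <- mod$e_k0 + 1L; p <- mod$e_p0 + 1L
  sym <- j == k
  term <- rt$erate * (DL[j] * DR[k] + ifelse(sym, 0, DL[k] * DR[j]))
  as.vector(rowsum(c(term, numeric(n)), c(p, 1:n)))
}

## the full pruning pass; internal workhorse shared by compute_loglik,
## the optimizer and the reconstruction machinery.
## clamp: optional list(node = <ape node id>, state = <index>) or
##        list(node = , mask = <0/1 vector>)
## returns loglik plus (optionally) per-node partial caches
.pruning_pass <- function(td, mod, params, options, clamp = NULL,
                          keep_cache = FALSE, tip_states) {
  n <- mod$space$n_states
  rt <- .model_rates(mod, params)
  nn <- td$n_nodes
  E_base <- matrix(NA_real_, n, nn)
  D_base <- matrix(NA_real_, n, nn)
  E_top <- if (keep_cache) matrix(NA_real_, n, nn) else NULL
  D_top <- if (keep_cache) matrix(NA_real_, n, nn) else NULL
  logsc <- numeric(nn)   # accumulated log-scaler of the subtree partials

  clamp_mask <- NULL
  if (!is.null(clamp)) {
    clamp_mask <- numeric(n)
    if (!is.null(clamp$mask)) clamp_mask <- as.numeric(clamp$mask)
    else clamp_mask[clamp$state] <- 1
  }

  ## top-of-branch partials, indexed by child node
  tmpE <- matrix(NA_real_, n, nn)
  tmpD <- matrix(NA_real_, n, nn)

  get_base <- function(v) {
    if (v <= td$ntip) {
      E <- rep(1 - options$rho, n)
      D <- numeric(n)
      D[tip_states[v]] <- options$rho
      sc <- 0
    } else {
      ch <- td$kids[[v]]
      if (length(ch) == 2L) {
        EL <- tmpE[, ch[1]]; ER <- tmpE[, ch[2]]
        dev <- max(abs(EL - ER))
        if (dev > 1e-4)
          warning(sprintf("daughter E vectors disagree by %.3g at node %d",
                          dev, v))
        E <- (EL + ER) / 2
        D <- .combine_D(tmpD[, ch[1]], tmpD[, ch[2]], mod, rt)
      } else {                           # degree-2 evaluation node
        E <- tmpE[, ch[1]]
        D <- tmpD[, ch[1]]
      }
      sc <- sum(logsc[ch])
    }
    if (!is.null(clamp_mask) && identical(v, as.integer(clamp$node)))
      D <- D * clamp_mask
    m <- max(D)
    if (m > 0) { D <- D / m; sc <- sc + log(m) }
    list(E = E, D = D, sc = sc)
  }

  ne <- nrow(td$edge)
  for (r in seq_len(ne)) {
    child <- td$edge[r, 2]
    b <- get_base(child)
    E_base[, child] <- b$E; D_base[, child] <- b$D; logsc[child] <- b$sc
    out <- branch_ode_cpp(c(b$E, b$D), td$edge_length[r], rt$mu,
                          mod$a_from0, mod$a_to0, rt$arate,
                          mod$e_p0, mod$e_j0, mod$e_k0, rt$erate,
                          rt$tot, options$rtol, options$atol, FALSE)
    E <- out$y[seq_len(n)]; D <- out$y[n + seq_len(n)]
    sc <- logsc[child] + out$dlog
    m <- max(D)
    if (m > 0) { D <- D / m; sc <- sc + log(m) }
    tmpE[, child] <- E; tmpD[, child] <- D; logsc[child] <- sc
    if (keep_cache) { E_top[, child] <- E; D_top[, child] <- D }
  }

  root <- td$root
  b <- get_base(root)
  E_base[, root] <- b$E; D_base[, root] <- b$D; logsc[root] <- b$sc

  D_root <- b$D; E_root <- b$E
  sD <- sum(D_root)
  w <- if (!is.null(options$root_weights)) {
    options$root_weights
  } else if (options$root_weighting == "uniform" || sD <= 0) {
    rep(1 / n, n)
  } else D_root / sD
  L <- sum(w * D_root)
  cond <- 1
  if (options$condition_on_survival) cond <- sum(w * (1 - E_root)^2)
  loglik <- if (L <= 0 || cond <= 0) -Inf else log(L) - log(cond) + logsc[root]

  res <- list(loglik = loglik, root_D = D_root, root_E = E_root,
              root_weights = w, root_logsc = logsc[root])
  if (keep_cache)
    res$cache <- list(E_base = E_base, D_base = D_base,
                      E_top = E_top, D_top = D_top, logsc = logsc,
                      rt = rt)
  res
}

#' Log-likelihood of tip ranges on a time-calibrated tree
#'
#' Computes the likelihood of the observed tip ranges under the
#' extinction-aware range-diversification process: the coupled extinction
#' (E) and data (D) partial vectors are numerically integrated from the
#' tips toward the root along every branch, combined at nodes through the
#' cladogenetic event table of the chosen model variant, and weighted at
#' the root. Whole-lineage extinction at the user-fixed rate \code{mu}
#' enters every state identically, which is what allows extinct lineages
#' and their (unobserved) ranges to contribute to the reconstruction.
#'
#' @param tree A rooted, binary, time-calibrated \code{phylo} tree with
#'   branch lengths.
#' @param tip_ranges Named vector mapping every tip label to a range:
#'   either integer state indices of \code{space}, or character strings
#'   parseable by [parse_range()].
#' @param space A \code{range_space}.
#' @param model \code{"DEC"}, \code{"DIVA"}, or a prebuilt
#'   \code{range_model}.
#' @param params A \code{range_rates}.
#' @param options A \code{range_lik_options}.
#' @param keep_cache Retain per-node partial vectors for downstream
#'   reconstruction (default \code{TRUE}).
#' @param clamp Internal/advanced: list with elements \code{node} (ape node
#'   id) and \code{state} (or \code{mask}) restricting that node to a
#'   state; used to define marginal ancestral reconstructions.
#' @return An object of class \code{range_lik}: list with \code{loglik},
#'   \code{params}, \code{model}, \code{options}, root summaries and, if
#'   requested, cached per-node partials.
#' @export
compute_loglik <- function(tree, tip_ranges, space, params,
                           model = c("DEC", "DIVA"),
                           options = likelihood_options(),
                           keep_cache = TRUE, clamp = NULL) {
  mod <- if (inherits(model, "range_model")) model
         else range_model(space, match.arg(model))
  td <- .tree_data(tree, allow_singles = !is.null(clamp))
  st <- .tip_state_vector(tip_ranges, td$tree, space)
  res <- .pruning_pass(td, mod, params, options, clamp = clamp,
                       keep_cache = keep_cache, tip_states = st)
  structure(list(loglik = res$loglik, params = params, model = mod$model,
                 options = options, root_D = res$root_D,
                 root_E = res$root_E, root_weights = res$root_weights,
                 n_tips = td$ntip, tree_height = td$height,
                 convention = .convention_note(),
                 tree_data = td, tip_states = st, mod = mod,
                 cache = res$cache),
            class = "range_lik")
}

.convention_note <- function() {
  paste("lambda_is per in-situ event, lambda_vic per unordered bipartition",
        "(no per-state normalization); dispersal rate d per occupied source",
        "area; root: FitzJohn weights with survival conditioning unless",
        "overridden")
}

#' @export
print.range_lik <- function(x, ...) {
  cat(sprintf("Range SSE likelihood (%s): loglik = %.6f on %d tips\n",
              x$model, x$loglik, x$n_tips))
  print(x$params)
  invisible(x)
}
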