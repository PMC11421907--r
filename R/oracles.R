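# Closed-form and brute-force reference computations used to validate the
# ODE pruning machinery. These deliberately avoid the compiled integrator:
# the birth-death likelihood is fully analytic, the linear-propagator
# likelihood uses a dense matrix exponential, and the clamp-based marginals
# re-run whole likelihood evaluations with one node restricted.

## E(t) and its time integral for the constant-rate birth-death process,
## complete sampling, t measured from the present
.bd_E <- function(t, lambda, mu) {
  if (mu == 0) return(rep(0, length(t)))
  if (abs(lambda - mu) < 1e-12) return(mu * t / (1 + lambda * t))
  r <- lambda - mu
  mu * (1 - exp(-r * t)) / (lambda - mu * exp(-r * t))
}

.bd_intE <- function(t, lambda, mu) {
  if (mu == 0) return(rep(0, length(t)))
  if (abs(lambda - mu) < 1e-12) return(t - log1p(lambda * t) / lambda)
  r <- lambda - mu
  t - r * t / lambda -
    (1 / lambda) * log(abs((lambda - mu * exp(-r * t)) / (lambda - mu)))
}

#' Closed-form constant-rate birth-death log-likelihood
#'
#' Analytic log-likelihood of a rooted ultrametric tree under the
#' constant-rate birth-death process with complete sampling, using the same
#' conventions as the pruning likelihood of this package: the crown age is
#' taken as given, state partials start at \code{D = 1} at the tips, each
#' branch contributes the analytic factor
#' \code{exp(-(lambda+mu) dt + 2 lambda int(E))}, each of the n-1 internal
#' nodes contributes a factor lambda, and (optionally) the result is
#' conditioned on survival of both root daughters by dividing by
#' \code{(1 - E(T))^2}. With \code{mu = 0} this reduces to the Yule
#' likelihood \code{(n-1) log(lambda) - lambda * (total branch length)}.
#'
#' @param tree Ultrametric binary \code{phylo}.
#' @param lambda,mu Speciation and extinction rates (> 0 and >= 0).
#' @param condition_on_survival Divide by \code{(1 - E(T))^2}.
#' @return Log-likelihood (numeric scalar).
#' @export
bd_loglik <- function(tree, lambda, mu, condition_on_survival = TRUE) {
  if (lambda <= 0 || mu < 0) stop("need lambda > 0 and mu >= 0")
  td <- .tree_data(tree)
  ty <- td$t_node[td$edge[, 2]]
  to <- td$t_node[td$edge[, 1]]
  ll <- (td$ntip - 1) * log(lambda) +
    sum(-(lambda + mu) * (to - ty) +
          2 * lambda * (.bd_intE(to, lambda, mu) - .bd_intE(ty, lambda, mu)))
  if (condition_on_survival)
    ll <- ll - 2 * log(1 - .bd_E(td$height, lambda, mu))
  ll
}

#' Linear-propagator log-likelihood oracle (zero extinction)
#'
#' With \code{mu = 0} and complete sampling the extinction partials vanish
#' identically, so the data partials obey a linear ODE whose solution along
#' a branch of duration t is the dense matrix exponential
#' \code{expm(A t) D} with generator
#' \code{A = Q - diag(total out-rate)}. This function propagates the tip
#' partials with \code{Matrix::expm}, applies the cladogenetic combination
#' by direct summation over the event table, and assembles the root in the
#' same way as the pruning likelihood. It is exact up to the matrix
#' exponential and therefore an independent check of the ODE integrator.
#'
#' @inheritParams compute_loglik
#' @return Log-likelihood (numeric scalar).
#' @export
loglik_matexp <- function(tree, tip_ranges, space, params,
                          model = c("DEC", "DIVA"),
                          options = likelihood_options()) {
  if (params$mu != 0) stop("the linear oracle requires mu = 0")
  if (options$rho != 1) stop("the linear oracle requires rho = 1")
  mod <- if (inherits(model, "range_model")) model
         else range_model(space, match.arg(model))
  td <- .tree_data(tree)
  st <- .tip_state_vector(tip_ranges, td$tree, space)
  n <- space$n_states
  rt <- .model_rates(mod, params)

  A <- matrix(0, n, n)
  for (r in seq_len(nrow(mod$ana)))
    A[mod$ana$from[r], mod$ana$to[r]] <-
      A[mod$ana$from[r], mod$ana$to[r]] + rt$arate[r]
  diag(A) <- diag(A) - rt$tot

  cla <- mod$clado
  combine <- function(DL, DR) {
    D <- numeric(n)
    for (r in seq_len(nrow(cla))) {
      j <- cla$left[r]; k <- cla$right[r]
      lam <- rt$erate[r]
      D[cla$parent[r]] <- D[cla$parent[r]] +
        if (j == k) lam * DL[j] * DR[j]
        else lam * (DL[j] * DR[k] + DL[k] * DR[j])
    }
    D
  }

  Dmat <- matrix(NA_real_, n, td$n_nodes)
  for (v in seq_len(td$ntip)) {
    Dmat[, v] <- 0
    Dmat[st[v], v] <- 1
  }
  for (r in seq_len(nrow(td$edge))) {
    child <- td$edge[r, 2]
    if (child > td$ntip) {
      ch <- td$kids[[child]]
      Dmat[, child] <- combine(Dmat[, ch[1]], Dmat[, ch[2]])
    }
    P <- as.matrix(Matrix::expm(Matrix::Matrix(A * td$edge_length[r])))
    Dmat[, child] <- as.vector(P %*% Dmat[, child])
  }
  ch <- td$kids[[td$root]]
  D_root <- combine(Dmat[, ch[1]], Dmat[, ch[2]])
  w <- if (!is.null(options$root_weights)) options$root_weights
       else if (options$root_weighting == "uniform") rep(1 / n, n)
       else D_root / sum(D_root)
  L <- sum(w * D_root)        # conditioning is a no-op at mu = 0, rho = 1
  log(L)
}

#' Marginal ancestral states by clamp-and-renormalise (brute force)
#'
#' Defines the marginal probability of each state at each internal node
#' operationally: the likelihood is recomputed with the node restricted
#' (clamped) to each state in turn, holding the root weights fixed at the
#' values of the unclamped run, and the clamped likelihoods are
#' renormalised. This is the reference against which the efficient
#' up/down-pass reconstruction is validated; the clamped likelihoods sum
#' to the unclamped likelihood by construction.
#'
#' @inheritParams compute_loglik
#' @return List with \code{prob} (internal nodes x states matrix of
#'   marginal probabilities, rows named by ape node id), \code{loglik}
#'   (unclamped), and \code{clamp_logsum} (log of the summed clamped
#'   likelihoods, equal to \code{loglik} up to numerical error).
#' @export
marginals_by_clamping <- function(tree, tip_ranges, space, params,
                                  model = c("DEC", "DIVA"),
                                  options = likelihood_options()) {
  mod <- if (inherits(model, "range_model")) model
         else range_model(space, match.arg(model))
  base <- compute_loglik(tree, tip_ranges, space, params, mod,
                         options = options, keep_cache = FALSE)
  opts <- options
  opts$root_weights <- base$root_weights
  ntip <- length(tree$tip.label)
  nodes <- ntip + seq_len(tree$Nnode)
  n <- space$n_states
  ll <- matrix(-Inf, length(nodes), n, dimnames = list(nodes, space$labels))
  for (a in seq_along(nodes)) {
    for (s in seq_len(n)) {
      fit <- compute_loglik(tree, tip_ranges, space, params, mod,
                            options = opts, keep_cache = FALSE,
                            clamp = list(node = nodes[a], state = s))
      ll[a, s] <- fit$loglik
    }
  }
  mx <- apply(ll, 1, max)
  prob <- exp(ll - mx)
  prob <- prob / rowSums(prob)
  base_fixed <- compute_loglik(tree, tip_ranges, space, params, mod,
                               options = opts, keep_cache = FALSE)
  list(prob = prob, loglik = base_fixed$loglik,
       clamp_logsum = log(rowSums(exp(ll - base_fixed$loglik))) + base_fixed$loglik)
}

## split the edge above `child` at time `at` (before present) by inserting
## a degree-2 node; returns list(tree, node = new node id)
.insert_single <- function(tree, child, at) {
  td <- .tree_data(tree)
  tree <- td$tree
  r <- which(tree$edge[, 2] == child)
  p <- tree$edge[r, 1]
  ty <- td$t_node[child]; to <- td$t_node[p]
  if (!(at >= ty && at <= to)) stop("time not on the branch above this node")
  ntip <- length(tree$tip.label)
  newid <- ntip + tree$Nnode + 1L
  e <- tree$edge
  len <- tree$edge.length
  e[r, ] <- c(p, newid)
  len[r] <- to - at
  e <- rbind(e, c(newid, child))
  len <- c(len, at - ty)
  tree$edge <- e
  tree$edge.length <- len
  tree$Nnode <- tree$Nnode + 1L
  list(tree = tree, node = newid)
}
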