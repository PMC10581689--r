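## Growing Neural Gas over visited arm postures (Fritzke-style incremental
## self-organizing graph). Nodes live in the 7-D joint-angle space; distances
## are Euclidean in radians.

#' Growing Neural Gas parameters
#'
#' Hyperparameters of the incremental self-organizing graph used to summarise
#' visited arm postures. The node budget `n_nodes` is the stopping rule (the
#' growth stops at the end of the first presentation pass in which the budget
#' is reached); the remaining parameters follow the canonical formulation:
#' a node is inserted every `lambda_insert` sample presentations at the
#' highest-error region, the winning node moves toward the sample by `eps_b`
#' and its graph neighbours by `eps_n`, edges die at age `max_age`, insertion
#' halves accumulated errors by `alpha`, and all errors decay by `beta` per
#' presentation.
#'
#' @param n_nodes Node budget (>= 2), 200 by default.
#' @param lambda_insert Presentations between insertions.
#' @param eps_b,eps_n Winner / neighbour learning rates, in (0, 1).
#' @param alpha,beta Error decay at insertion / per presentation, in (0, 1).
#' @param max_age Edge age limit (presentations).
#' @param max_passes Maximum passes over the data before the budget is
#'   declared unreachable.
#' @param seed Integer seed for presentation order and initialisation.
#' @return A list of class `gng_params`.
#' @export
gng_params <- function(n_nodes = 200, lambda_insert = 100, eps_b = 0.2,
                       eps_n = 0.006, alpha = 0.5, beta = 0.995,
                       max_age = 50, max_passes = 25, seed = NULL) {
  if (n_nodes < 2) abort("`n_nodes` must be >= 2.")
  for (r in c(eps_b = eps_b, eps_n = eps_n, alpha = alpha, beta = beta)) {
    if (!is.finite(r) || r <= 0 || r >= 1) {
      abort("learning rates and decays must lie in (0, 1).")
    }
  }
  if (lambda_insert < 1 || max_age < 1 || max_passes < 1) {
    abort("`lambda_insert`, `max_age` and `max_passes` must be >= 1.")
  }
  structure(
    list(
      n_nodes = as.integer(n_nodes), lambda_insert = as.integer(lambda_insert),
      eps_b = eps_b, eps_n = eps_n, alpha = alpha, beta = beta,
      max_age = as.integer(max_age), max_passes = as.integer(max_passes),
      seed = seed
    ),
    class = "gng_params"
  )
}

#' Fit a Growing Neural Gas to arm postures
#'
#' Learns the topology of the set of visited postures: starting from two
#' nodes, samples are presented in seeded random order; the two nearest nodes
#' are found, the winner (and, more weakly, its neighbours) moves toward the
#' sample, the winner pair is connected, edges age and die, and every
#' `lambda_insert` presentations a node is inserted halfway between the
#' highest-error node and its worst neighbour — until the node budget is
#' reached (growth stops, the current pass completes, and fitting ends).
#' Samples are presented in passes over the data; an error is raised when the
#' budget cannot be reached from the available data within
#' `params$max_passes` passes.
#'
#' @param postures Data frame of joint-angle samples (the downsampled
#'   acquisition postures) or a numeric matrix with the seven angle columns.
#' @param params A [gng_params()].
#' @return A tibble of `params$n_nodes` node postures (seven angle columns),
#'   with attributes `quantization_error` (mean distance of the input samples
#'   to their nearest node, radians), `n_presented` and `passes`.
#' @export
gng_fit <- function(postures, params = gng_params()) {
  if (!inherits(params, "gng_params")) abort("`params` must be gng_params().")
  X <- angles_matrix(postures)
  n <- nrow(X)
  if (n < 2) abort("need at least 2 input postures.")
  budget <- params$n_nodes
  achievable <- 2L + params$max_passes * (n %/% params$lambda_insert)
  if (budget > achievable) {
    abort(sprintf(
      "n_nodes = %d is not achievable from %d postures with lambda_insert = %d within %d passes (at most %d nodes); provide more data or lower the budget.",
      budget, n, params$lambda_insert, params$max_passes, achievable
    ))
  }

  with_seed_if(params$seed, {
    d <- ncol(X)
    W <- matrix(NA_real_, budget, d) # node positions
    err <- rep(0, budget)
    alive <- rep(FALSE, budget)
    age <- matrix(NA_real_, budget, budget) # NA = no edge
    init <- sample.int(n, 2L)
    W[1:2, ] <- X[init, ]
    alive[1:2] <- TRUE
    age[1, 2] <- age[2, 1] <- 0

    n_alive <- 2L
    presented <- 0L
    passes <- 0L
    done_growing <- FALSE

    while (passes < params$max_passes) {
      passes <- passes + 1L
      ord <- sample.int(n)
      for (i in ord) {
        x <- X[i, ]
        idx <- which(alive)
        dif <- W[idx, , drop = FALSE] - rep(x, each = length(idx))
        d2 <- rowSums(dif * dif)
        o <- order(d2)[1:2]
        s1 <- idx[o[1]]
        s2 <- idx[o[2]]

        err[s1] <- err[s1] + d2[o[1]]
        W[s1, ] <- W[s1, ] + params$eps_b * (x - W[s1, ])
        nbr <- which(!is.na(age[s1, ]))
        if (length(nbr) > 0) {
          W[nbr, ] <- W[nbr, ] + params$eps_n *
            (rep(x, each = length(nbr)) - W[nbr, , drop = FALSE])
          age[s1, nbr] <- age[s1, nbr] + 1
          age[nbr, s1] <- age[s1, nbr]
        }
        age[s1, s2] <- age[s2, s1] <- 0
        old <- which(age[s1, ] > params$max_age)
        if (length(old) > 0) {
          age[s1, old] <- age[old, s1] <- NA
          if (!done_growing) {
            ## node removal stops once the budget is met, so the final node
            ## count equals the budget exactly
            for (k in c(old, s1)) {
              if (alive[k] && n_alive > 2L && all(is.na(age[k, ]))) {
                alive[k] <- FALSE
                err[k] <- 0
                n_alive <- n_alive - 1L
              }
            }
          }
        }

        presented <- presented + 1L
        if (!done_growing && presented %% params$lambda_insert == 0L &&
          n_alive < budget) {
          q <- which(alive)[which.max(err[alive])]
          nbr_q <- which(!is.na(age[q, ]))
          if (length(nbr_q) > 0) {
            f <- nbr_q[which.max(err[nbr_q])]
            r <- which(!alive)[1]
            W[r, ] <- (W[q, ] + W[f, ]) / 2
            alive[r] <- TRUE
            n_alive <- n_alive + 1L
            age[q, f] <- age[f, q] <- NA
            age[q, r] <- age[r, q] <- 0
            age[f, r] <- age[r, f] <- 0
            err[q] <- err[q] * params$alpha
            err[f] <- err[f] * params$alpha
            err[r] <- err[q]
          }
        }
        if (n_alive >= budget) done_growing <- TRUE
        err <- err * params$beta
      }
      if (n_alive >= budget) break
    }

    if (n_alive != budget) {
      abort(sprintf(
        "GNG reached %d nodes after %d passes (budget %d); edge pruning removed too many nodes for this data.",
        n_alive, passes, budget
      ))
    }

    nodes <- as_tibble(as.data.frame(W[alive, , drop = FALSE]))
    names(nodes) <- ANGLE_COLS
    ## mean quantization error over the full input set
    Wf <- as.matrix(nodes)
    d2 <- outer(rowSums(X^2), rep(1, nrow(Wf))) +
      outer(rep(1, n), rowSums(Wf^2)) - 2 * X %*% t(Wf)
    qe <- mean(sqrt(pmax(apply(d2, 1, min), 0)))
    attr(nodes, "quantization_error") <- qe
    attr(nodes, "n_presented") <- presented
    attr(nodes, "passes") <- passes
    attr(nodes, "params") <- params
    nodes
  })
}
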