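# Marginal maximum-likelihood engine for the segmented multilevel
# modified-Poisson model.
#
# The binary outcome is modelled with a Poisson likelihood and log link
# ("modified Poisson"), so coefficients are log rate ratios; the
# mis-specified variance is corrected later by a region-clustered sandwich
# estimator. Cluster-level random effects are integrated out by adaptive
# Gauss-Hermite quadrature (tensor nodes, centred and scaled at the
# per-cluster posterior mode); one quadrature node per dimension gives the
# Laplace approximation, which is the default above two random dimensions.
# A woman-level random intercept is handled by nesting a one-dimensional
# inner quadrature per woman inside each outer node.

#' Fitting control parameters
#'
#' @param agq_nodes quadrature nodes per random-effect dimension at the
#'   cluster level (1 = Laplace). Default 7 for up to two dimensions,
#'   Laplace above.
#' @param inner_nodes nodes for the nested woman-level quadrature.
#' @param maxit,reltol BFGS iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param restarts extra optimizer starts (with perturbed variance starts)
#'   attempted if the first does not converge.
#' @param se compute model-based and region-clustered robust covariance at
#'   fit time. Disable in simulation harnesses that only need point
#'   estimates.
#' @param boundary_tol a cluster-level variance below this is treated as a
#'   boundary estimate: the term is dropped and the model refitted.
#' @param fd_step relative step for finite-difference derivatives.
#' @param verbose print optimizer progress.
#' @return list of class `mpits_control`.
#' @export
mpits_control <- function(agq_nodes = NULL, inner_nodes = 7L, maxit = 400L,
                          reltol = 1e-8, restarts = 2L, se = TRUE,
                          boundary_tol = 1e-3, fd_step = 1e-5,
                          verbose = FALSE) {
  structure(list(agq_nodes = agq_nodes, inner_nodes = inner_nodes,
                 maxit = maxit, reltol = reltol, restarts = restarts,
                 se = se, boundary_tol = boundary_tol, fd_step = fd_step,
                 verbose = verbose), class = "mpits_control")
}

# --- Gauss-Hermite nodes (Golub-Welsch) ----------------------------------
gauss_hermite <- function(M) {
  if (M == 1L) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(M - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, M, M)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

# --- internal dimensions / parameter layout ------------------------------
# theta = c(beta, theta_psi, log_sd_woman?)
# theta_psi parameterizes the lower Cholesky factor of the cluster
# random-effect covariance: log-diagonal entries, then (if unstructured)
# free sub-diagonal entries, column-major.
internal_dims <- function(bundle, control) {
  q <- if (is.null(bundle$Z)) 0L else ncol(bundle$Z)
  has_woman <- !is.null(bundle$woman)
  # a woman-level-only model is handled as a 2-level model grouped by woman
  woman_as_cluster <- (q == 0L && has_woman)
  structure_ <- bundle$spec$covariance %||% "unstructured"
  npsi <- if (q == 0L) 0L
          else if (structure_ == "diagonal") q
          else (q * (q + 1L)) %/% 2L
  p <- ncol(bundle$X)
  M <- control$agq_nodes %||% (if (q <= 2L) 7L else 1L)
  if (q > 2L) M <- min(M, 1L)   # Laplace fallback in >2 dimensions
  list(q = q, p = p, npsi = npsi, structure = structure_,
       has_woman = has_woman && !woman_as_cluster,
       woman_as_cluster = woman_as_cluster,
       M = M, Mw = control$inner_nodes %||% 7L,
       ntheta = p + npsi + as.integer(has_woman))
}

psi_chol_from_theta <- function(tp, q, structure_) {
  L <- matrix(0, q, q)
  diag(L) <- exp(tp[seq_len(q)])
  if (structure_ == "unstructured" && q > 1L) {
    k <- q
    for (j in seq_len(q - 1L)) for (i in (j + 1L):q) {
      k <- k + 1L
      L[i, j] <- tp[k]
    }
  }
  L
}

split_theta <- function(theta, dims) {
  p <- dims$p; q <- dims$q
  beta <- theta[seq_len(p)]
  L <- if (q > 0L)
    psi_chol_from_theta(theta[p + seq_len(dims$npsi)], q, dims$structure)
  else NULL
  sd_w <- if (dims$has_woman || dims$woman_as_cluster)
    exp(theta[length(theta)]) else 0
  list(beta = beta, L = L, sd_w = sd_w)
}

# --- core marginal log-likelihood ----------------------------------------
# Returns the vector of per-group log-likelihood contributions (groups are
# clusters, or women when the only random term is the woman intercept).
# `cache` is an environment holding warm-start posterior modes.

mll_groups <- function(theta, bundle, dims, cache = NULL) {
  pars <- split_theta(theta, dims)
  eta0 <- drop(bundle$X %*% pars$beta)
  if (any(!is.finite(eta0)))
    stop("non-finite linear predictor at record ",
         which(!is.finite(eta0))[1])
  y <- bundle$y
  lf <- -lfactorial(y)    # 0 for binary outcomes; kept for exactness

  if (dims$q == 0L && !dims$woman_as_cluster) {
    ll <- y * eta0 - exp(eta0) + lf
    return(drop(rowsum(ll, bundle$cluster)))
  }

  if (dims$woman_as_cluster) {
    ZL <- matrix(pars$sd_w, bundle$n, 1L)
    grp <- bundle$woman
    M <- max(1L, dims$Mw)
  } else {
    ZL <- bundle$Z %*% pars$L
    grp <- bundle$cluster
    M <- dims$M
  }
  K <- max(grp)
  q <- ncol(ZL)

  if (!dims$has_woman) {
    agq_group_ll(y, eta0, lf, ZL, grp, K, q, M, cache, key = "U")
  } else {
    nested_group_ll(y, eta0, lf, ZL, grp, K, q, M, dims$Mw,
                    pars$sd_w, bundle$woman, cache)
  }
}

# Newton search for per-group posterior modes of the standardized effects
# u (b = L u). U: K x q warm start. Returns U, per-group conditional
# log-lik parts and the negative-Hessian pieces.
group_modes <- function(y, eta0, lf, ZL, grp, K, q, U) {
  ij <- which(upper.tri(diag(q), diag = TRUE), arr.ind = TRUE) # a<=b pairs
  obj <- function(U) {
    eta <- eta0 + rowSums(ZL * U[grp, , drop = FALSE])
    cll <- drop(rowsum(y * eta - exp(eta) + lf, grp))
    list(eta = eta, g = cll - 0.5 * rowSums(U * U))
  }
  hess_cols <- function(mu) {
    Wz <- mu * ZL
    HC <- matrix(0, length(mu), nrow(ij))
    for (r in seq_len(nrow(ij)))
      HC[, r] <- Wz[, ij[r, 1]] * ZL[, ij[r, 2]]
    HC
  }
  cur <- obj(U)
  for (iter in 1:60) {
    mu <- exp(cur$eta)
    GH <- rowsum(cbind((y - mu) * ZL, hess_cols(mu)), grp)
    G <- GH[, seq_len(q), drop = FALSE] - U      # K x q gradient
    H <- GH[, q + seq_len(nrow(ij)), drop = FALSE]
    gmax <- max(abs(G))
    if (!is.finite(gmax) || gmax < 1e-9) break
    step <- matrix(0, K, q)
    if (q == 1L) {
      step[, 1] <- G[, 1] / (H[, 1] + 1)
    } else if (q == 2L) {
      a <- H[, 1] + 1; b <- H[, 2]; d <- H[, 3] + 1
      det <- a * d - b * b
      step[, 1] <- (d * G[, 1] - b * G[, 2]) / det
      step[, 2] <- (a * G[, 2] - b * G[, 1]) / det
    } else {
      for (k in seq_len(K)) {
        A <- matrix(0, q, q)
        A[cbind(ij[, 1], ij[, 2])] <- H[k, ]
        A <- A + t(A); diag(A) <- diag(A) / 2 + 1
        step[k, ] <- solve(A, G[k, ])
      }
    }
    step[!is.finite(step)] <- 0
    # per-group step halving; non-finite objectives count as rejected
    lam <- rep(1, K)
    for (h in 1:30) {
      nxt <- obj(U + lam * step)
      bad <- !is.finite(nxt$g) | nxt$g < cur$g - 1e-12
      if (!any(bad)) break
      lam[bad] <- lam[bad] / 2
      if (h == 30) lam[bad] <- 0
    }
    U <- U + lam * step
    cur <- obj(U)
  }
  H <- rowsum(hess_cols(exp(cur$eta)), grp)
  list(U = U, g = cur$g, H = H, ij = ij)
}

# Adaptive GH quadrature for a single grouping level. The node pass is
# vectorized: per-observation linear predictors for all tensor nodes are
# assembled as an n x nodes matrix and reduced with a single rowsum().
agq_group_ll <- function(y, eta0, lf, ZL, grp, K, q, M, cache, key) {
  U0 <- if (!is.null(cache) && !is.null(cache[[key]]) &&
            all(dim(cache[[key]]) == c(K, q))) cache[[key]]
        else matrix(0, K, q)
  md <- group_modes(y, eta0, lf, ZL, grp, K, q, U0)
  if (!is.null(cache)) cache[[key]] <- md$U

  # scale factors: C_k (upper triangular) with C C' = (A_k + I)^{-1}
  ldetC <- numeric(K)
  Cup <- NULL                 # K x q x q array of C entries (i <= j)
  if (q == 1L) {
    ldetC <- -0.5 * log(md$H[, 1] + 1)
  } else {
    Cup <- array(0, c(K, q, q))
    for (k in seq_len(K)) {
      A <- matrix(0, q, q)
      A[cbind(md$ij[, 1], md$ij[, 2])] <- md$H[k, ]
      A <- A + t(A); diag(A) <- diag(A) / 2 + 1
      R <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(R)) return(rep(-Inf, K))
      Cup[k, , ] <- backsolve(R, diag(q))
      ldetC[k] <- -sum(log(diag(R)))
    }
  }
  if (M == 1L) return(md$g + ldetC)       # Laplace

  gh <- gauss_hermite(M)
  nodes <- as.matrix(expand.grid(rep(list(seq_len(M)), q)))
  nnode <- nrow(nodes)
  X <- matrix(gh$x[nodes], nnode, q)                    # node coordinates
  lw <- rowSums(matrix(log(gh$w[nodes]), nnode, q)) + rowSums(X * X)
  # per-dimension node values for every group: Umat[[j]] is K x nnode
  Umat <- vector("list", q)
  for (j in seq_len(q)) {
    if (q == 1L) {
      shift <- (1 / sqrt(md$H[, 1] + 1)) %o% X[, 1]
    } else {
      shift <- matrix(0, K, nnode)
      for (l in j:q)                       # C upper triangular
        shift <- shift + Cup[, j, l] %o% X[, l]
    }
    Umat[[j]] <- md$U[, j] + sqrt(2) * shift
  }
  eta <- eta0 + lf * 0
  Emat <- matrix(eta0, length(y), nnode)
  for (j in seq_len(q))
    Emat <- Emat + ZL[, j] * Umat[[j]][grp, , drop = FALSE]
  cll <- rowsum(y * Emat - exp(Emat) + lf, grp)          # K x nnode
  Tmat <- matrix(lw, K, nnode, byrow = TRUE) + cll
  for (j in seq_len(q)) Tmat <- Tmat - 0.5 * Umat[[j]]^2
  mx <- apply(Tmat, 1, max)
  -0.5 * q * log(2 * pi) + 0.5 * q * log(2) + ldetC + mx +
    log(rowSums(exp(Tmat - mx)))
}

# Nested scheme for cluster random effects plus a woman-level intercept:
# outer AGQ over the cluster effects, inner one-dimensional AGQ per woman.
nested_group_ll <- function(y, eta0, lf, ZL, grp, K, q, M, Mw, sd_w,
                            woman, cache) {
  W <- max(woman)
  woman_cluster <- integer(W)
  woman_cluster[woman] <- grp
  U <- if (!is.null(cache$U) && all(dim(cache$U) == c(K, q))) cache$U
       else matrix(0, K, q)
  s <- if (!is.null(cache$s) && length(cache$s) == W) cache$s
       else numeric(W)

  cond <- function(U, s) {
    eta <- eta0 + rowSums(ZL * U[grp, , drop = FALSE]) + sd_w * s[woman]
    eta
  }
  # --- joint mode by alternating Newton ---------------------------------
  ij <- which(upper.tri(diag(q), diag = TRUE), arr.ind = TRUE)
  for (it in 1:100) {
    eta <- cond(U, s)
    mu <- exp(eta)
    # woman step
    gs <- sd_w * drop(rowsum(y - mu, woman)) - s
    ds <- sd_w^2 * drop(rowsum(mu, woman)) + 1
    stp <- gs / ds
    stp[!is.finite(stp)] <- 0
    s <- s + stp
    eta <- cond(U, s)
    mu <- exp(eta)
    # cluster step
    G <- rowsum(ZL * (y - mu), grp) - U
    Wz <- mu * ZL
    H <- matrix(0, K, nrow(ij))
    for (r in seq_len(nrow(ij)))
      H[, r] <- drop(rowsum(Wz[, ij[r, 1]] * ZL[, ij[r, 2]], grp))
    if (q == 1L) {
      U <- U + G / (H[, 1] + 1)
    } else if (q == 2L) {
      a <- H[, 1] + 1; b <- H[, 2]; d <- H[, 3] + 1
      det <- a * d - b * b
      U <- U + cbind((d * G[, 1] - b * G[, 2]) / det,
                     (a * G[, 2] - b * G[, 1]) / det)
    } else {
      for (k in seq_len(K)) {
        A <- matrix(0, q, q)
        A[cbind(ij[, 1], ij[, 2])] <- H[k, ]
        A <- A + t(A); diag(A) <- diag(A) / 2 + 1
        U[k, ] <- U[k, ] + solve(A, G[k, ])
      }
    }
    U[!is.finite(U)] <- 0
    gm <- suppressWarnings(max(abs(G), abs(gs)))
    if (!is.finite(gm) || gm < 1e-8) break
  }
  cache$U <- U; cache$s <- s

  # --- outer curvature: Schur complement at the joint mode ---------------
  eta <- cond(U, s)
  mu <- exp(eta)
  Wz <- mu * ZL
  H <- matrix(0, K, nrow(ij))
  for (r in seq_len(nrow(ij)))
    H[, r] <- drop(rowsum(Wz[, ij[r, 1]] * ZL[, ij[r, 2]], grp))
  d_w <- sd_w^2 * drop(rowsum(mu, woman)) + 1            # W
  Bw <- sd_w * rowsum(Wz, woman)                          # W x q
  # S_k = sum_j B_j B_j' / d_j
  Smat <- matrix(0, K, nrow(ij))
  for (r in seq_len(nrow(ij)))
    Smat[, r] <- drop(rowsum(Bw[, ij[r, 1]] * Bw[, ij[r, 2]] / d_w,
                             woman_cluster))
  ldetC <- numeric(K)
  Clist <- vector("list", K)
  for (k in seq_len(K)) {
    A <- matrix(0, q, q)
    A[cbind(ij[, 1], ij[, 2])] <- H[k, ] - Smat[k, ]
    A <- A + t(A); diag(A) <- diag(A) / 2 + 1
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(rep(-Inf, K))
    Clist[[k]] <- backsolve(R, diag(q))
    ldetC[k] <- -sum(log(diag(R)))
  }

  # --- outer nodes --------------------------------------------------------
  gh <- gauss_hermite(max(1L, M))
  nodes <- as.matrix(expand.grid(rep(list(seq_len(max(1L, M))), q)))
  Tmat <- matrix(-Inf, K, nrow(nodes))
  sw <- s
  for (m in seq_len(nrow(nodes))) {
    x <- gh$x[nodes[m, ]]
    lw <- sum(log(gh$w[nodes[m, ]])) + sum(x * x)
    sh <- vapply(Clist, function(Ck) drop(Ck %*% x), numeric(q))
    shift <- if (q == 1L) matrix(sh, ncol = 1L) else t(sh)
    Um <- U + sqrt(2) * shift
    base <- eta0 + rowSums(ZL * Um[grp, , drop = FALSE])
    # inner modes given this outer node (warm start at joint mode)
    sm <- sw
    for (itw in 1:40) {
      mu <- exp(base + sd_w * sm[woman])
      gsw <- sd_w * drop(rowsum(y - mu, woman)) - sm
      gm_in <- max(abs(gsw))
      if (!is.finite(gm_in) || gm_in < 1e-9) break
      dsw <- sd_w^2 * drop(rowsum(mu, woman)) + 1
      stw <- gsw / dsw
      stw[!is.finite(stw)] <- 0
      sm <- sm + stw
    }
    sm[!is.finite(sm)] <- 0
    mu <- exp(base + sd_w * sm[woman])
    dsw <- sd_w^2 * drop(rowsum(mu, woman)) + 1
    # inner 1-dim AGQ per woman, all nodes in one pass
    Mw1 <- max(1L, Mw)
    ghw <- gauss_hermite(Mw1)
    SMW <- sm + sqrt(2) * (1 / sqrt(dsw)) %o% ghw$x        # W x Mw
    EM <- base + sd_w * SMW[woman, , drop = FALSE]          # n x Mw
    cllw <- rowsum(y * EM - exp(EM) + lf, woman)
    Tw <- matrix(log(ghw$w) + ghw$x^2, W, Mw1, byrow = TRUE) +
      cllw - 0.5 * SMW^2
    mxw <- apply(Tw, 1, max)
    logIj <- -0.5 * log(2 * pi) + 0.5 * log(2) - 0.5 * log(dsw) + mxw +
      log(rowSums(exp(Tw - mxw)))
    hval <- drop(rowsum(logIj, woman_cluster)) - 0.5 * rowSums(Um * Um)
    Tmat[, m] <- lw + hval
  }
  mx <- apply(Tmat, 1, max)
  -0.5 * q * log(2 * pi) + 0.5 * q * log(2) + ldetC + mx +
    log(rowSums(exp(Tmat - mx)))
}

#' Marginal log-likelihood of the multilevel modified-Poisson model
#'
#' Evaluates the Poisson log-likelihood with the cluster-level (and, if
#' present, woman-level) random effects integrated out by adaptive
#' Gauss-Hermite quadrature. Deterministic for a fixed node count.
#'
#' @param design an [build_design()] bundle.
#' @param beta fixed-effect vector (in design column order).
#' @param psi cluster random-effect covariance matrix (q x q, positive
#'   semi-definite), or NULL when the design has no cluster random terms.
#' @param sd_woman woman-level random-intercept standard deviation.
#' @param nodes quadrature nodes per dimension (1 = Laplace); default as
#'   in [mpits_control()].
#' @return total marginal log-likelihood (numeric scalar) with attribute
#'   `"by_group"` (per-cluster contributions).
#' @export
marginal_loglik <- function(design, beta, psi = NULL, sd_woman = 0,
                            nodes = NULL) {
  control <- mpits_control(agq_nodes = nodes)
  dims <- internal_dims(design, control)
  theta <- beta
  if (dims$q > 0L) {
    stopifnot(!is.null(psi), nrow(psi) == dims$q)
    if (!is_psd(psi)) stop("psi is not positive semi-definite")
    # log-Cholesky; guard hard zeros
    L <- tryCatch(t(chol(psi + diag(1e-12, dims$q))),
                  error = function(e) stop("psi is not positive semi-definite"))
    tp <- log(pmax(diag(L), 1e-154))
    if (dims$structure == "unstructured" && dims$q > 1L) {
      for (j in seq_len(dims$q - 1L)) for (i in (j + 1L):dims$q)
        tp <- c(tp, L[i, j])
    }
    theta <- c(theta, tp)
  }
  if (dims$has_woman || dims$woman_as_cluster)
    theta <- c(theta, log(max(sd_woman, 1e-154)))
  cache <- new.env(parent = emptyenv())
  llk <- mll_groups(theta, design, dims, cache)
  structure(sum(llk), by_group = llk)
}
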