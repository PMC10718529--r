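#' Hyperparameters for the group factor analysis model
#'
#' @param K number of latent factors (default 6).
#' @param a0,b0 Gamma prior shape/rate for the per-(view, factor) weight
#'   ARD precisions alpha.
#' @param c0,d0 Gamma prior shape/rate for the per-(group, factor) score
#'   ARD precisions beta (fixed to 1 for single-group data).
#' @param e0,f0 Gamma prior shape/rate for the per-feature noise
#'   precisions tau.
#' @param max_iter maximum coordinate-ascent iterations.
#' @param tol relative ELBO change below which iteration stops.
#' @param seed seed for the random normal initialization of the scores.
#' @return a list of class `gfa_hyperparams`.
#' @export
gfa_hyperparams <- function(K = 6, a0 = 1e-3, b0 = 1e-3, c0 = 1e-3,
                            d0 = 1e-3, e0 = 1e-3, f0 = 1e-3,
                            max_iter = 1000, tol = 1e-6, seed = 1) {
  stopifnot(K >= 1, a0 > 0, b0 > 0, c0 > 0, d0 > 0, e0 > 0, f0 > 0,
            max_iter >= 1, tol > 0)
  structure(list(K = as.integer(K), a0 = a0, b0 = b0, c0 = c0, d0 = d0,
                 e0 = e0, f0 = f0, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "gfa_hyperparams")
}

gamma_entropy <- function(a, b) a - log(b) + lgamma(a) + (1 - a) * digamma(a)

#' Fit a variational Bayesian group factor analysis with ARD
#'
#' Mean-field coordinate ascent for the model
#' \deqn{y^{m,g}_{nd} = \sum_k z^g_{nk} w^m_{dk} + \epsilon,\quad
#'       \epsilon \sim N(0, 1/\tau^{m,g}_d)}
#' with automatic relevance determination priors
#' \eqn{w \sim N(0, 1/\alpha^m_k)}, \eqn{z \sim N(0, 1/\beta^g_k)} and
#' Gamma hyperpriors on all precisions. Entries recorded as NA (including
#' wholly missing (sample, view) pairs) are masked out of every sufficient
#' statistic. Gaussian likelihood, no feature-wise spike-and-slab.
#'
#' The scores are initialized from a seeded standard normal and consumed
#' by the first weight update; from the second iteration on the update
#' order is Z, W, alpha, beta, tau, followed by the ELBO.
#'
#' @param data a `multiview_dataset` from [assemble_views] (features
#'   centered per group; a deviation above 1e-4 is an error).
#' @param hp a [gfa_hyperparams] object.
#' @return a `gfa_model` with posterior means/variances of weights and
#'   scores, ARD and noise precisions, the ELBO trace and the explained
#'   variance decomposition.
#' @export
fit_gfa <- function(data, hp = gfa_hyperparams()) {
  stopifnot(inherits(data, "multiview_dataset"), inherits(hp, "gfa_hyperparams"))
  K <- hp$K
  gnames <- unique(unname(data$groups))
  vnames <- names(data$views)
  G <- length(gnames); M <- length(vnames)
  single_group <- G == 1L

  ## split views by group, build masks
  Y <- O <- Y0 <- vector("list", M)
  D <- integer(M)
  rows_g <- lapply(gnames, function(g) names(data$groups)[data$groups == g])
  names(rows_g) <- gnames
  Ng <- vapply(rows_g, length, 0L)
  for (m in seq_len(M)) {
    vm <- data$views[[m]]
    D[m] <- ncol(vm)
    Y[[m]] <- lapply(rows_g, function(r) vm[r, , drop = FALSE])
    O[[m]] <- lapply(Y[[m]], function(y) (!is.na(y)) * 1)
    Y0[[m]] <- lapply(Y[[m]], function(y) { y[is.na(y)] <- 0; y })
    if (sum(vapply(O[[m]], sum, 0)) == 0)
      stop(sprintf("view '%s' has zero observed entries", vnames[m]))
    for (g in gnames) {
      ob <- O[[m]][[g]]
      if (sum(ob) == 0) next
      cm <- colSums(Y0[[m]][[g]]) / pmax(colSums(ob), 1)
      cm <- cm[colSums(ob) > 0]
      if (max(abs(cm)) > 1e-4)
        stop(sprintf("view '%s', group '%s' is not centered; run assemble_views first",
                     vnames[m], g))
    }
  }
  Ntot <- sum(Ng)
  if (K > Ntot) warning("K exceeds the total number of samples")

  ## variational state ------------------------------------------------------
  ## q factorizes over every scalar z_{nk} and w_{dk} (MOFA-style); scores
  ## start from a seeded normal draw (one stream per group), weights at 0.
  Zmu <- lapply(seq_len(G), function(gi) with_seed(hp$seed + gi - 1L,
                  matrix(rnorm(Ng[gi] * K), Ng[gi], K)))
  names(Zmu) <- gnames
  Zvar <- lapply(Ng, function(n) matrix(1, n, K)); names(Zvar) <- gnames
  Wmu <- lapply(D, function(d) matrix(0, d, K))
  Wvar <- lapply(D, function(d) matrix(1, d, K))
  names(Wmu) <- names(Wvar) <- vnames

  a_alpha <- setNames(rep(hp$a0, M), vnames)
  b_alpha <- lapply(vnames, function(v) rep(hp$b0, K)); names(b_alpha) <- vnames
  Ealpha <- lapply(vnames, function(v) rep(1, K)); names(Ealpha) <- vnames
  a_beta <- setNames(rep(hp$c0, G), gnames)
  b_beta <- lapply(gnames, function(g) rep(hp$d0, K)); names(b_beta) <- gnames
  Ebeta <- lapply(gnames, function(g) rep(1, K)); names(Ebeta) <- gnames
  a_tau <- b_tau <- Etau <- Elogtau <- list()
  nobs <- list()
  for (m in vnames) {
    a_tau[[m]] <- b_tau[[m]] <- Etau[[m]] <- Elogtau[[m]] <- nobs[[m]] <- list()
    for (g in gnames) {
      nobs[[m]][[g]] <- colSums(O[[match(m, vnames)]][[g]])
      Etau[[m]][[g]] <- rep(1, D[match(m, vnames)])
      Elogtau[[m]][[g]] <- rep(0, D[match(m, vnames)])
    }
  }

  ## running fit F = Zmu Wmu^T and masked residual R = O * (Y0 - F)
  Fit <- Res <- vector("list", M)
  for (m in seq_len(M)) {
    Fit[[m]] <- lapply(gnames, function(g) matrix(0, Ng[g], D[m]))
    names(Fit[[m]]) <- gnames
    Res[[m]] <- lapply(gnames, function(g) Y0[[m]][[g]])
    names(Res[[m]]) <- gnames
  }

  elbo_trace <- numeric(0)
  log2pi <- log(2 * pi)

  for (iter in seq_len(hp$max_iter)) {
    ## ---- Z update (skipped on iteration 1: random init feeds W first) ----
    if (iter > 1L) {
      for (gi in seq_len(G)) {
        g <- gnames[gi]
        prec <- matrix(0, Ng[gi], K)
        for (m in seq_len(M)) {
          v <- vnames[m]
          Ew2 <- Wmu[[v]]^2 + Wvar[[v]]
          prec <- prec + O[[m]][[g]] %*% (Etau[[v]][[g]] * Ew2)
        }
        prec <- sweep(prec, 2, Ebeta[[g]], "+")
        for (k in seq_len(K)) {
          num <- numeric(Ng[gi])
          for (m in seq_len(M)) {
            v <- vnames[m]
            wk <- Wmu[[v]][, k]
            tau <- Etau[[v]][[g]]
            num <- num + Res[[m]][[g]] %*% (tau * wk) +
                   Zmu[[g]][, k] * (O[[m]][[g]] %*% (tau * wk^2))
          }
          znew <- as.vector(num) / prec[, k]
          dz <- znew - Zmu[[g]][, k]
          Zmu[[g]][, k] <- znew
          Zvar[[g]][, k] <- 1 / prec[, k]
          for (m in seq_len(M)) {
            dF <- dz %o% Wmu[[vnames[m]]][, k]
            Fit[[m]][[g]] <- Fit[[m]][[g]] + dF
            Res[[m]][[g]] <- Res[[m]][[g]] - O[[m]][[g]] * dF
          }
        }
      }
    }

    ## ---- W update --------------------------------------------------------
    for (m in seq_len(M)) {
      v <- vnames[m]
      prec <- matrix(0, D[m], K)
      for (g in gnames) {
        Ez2 <- Zmu[[g]]^2 + Zvar[[g]]
        prec <- prec + Etau[[v]][[g]] * crossprod(O[[m]][[g]], Ez2)
      }
      prec <- sweep(prec, 2, Ealpha[[v]], "+")
      for (k in seq_len(K)) {
        num <- numeric(D[m])
        for (g in gnames) {
          zk <- Zmu[[g]][, k]
          tau <- Etau[[v]][[g]]
          num <- num + tau * (crossprod(Res[[m]][[g]], zk) +
                              Wmu[[v]][, k] * crossprod(O[[m]][[g]], zk^2))
        }
        wnew <- as.vector(num) / prec[, k]
        dw <- wnew - Wmu[[v]][, k]
        Wmu[[v]][, k] <- wnew
        Wvar[[v]][, k] <- 1 / prec[, k]
        for (g in gnames) {
          dF <- Zmu[[g]][, k] %o% dw
          Fit[[m]][[g]] <- Fit[[m]][[g]] + dF
          Res[[m]][[g]] <- Res[[m]][[g]] - O[[m]][[g]] * dF
        }
      }
    }

    ## ---- alpha -----------------------------------------------------------
    for (m in seq_len(M)) {
      v <- vnames[m]
      Ew2 <- colSums(Wmu[[v]]^2 + Wvar[[v]])
      a_alpha[v] <- hp$a0 + D[m] / 2
      b_alpha[[v]] <- hp$b0 + Ew2 / 2
      Ealpha[[v]] <- a_alpha[v] / b_alpha[[v]]
    }

    ## ---- beta (learned only with >1 group) -------------------------------
    if (!single_group) {
      for (gi in seq_len(G)) {
        g <- gnames[gi]
        Ez2 <- colSums(Zmu[[g]]^2 + Zvar[[g]])
        a_beta[g] <- hp$c0 + Ng[gi] / 2
        b_beta[[g]] <- hp$d0 + Ez2 / 2
        Ebeta[[g]] <- a_beta[g] / b_beta[[g]]
      }
    }

    ## ---- tau + expected residuals ---------------------------------------
    ## E[(y - z.w)^2] = (y - F)^2 + sum_k (E[z^2]E[w^2] - mu_z^2 mu_w^2)
    Sres <- list()
    for (m in seq_len(M)) {
      v <- vnames[m]
      Sres[[v]] <- list()
      Ew2 <- Wmu[[v]]^2 + Wvar[[v]]
      for (g in gnames) {
        Ez2 <- Zmu[[g]]^2 + Zvar[[g]]
        Q <- Ez2 %*% t(Ew2) - (Zmu[[g]]^2) %*% t(Wmu[[v]]^2)
        S <- colSums(Res[[m]][[g]]^2 + O[[m]][[g]] * Q)
        Sres[[v]][[g]] <- S
        a_tau[[v]][[g]] <- hp$e0 + nobs[[v]][[g]] / 2
        b_tau[[v]][[g]] <- hp$f0 + S / 2
        Etau[[v]][[g]] <- a_tau[[v]][[g]] / b_tau[[v]][[g]]
        Elogtau[[v]][[g]] <- digamma(a_tau[[v]][[g]]) - log(b_tau[[v]][[g]])
      }
    }

    ## ---- ELBO ------------------------------------------------------------
    elbo <- 0
    for (v in vnames) for (g in gnames) {
      elbo <- elbo + sum(0.5 * nobs[[v]][[g]] * (Elogtau[[v]][[g]] - log2pi) -
                         0.5 * Etau[[v]][[g]] * Sres[[v]][[g]])
      ## tau prior + entropy
      elbo <- elbo + sum(hp$e0 * log(hp$f0) - lgamma(hp$e0) +
                         (hp$e0 - 1) * Elogtau[[v]][[g]] -
                         hp$f0 * Etau[[v]][[g]]) +
              sum(gamma_entropy(a_tau[[v]][[g]], b_tau[[v]][[g]]))
    }
    for (gi in seq_len(G)) {
      g <- gnames[gi]
      Ez2 <- colSums(Zmu[[g]]^2 + Zvar[[g]])
      if (single_group) {
        elbo <- elbo + sum(-0.5 * Ng[gi] * log2pi - 0.5 * Ez2)
      } else {
        Elogbeta <- digamma(a_beta[g]) - log(b_beta[[g]])
        elbo <- elbo + sum(0.5 * Ng[gi] * (Elogbeta - log2pi) -
                           0.5 * Ebeta[[g]] * Ez2)
        elbo <- elbo + sum(hp$c0 * log(hp$d0) - lgamma(hp$c0) +
                           (hp$c0 - 1) * Elogbeta - hp$d0 * Ebeta[[g]]) +
                sum(gamma_entropy(a_beta[g], b_beta[[g]]))
      }
      elbo <- elbo + 0.5 * sum(log(2 * pi * exp(1) * Zvar[[g]]))
    }
    for (m in seq_len(M)) {
      v <- vnames[m]
      Ew2 <- colSums(Wmu[[v]]^2 + Wvar[[v]])
      Elogalpha <- digamma(a_alpha[v]) - log(b_alpha[[v]])
      elbo <- elbo + sum(0.5 * D[m] * (Elogalpha - log2pi) -
                         0.5 * Ealpha[[v]] * Ew2)
      elbo <- elbo + sum(hp$a0 * log(hp$b0) - lgamma(hp$a0) +
                         (hp$a0 - 1) * Elogalpha - hp$b0 * Ealpha[[v]]) +
              sum(gamma_entropy(a_alpha[v], b_alpha[[v]]))
      elbo <- elbo + 0.5 * sum(log(2 * pi * exp(1) * Wvar[[v]]))
    }

    elbo_trace <- c(elbo_trace, unname(elbo))
    if (iter > 1L) {
      delta <- abs(elbo - elbo_trace[iter - 1L]) / abs(elbo)
      if (delta < hp$tol) break
    }
  }

  model <- structure(list(
    W = lapply(vnames, function(v) {
      m <- Wmu[[v]]
      rownames(m) <- colnames(data$views[[v]])
      colnames(m) <- paste0("Factor", seq_len(K)); m
    }),
    W_var = lapply(vnames, function(v) {
      m <- Wvar[[v]]
      dimnames(m) <- list(colnames(data$views[[v]]),
                          paste0("Factor", seq_len(K))); m
    }),
    Z = lapply(gnames, function(g) {
      m <- Zmu[[g]]
      rownames(m) <- rows_g[[g]]
      colnames(m) <- paste0("Factor", seq_len(K)); m
    }),
    Z_var = lapply(gnames, function(g) {
      m <- Zvar[[g]]
      dimnames(m) <- list(rows_g[[g]], paste0("Factor", seq_len(K))); m
    }),
    alpha = lapply(vnames, function(v) setNames(Ealpha[[v]],
                                                paste0("Factor", seq_len(K)))),
    beta = lapply(gnames, function(g) setNames(Ebeta[[g]],
                                               paste0("Factor", seq_len(K)))),
    tau = lapply(vnames, function(v) Etau[[v]]),
    elbo_trace = elbo_trace,
    K = K, view_names = vnames, group_names = gnames,
    view_kind = data$view_kind,
    transform = data$transform,
    groups = data$groups,
    hp = hp,
    converged = length(elbo_trace) < hp$max_iter), class = "gfa_model")
  names(model$W) <- names(model$W_var) <- vnames
  names(model$Z) <- names(model$Z_var) <- gnames
  names(model$alpha) <- names(model$tau) <- vnames
  names(model$beta) <- gnames
  model$r2 <- explained_variance(model, data)
  model
}

#' @export
print.gfa_model <- function(x, ...) {
  cat(sprintf("gfa_model: K=%d, %d views, %d groups, %d iterations%s\n",
              x$K, length(x$view_names), length(x$group_names),
              length(x$elbo_trace),
              if (x$converged) " (converged)" else ""))
  cat(sprintf("  total explained variance: %.1f%%\n",
              100 * x$r2$overall_total))
  invisible(x)
}

#' Explained variance decomposition of a fitted model
#'
#' For every (view, group, factor) the fraction of the observed sum of
#' squares captured by the single-factor reconstruction, and per
#' (view, group) the total over the full reconstruction. Masked entries
#' are excluded from both sums; raw (possibly negative) values are kept.
#'
#' @param model a `gfa_model`.
#' @param data the `multiview_dataset` it was fitted on.
#' @return list with `per_factor` (view x group x factor array), `total`
#'   (view x group), `factor_total` (per factor, aggregated over all views
#'   and groups) and `overall_total`.
#' @export
explained_variance <- function(model, data) {
  vnames <- model$view_names; gnames <- model$group_names
  K <- model$K
  per <- array(NA_real_, c(length(vnames), length(gnames), K),
               dimnames = list(vnames, gnames, paste0("Factor", seq_len(K))))
  tot <- matrix(NA_real_, length(vnames), length(gnames),
                dimnames = list(vnames, gnames))
  num_k <- matrix(0, K, 1); den_all <- 0
  num_f <- rep(0, K); num_tot <- 0
  for (v in vnames) {
    for (g in gnames) {
      rows <- names(model$groups)[model$groups == g]
      y <- data$views[[v]][rows, , drop = FALSE]
      ob <- !is.na(y)
      if (!any(ob)) next
      ss <- sum(y[ob]^2)
      if (ss == 0) next
      z <- model$Z[[g]]; w <- model$W[[v]]
      full <- z %*% t(w)
      tot[v, g] <- 1 - sum(((y - full)[ob])^2) / ss
      for (k in seq_len(K)) {
        rk <- tcrossprod(z[, k], w[, k])
        res <- sum(((y - rk)[ob])^2)
        per[v, g, k] <- 1 - res / ss
        num_f[k] <- num_f[k] + res
      }
      den_all <- den_all + ss
      num_tot <- num_tot + sum(((y - full)[ob])^2)
    }
  }
  list(per_factor = per, total = tot,
       factor_total = setNames(1 - num_f / den_all,
                               paste0("Factor", seq_len(K))),
       overall_total = 1 - num_tot / den_all)
}

#' Reorder and sign-fix the factors of a fitted model
#'
#' Factors are sorted by decreasing total explained variance and each
#' factor's sign is flipped so that the sum of cubed weights is positive
#' in the view where that factor explains the most variance (the scores
#' are flipped to compensate; the reconstruction is invariant). Factors
#' whose total explained variance falls below `inactive_threshold` are
#' flagged inactive.
#'
#' @param model a `gfa_model`.
#' @param inactive_threshold total-r2 fraction below which a factor is
#'   marked inactive (default 0.005).
#' @return the reordered model (idempotent).
#' @export
postprocess_factors <- function(model, inactive_threshold = 0.005) {
  stopifnot(inherits(model, "gfa_model"))
  ft <- model$r2$factor_total
  ord <- order(ft, decreasing = TRUE)
  ## per-factor top view (summed over groups, NAs removed)
  per <- model$r2$per_factor
  flip <- rep(1, model$K)
  for (k in seq_len(model$K)) {
    vtot <- apply(per[, , k, drop = FALSE], 1, sum, na.rm = TRUE)
    topv <- names(which.max(vtot))
    if (sum(model$W[[topv]][, k]^3) < 0) flip[k] <- -1
  }
  out <- model
  fn <- paste0("Factor", seq_len(model$K))
  for (v in model$view_names) {
    out$W[[v]] <- sweep(model$W[[v]], 2, flip, "*")[, ord, drop = FALSE]
    out$W_var[[v]] <- model$W_var[[v]][, ord, drop = FALSE]
    colnames(out$W[[v]]) <- colnames(out$W_var[[v]]) <- fn
    out$alpha[[v]] <- setNames(model$alpha[[v]][ord], fn)
  }
  for (g in model$group_names) {
    out$Z[[g]] <- sweep(model$Z[[g]], 2, flip, "*")[, ord, drop = FALSE]
    out$Z_var[[g]] <- model$Z_var[[g]][, ord, drop = FALSE]
    colnames(out$Z[[g]]) <- colnames(out$Z_var[[g]]) <- fn
    out$beta[[g]] <- setNames(model$beta[[g]][ord], fn)
  }
  out$r2$per_factor <- model$r2$per_factor[, , ord, drop = FALSE]
  dimnames(out$r2$per_factor)[[3]] <- fn
  out$r2$factor_total <- setNames(model$r2$factor_total[ord], fn)
  out$active <- out$r2$factor_total >= inactive_threshold
  out
}

#' Reconstruct a (view, group) block from the fitted factors
#'
#' Returns `E[Z^g] E[W^m]^T`; with `denormalize = TRUE` the per-group
#' feature scaling and centering recorded at assembly time are re-applied.
#'
#' @param model a `gfa_model`.
#' @param view,group names of the block.
#' @param denormalize re-apply scaling/centering (default FALSE).
#' @return samples x features matrix.
#' @export
reconstruct <- function(model, view, group, denormalize = FALSE) {
  if (!view %in% model$view_names) stop("unknown view: ", view)
  if (!group %in% model$group_names) stop("unknown group: ", group)
  rec <- model$Z[[group]] %*% t(model$W[[view]])
  colnames(rec) <- rownames(model$W[[view]])
  if (denormalize) {
    tr <- model$transform[[view]][[group]]
    if (!is.null(tr$scale)) {
      sc <- tr$scale; sc[is.na(sc)] <- 1
      rec <- sweep(rec, 2, sc, "*")
    }
    rec <- sweep(rec, 2, tr$center, "+")
  }
  rec
}
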