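#' Pool FRET values for population analysis
#'
#' Two pooling policies are used for FRET histograms and Gaussian fits:
#' `"steady_state"` pools every unmasked frame of every series (equilibrium
#' distributions), while `"post_sync"` pools the first `M` frames after each
#' trace's synchronization point (the histograms drawn next to
#' post-synchronized contour plots; `M` between 10 and 30 frames, i.e.
#' 0.3-1.0 s at 30 frames/s).
#'
#' @param fret_list list of `fret_series`.
#' @param policy `"steady_state"` or `"post_sync"`.
#' @param M number of post-synchronization frames pooled (default 20).
#' @param sync_frames integer vector, one 0-based synchronization frame per
#'   series (`NA` drops the trace); required for `"post_sync"`. See
#'   [synchronize_traces()].
#' @return numeric vector of pooled FRET values.
#' @export
collect_fret_samples <- function(fret_list, policy = c("steady_state", "post_sync"),
                                 M = 20, sync_frames = NULL) {
  policy <- match.arg(policy)
  if (policy == "steady_state") {
    return(unlist(lapply(fret_list, function(f) f$fret[f$valid])))
  }
  if (is.null(sync_frames) || length(sync_frames) != length(fret_list)) {
    stop("post_sync pooling needs one sync frame per series")
  }
  if (M < 1) stop("M must be >= 1")
  out <- lapply(seq_along(fret_list), function(i) {
    s <- sync_frames[i]
    if (is.na(s)) return(numeric(0))
    f <- fret_list[[i]]
    # frame indices are 0-based positions in the original trace
    pos <- match(s + 0:(M - 1), which_frames(f))
    pos <- pos[!is.na(pos)]
    f$fret[pos][f$valid[pos]]
  })
  unlist(out)
}

which_frames <- function(f) {
  # 0-based frame index of each stored value of a fret_series
  seq_along(f$fret) - 1L
}

#' Fit a Gaussian mixture to pooled FRET values
#'
#' The population distributions reported for each complex: component means,
#' sds and weights (`p`, the area fraction of each Gaussian). The default
#' method is maximum-likelihood EM on the raw pooled values with quantile
#' initialization and seeded restarts, which makes the fitted populations
#' independent of any histogram bin width. `method = "binned"` performs the
#' classical least-squares fit of Gaussians to the binned histogram instead;
#' on clean data the two agree.
#'
#' @param values pooled FRET values (from [collect_fret_samples()]).
#' @param n_components number of Gaussian components.
#' @param method `"em"` (default) or `"binned"`.
#' @param n_restarts randomized EM restarts.
#' @param max_iter,tol EM iteration cap and relative tolerance.
#' @param seed seed for the restarts.
#' @param binwidth histogram bin width for `method = "binned"` (FRET units).
#' @param init_means optional starting component means (e.g. the median
#'   fitted HMM state means across traces); restarts then perturb around
#'   these instead of the sample quantiles, which stabilizes fits on
#'   fast-exchange data where frame averaging adds intermediate density.
#' @return An object of class `gmm_fit`: `mean`, `sd`, `weight` (sum to 1),
#'   `loglik`, `n`, `method`, components sorted by ascending mean.
#' @examples
#' v <- c(rnorm(800, 0.73, 0.05), rnorm(200, 0.52, 0.05))
#' fit <- fit_gmm(v, 2)
#' round(fit$mean, 2); round(fit$weight, 2)
#' @export
fit_gmm <- function(values, n_components, method = c("em", "binned"),
                    n_restarts = 3, max_iter = 500, tol = 1e-8, seed = 1,
                    binwidth = 0.02, init_means = NULL) {
  method <- match.arg(method)
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 10 * n_components) {
    stop("need at least 10 values per component (have ", n, ")")
  }
  if (sd(x) == 0) stop("degenerate input: all values identical")

  if (method == "binned") {
    return(fit_gmm_binned(x, n_components, binwidth))
  }

  if (is.null(init_means)) {
    base_means <- quantile(x, (seq_len(n_components)) / (n_components + 1),
                           names = FALSE)
    jitter_sd <- sd(x) / 2
  } else {
    stopifnot(length(init_means) == n_components)
    base_means <- sort(init_means)
    jitter_sd <- 0.02
  }
  spread <- sd(x)
  best <- NULL
  for (r in 0:n_restarts) {
    mu0 <- base_means
    if (r > 0) {
      set.seed(seed + r)
      mu0 <- base_means + rnorm(n_components, 0, jitter_sd)
    }
    fit <- gmm_em(x, mu0, rep(spread / sqrt(n_components), n_components),
                  max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mean)
  structure(
    list(mean = best$mean[ord], sd = best$sd[ord], weight = best$weight[ord],
         loglik = best$loglik, n = n, method = "em",
         bic = -2 * best$loglik + (3 * n_components - 1) * log(n)),
    class = "gmm_fit"
  )
}

gmm_em <- function(x, mu, s, max_iter, tol) {
  K <- length(mu)
  n <- length(x)
  w <- rep(1 / K, K)
  s <- pmax(s, 1e-4)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k) w[k] * dnorm(x, mu[k], s[k]),
                   numeric(n))
    dim(dens) <- c(n, K)
    tot <- rowSums(dens)
    tot[tot <= 0] <- 1e-300
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    s <- sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk)
    s <- pmax(s, 1e-4)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll_prev) + 1)) break
    ll_prev <- ll
  }
  list(mean = mu, sd = s, weight = w, loglik = ll)
}

fit_gmm_binned <- function(x, K, binwidth) {
  breaks <- seq(floor(min(x) / binwidth) * binwidth,
                ceiling(max(x) / binwidth) * binwidth + binwidth, by = binwidth)
  h <- hist(x, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  # least squares on the binned histogram; parameters on transformed scale
  em0 <- fit_gmm(x, K, method = "em")
  par0 <- c(em0$mean, log(em0$sd), qlogis(pmin(pmax(em0$weight, 1e-6), 1 - 1e-6)))
  model <- function(p) {
    mu <- p[1:K]
    s <- exp(p[(K + 1):(2 * K)])
    wraw <- plogis(p[(2 * K + 1):(3 * K)])
    w <- wraw / sum(wraw)
    dens <- vapply(seq_len(K), function(k) w[k] * dnorm(mids, mu[k], s[k]),
                   numeric(length(mids)))
    rowSums(matrix(dens, ncol = K)) * length(x) * binwidth
  }
  obj <- function(p) sum((model(p) - counts)^2)
  opt <- optim(par0, obj, method = "BFGS", control = list(maxit = 500))
  mu <- opt$par[1:K]
  s <- exp(opt$par[(K + 1):(2 * K)])
  w <- plogis(opt$par[(2 * K + 1):(3 * K)])
  w <- w / sum(w)
  ord <- order(mu)
  structure(
    list(mean = mu[ord], sd = s[ord], weight = w[ord],
         loglik = NA_real_, n = length(x), method = "binned",
         rss = opt$value),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("Gaussian mixture (", x$method, "), ", length(x$mean),
      " component(s), n = ", x$n, "\n", sep = "")
  print(data.frame(mean = round(x$mean, 4), sd = round(x$sd, 4),
                   p = round(x$weight, 4)), row.names = FALSE)
  invisible(x)
}

#' Fraction of dynamic traces
#'
#' The fraction of traces showing at least one surviving transition after
#' state merging, with its binomial standard error. Complexes are described
#' as dynamic (frequent reversible transitions) or static (transitions in
#' less than ~20% of traces) by this quantity.
#'
#' @param paths list of `idealized_path` (after [exclude_for_kinetics()]).
#' @return list with `fraction`, `se`, `n_dynamic`, `n_traces`.
#' @export
dynamic_fraction <- function(paths) {
  if (length(paths) == 0) stop("no idealized paths supplied")
  dyn <- vapply(paths, function(p) p$n_transitions >= 1, logical(1))
  p <- mean(dyn)
  list(
    fraction = p,
    se = sqrt(p * (1 - p) / length(dyn)),
    n_dynamic = sum(dyn),
    n_traces = length(dyn)
  )
}
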