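# Mass-photometry dimerization analysis: Gaussian-mixture fit of the
# single-particle mass histogram, dimer particle fraction, and the
# law-of-mass-action relation between fraction, total concentration and
# dissociation constant for M + M <=> D.

#' A set of single-particle mass events
#'
#' @param masses numeric vector of particle masses, kDa (all positive).
#' @param c_total total monomer-equivalent concentration of the assay, nM.
#' @param replicate replicate identifier.
#' @return A list of class `mass_events`.
#' @export
mass_events <- function(masses, c_total, replicate = 1L) {
  masses <- as.numeric(masses)
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("masses must be positive and finite", call. = FALSE)
  }
  if (c_total <= 0) stop("c_total must be > 0", call. = FALSE)
  structure(list(masses = masses, c_total = c_total, replicate = replicate),
            class = "mass_events")
}

.gauss_loglik <- function(x, means, sds, weights) {
  dens <- vapply(seq_along(means), function(j) {
    weights[j] * stats::dnorm(x, means[j], sds[j])
  }, numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(rowSums(dens)))
}

#' Fit a Gaussian mixture to a mass histogram by EM
#'
#' Expectation-maximization with deterministic initialization: component
#' `i` of `k` starts at the mass quantile `(i - 0.5)/k`, with equal
#' weights and the pooled standard deviation. Convergence is declared
#' when the log-likelihood improves by less than `tol` (default 1e-8) or
#' after `max_iter` iterations. Components are reported sorted by mean.
#'
#' A fit is flagged degenerate when any component weight drops below
#' 1e-3 or any standard deviation collapses below 0.1 kDa; downstream
#' consumers then fall back to threshold classification.
#'
#' @param events a [mass_events()] or numeric vector of masses (kDa).
#' @param components number of Gaussian components (default 2:
#'   monomer and dimer).
#' @param max_iter iteration cap.
#' @param tol log-likelihood convergence tolerance.
#' @return A list of class `mass_mixture`: `means`, `sds`, `weights`
#'   (ascending by mean), `loglik`, `iterations`, `converged`,
#'   `degenerate`, `n`.
#' @export
fit_mass_mixture <- function(events, components = 2L, max_iter = 500L,
                             tol = 1e-8) {
  x <- if (inherits(events, "mass_events")) events$masses else as.numeric(events)
  n <- length(x)
  if (n < 50) stop("need at least 50 events to fit a mixture", call. = FALSE)
  k <- as.integer(components)
  means <- as.numeric(stats::quantile(x, probs = (seq_len(k) - 0.5) / k,
                                      names = FALSE))
  sds <- rep(max(stats::sd(x), 1e-6), k)
  weights <- rep(1 / k, k)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E step
    dens <- vapply(seq_len(k), function(j) {
      weights[j] * stats::dnorm(x, means[j], sds[j])
    }, numeric(n))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    resp <- dens / tot
    # M step
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.xmin
    weights <- nk / n
    means <- colSums(resp * x) / nk
    sds <- sqrt(colSums(resp * (x - rep(means, each = n))^2) / nk)
    sds <- pmax(sds, 1e-8)
    ll <- sum(log(tot))
    if (is.finite(ll) && ll - ll_old < tol && iter > 1L) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  ord <- order(means)
  degenerate <- any(weights < 1e-3) || any(sds < 0.1)
  structure(list(means = means[ord], sds = sds[ord], weights = weights[ord],
                 loglik = .gauss_loglik(x, means[ord], sds[ord], weights[ord]),
                 iterations = iter, converged = converged,
                 degenerate = degenerate, n = n),
            class = "mass_mixture")
}

#' Dimer particle fraction from a mixture fit
#'
#' In mixture mode, the dimer fraction is the weight of the component
#' whose mean is nearest twice the monomer mass; the component must land
#' within 25% (relative) of the expected dimer mass. When the fit is
#' degenerate (or `fit` is `NULL`), the fallback classifies events by a
#' 1.5x-monomer mass threshold. The fraction is by particle count, the
#' quantity a landing-event histogram measures.
#'
#' @param fit a [fit_mass_mixture()] result, or `NULL` to force fallback.
#' @param monomer_kda expected monomer mass, kDa.
#' @param events events used for the fallback mode.
#' @return Dimer particle fraction in \[0, 1\].
#' @export
dimer_fraction <- function(fit, monomer_kda, events = NULL) {
  fallback <- function() {
    if (is.null(events)) stop("fallback classification requires events", call. = FALSE)
    x <- if (inherits(events, "mass_events")) events$masses else as.numeric(events)
    mean(x > 1.5 * monomer_kda)
  }
  if (is.null(fit) || isTRUE(fit$degenerate)) return(fallback())
  stopifnot(inherits(fit, "mass_mixture"))
  target <- 2 * monomer_kda
  rel_dev <- abs(fit$means - target) / target
  j <- which.min(rel_dev)
  if (rel_dev[j] > 0.25) {
    stop("no mixture component within 25% of the dimer mass (",
         target, " kDa)", call. = FALSE)
  }
  fit$weights[j]
}

#' Dissociation constant from the dimer particle fraction
#'
#' For M + M <=> D with particle dimer fraction
#' \eqn{p = [D]/([M]+[D])} and total monomer-equivalent concentration
#' \eqn{C = [M] + 2[D]}, the law of mass action
#' \eqn{K_d = [M]^2/[D]} gives
#' \deqn{K_d = C (1-p)^2 / (p (1+p)).}
#'
#' @param p dimer particle fraction, in (0, 1\].
#' @param c_total total monomer-equivalent concentration, nM.
#' @return Kd in nM (`0` when `p = 1`).
#' @export
kd_from_fraction <- function(p, c_total) {
  if (c_total <= 0) stop("c_total must be > 0", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  if (any(p == 0)) stop("no dimer observed (Kd unbounded)", call. = FALSE)
  ifelse(p == 1, 0, c_total * (1 - p)^2 / (p * (1 + p)))
}

#' Forward monomer-dimer equilibrium
#'
#' Solves the law of mass action for given Kd and total concentration:
#' \eqn{[M] = (K_d/4)(\sqrt{1 + 8C/K_d} - 1)}, \eqn{[D] = (C - [M])/2},
#' and the particle dimer fraction \eqn{p = [D]/([M]+[D])}.
#'
#' @param kd dissociation constant, nM (> 0).
#' @param c_total total monomer-equivalent concentration, nM (> 0).
#' @return A list with `p` and `state` (`monomer`, `dimer`, `c_total`,
#'   `kd`, all nM); the state satisfies \eqn{[M] + 2[D] = C} to 1e-9
#'   relative.
#' @export
equilibrium_fraction <- function(kd, c_total) {
  if (kd <= 0 || c_total <= 0) stop("kd and c_total must be > 0", call. = FALSE)
  # rationalised root of 2[M]^2/Kd + [M] - C = 0; avoids the cancellation
  # in (sqrt(1 + x) - 1) when 8C/Kd is small
  m <- 2 * c_total / (1 + sqrt(1 + 8 * c_total / kd))
  d <- (c_total - m) / 2
  p <- d / (m + d)
  list(p = p, state = list(monomer = m, dimer = d, c_total = c_total, kd = kd))
}

#' Estimate a dimerization Kd from replicate mass-event sets
#'
#' Per replicate: two-component Gaussian-mixture fit, dimer particle
#' fraction, law-of-mass-action inversion. The reported Kd is the mean of
#' the per-replicate estimates.
#'
#' @param event_sets a list of [mass_events()] (one per replicate), or a
#'   single `mass_events`.
#' @param monomer_kda expected monomer mass, kDa.
#' @return A list of class `kd_estimate`: `per_replicate` (data.frame
#'   with `replicate`, `n`, `p`, `kd_nM`), `kd_nM`, `kd_uM`, and `fits`.
#' @export
estimate_kd <- function(event_sets, monomer_kda) {
  if (inherits(event_sets, "mass_events")) event_sets <- list(event_sets)
  fits <- lapply(event_sets, fit_mass_mixture)
  per <- do.call(rbind, lapply(seq_along(event_sets), function(i) {
    ev <- event_sets[[i]]
    p <- dimer_fraction(fits[[i]], monomer_kda, events = ev)
    data.frame(replicate = ev$replicate, n = length(ev$masses), p = p,
               kd_nM = kd_from_fraction(p, ev$c_total))
  }))
  structure(list(per_replicate = per,
                 kd_nM = mean(per$kd_nM),
                 kd_uM = mean(per$kd_nM) / 1000,
                 fits = fits),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  cat("Dimerization Kd estimate (monomer-dimer equilibrium)\n")
  cat(sprintf("  replicates: %d\n", nrow(x$per_replicate)))
  for (i in seq_len(nrow(x$per_replicate))) {
    cat(sprintf("  replicate %s: n = %d, dimer fraction p = %.4f, Kd = %.1f nM\n",
                x$per_replicate$replicate[i], x$per_replicate$n[i],
                x$per_replicate$p[i], x$per_replicate$kd_nM[i]))
  }
  cat(sprintf("  pooled Kd: %.1f nM = %.2f uM\n", x$kd_nM, x$kd_uM))
  invisible(x)
}
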