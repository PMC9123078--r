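# Axial circular statistics. AoP is axial (180-degree period): angles are
# doubled, ordinary circular statistics applied on the doubled scale, and
# mean directions halved back. Notation follows Batschelet: mean resultant
# vector length r in [0, 1], preferred AoP phi_max in [0, 180).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Axial sample of polarizer orientations
#'
#' @param angles degrees; reduced modulo 360.
#' @return list of class `"axial_sample"` with `angles` and the `doubled`
#'   angles (`(2 * angles) mod 360`) that ordinary circular statistics are
#'   applied to.
#' @export
axial_sample <- function(angles) {
  angles <- as.numeric(angles) %% 360
  structure(list(angles = angles, doubled = (2 * angles) %% 360),
            class = "axial_sample")
}

#' Axial mean direction and resultant length
#'
#' Doubles the angles, takes the vector-sum mean direction and mean
#' resultant length on the doubled scale, and halves the mean direction,
#' yielding the preferred AoP `phi_max` in `[0, 180)` and the directedness
#' `r` in `[0, 1]`.
#'
#' @param sample an [axial_sample()] or a numeric vector of degrees.
#' @return list of class `"circ_result"`: `phi_max` (degrees, `NA` when the
#'   resultant is numerically zero, with `phi_defined = FALSE`), `r`, `n`.
#' @export
axial_mean <- function(sample) {
  if (!inherits(sample, "axial_sample")) sample <- axial_sample(sample)
  n <- length(sample$angles)
  if (n == 0L)
    stop("axial_mean is undefined for an empty sample")
  th <- deg2rad(sample$doubled)
  C <- mean(cos(th))
  S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  defined <- r > 1e-12
  phi <- if (defined) (rad2deg(atan2(S, C)) %% 360) / 2 else NA_real_
  structure(list(phi_max = phi, r = r, n = n, phi_defined = defined),
            class = "circ_result")
}

#' @export
print.circ_result <- function(x, ...) {
  cat(sprintf("<circ_result> n=%d, r=%.3f, phi_max=%s\n", x$n, x$r,
              if (x$phi_defined) sprintf("%.1f deg", x$phi_max) else "undefined"))
  invisible(x)
}

#' Circular-linear correlation of binned spike counts with bin angle
#'
#' Tests whether spike counts per AoP bin are correlated with the (doubled)
#' bin angle. With counts x and doubled angles theta:
#' `rcx = cor(x, cos theta)`, `rsx = cor(x, sin theta)`,
#' `rcs = cor(cos theta, sin theta)`, and
#' \deqn{r_{cl} = \sqrt{(r_{cx}^2 + r_{sx}^2 - 2 r_{cx} r_{sx} r_{cs}) / (1 - r_{cs}^2)}.}
#' The asymptotic p-value refers `n * r_cl^2` to a chi-square distribution
#' with 2 df; the permutation p-value shuffles counts across bins.
#'
#' @param bin_counts spike counts per bin.
#' @param bin_centers_doubled doubled bin-centre angles, degrees.
#' @param method `"asymptotic"` or `"permutation"`.
#' @param n_perm permutations (>= 100) for the permutation method.
#' @param seed optional seed for the permutation method.
#' @return list with `r_cl`, `p`, `n`, `method`.
#' @export
circ_linear_corr <- function(bin_counts, bin_centers_doubled,
                             method = c("asymptotic", "permutation"),
                             n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  n <- length(bin_counts)
  if (length(bin_centers_doubled) != n)
    stop("bin_counts and bin_centers_doubled must have the same length")
  if (n < 3L) stop("need at least 3 bins")
  if (stats::var(bin_counts) == 0)
    stop(structure(class = c("polspike_degenerate_error", "error", "condition"),
                   list(message = "constant bin counts: correlation undefined",
                        call = NULL)))
  if (method == "permutation" && n_perm < 100)
    stop("n_perm must be at least 100 for the permutation method")
  th <- deg2rad(bin_centers_doubled)
  cs <- cos(th); sn <- sin(th)
  rcs <- stats::cor(cs, sn)
  r_of <- function(x) {
    rcx <- stats::cor(x, cs)
    rsx <- stats::cor(x, sn)
    num <- rcx^2 + rsx^2 - 2 * rcx * rsx * rcs
    sqrt(max(0, min(1, num / (1 - rcs^2))))
  }
  r_cl <- r_of(bin_counts)
  p <- if (method == "asymptotic") {
    stats::pchisq(n * r_cl^2, df = 2, lower.tail = FALSE)
  } else {
    exc <- with_seed(seed, {
      perms <- vapply(seq_len(n_perm), function(i) sample(bin_counts),
                      numeric(n))
      pc <- perms - rep(colMeans(perms), each = n)
      sdp <- sqrt(colSums(pc^2))
      csc <- (cs - mean(cs)) / sqrt(sum((cs - mean(cs))^2))
      snc <- (sn - mean(sn)) / sqrt(sum((sn - mean(sn))^2))
      rcx <- colSums(pc * csc) / sdp
      rsx <- colSums(pc * snc) / sdp
      num <- rcx^2 + rsx^2 - 2 * rcx * rsx * rcs
      rp <- sqrt(pmax(0, pmin(1, num / (1 - rcs^2))))
      sum(rp >= r_cl - 1e-12)
    })
    (1 + exc) / (n_perm + 1)
  }
  list(r_cl = r_cl, p = p, n = n, method = method)
}

# ---- bimodal (axial) von Mises tuning fit ----------------------------------

vm_curve <- function(theta_deg, b, a, kappa, mu)
  b + a * exp(kappa * cos(2 * (theta_deg - mu) * pi / 180))

# for fixed (mu, kappa) the model is linear in (b, a): solve by least
# squares with b >= 0, a >= 0 (keeps the fitted rate non-negative and the
# mode at mu)
vm_profile <- function(theta, rates, mu, kappa) {
  x <- exp(kappa * cos(2 * (theta - mu) * pi / 180))
  fit_ba <- function(b, a) sum((rates - b - a * x)^2)
  xc <- x - mean(x); yc <- rates - mean(rates)
  sxx <- sum(xc^2)
  a <- if (sxx > 0) sum(xc * yc) / sxx else 0
  b <- mean(rates) - a * mean(x)
  if (a < 0 || b < 0) {
    # constrained corners
    a0 <- max(0, sum(rates * x) / sum(x^2))        # b = 0
    b0 <- max(0, mean(rates))                      # a = 0
    cand <- rbind(c(0, a0), c(b0, 0))
    rss <- apply(cand, 1L, function(p) fit_ba(p[1L], p[2L]))
    b <- cand[which.min(rss), 1L]; a <- cand[which.min(rss), 2L]
  }
  list(b = b, a = a, rss = fit_ba(b, a))
}

#' Fit a bimodal (axial) von Mises tuning curve to binned firing rates
#'
#' Least-squares fit of the firing-rate curve
#' \deqn{rate(\theta) = b + a\, e^{\kappa \cos(2(\theta - \mu))}}
#' to the per-bin rates, an un-normalised axial von Mises shape with mode at
#' the preferred AoP \eqn{\mu} and antimode 90 degrees away (`a >= 0`). The
#' fit multistarts over \eqn{\mu \in \{0, 45, 90, 135\}} degrees and
#' \eqn{\kappa \in \{0.5, 2\}} and keeps the lowest residual sum of squares,
#' breaking exact ties towards the smallest \eqn{\kappa}.
#'
#' @param rates firing rates per bin, spikes/s (or a `binned_response`,
#'   whose rates and bin centres are used).
#' @param bin_centers AoP bin centres in degrees; required when `rates` is a
#'   bare vector.
#' @return An object of class `"vonmises_fit"` with components `b` (offset),
#'   `a` (gain), `kappa` (concentration), `mu` (preferred AoP, degrees in
#'   `[0, 180)`), `rss`, `converged`, `mu_defined` (`FALSE` for flat data
#'   where the preferred angle is unidentifiable), and the data.
#' @seealso [rate_at()], [coef.vonmises_fit()], [predict.vonmises_fit()]
#' @export
fit_bimodal_von_mises <- function(rates, bin_centers = NULL) {
  if (inherits(rates, "binned_response")) {
    bin_centers <- rates$bin_centers
    rates <- rates$rates
  }
  if (is.null(bin_centers))
    stop("bin_centers required when rates is a plain vector")
  theta <- as.numeric(bin_centers)
  rates <- as.numeric(rates)

  obj <- function(par) {
    kappa <- max(par[2L], 0)
    vm_profile(theta, rates, par[1L], kappa)$rss
  }
  best <- NULL
  for (mu0 in c(0, 45, 90, 135)) for (k0 in c(0.5, 2)) {
    fit <- tryCatch(
      stats::optim(c(mu0, k0), obj, method = "L-BFGS-B",
                   lower = c(-Inf, 0), upper = c(Inf, 50),
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    take <- is.null(best) || fit$value < best$value - 1e-12 ||
      (abs(fit$value - best$value) <= 1e-12 && fit$par[2L] < best$par[2L])
    if (take) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(b = mean(rates), a = 0, kappa = 0, mu = NA_real_,
                          rss = sum((rates - mean(rates))^2),
                          converged = FALSE, mu_defined = FALSE,
                          rates = rates, bin_centers = theta),
                     class = "vonmises_fit"))
  }
  mu <- best$par[1L] %% 180
  kappa <- max(best$par[2L], 0)
  ba <- vm_profile(theta, rates, mu, kappa)
  # the angle is unidentifiable when the modulated part of the curve is flat
  depth <- ba$a * (exp(kappa) - exp(-kappa))
  mu_defined <- depth > 1e-6 * max(1, max(abs(rates)))
  structure(list(b = ba$b, a = ba$a, kappa = kappa,
                 mu = if (mu_defined) mu else NA_real_, rss = ba$rss,
                 converged = TRUE, mu_defined = mu_defined,
                 rates = rates, bin_centers = theta),
            class = "vonmises_fit")
}

#' Fitted firing rate at an angle
#'
#' Evaluates the fitted tuning curve; by construction
#' `rate_at(fit, mu) >= rate_at(fit, mu + 90)` and the curve has period
#' 180 degrees.
#'
#' @param fit a [fit_bimodal_von_mises()] result.
#' @param theta angle(s), degrees.
#' @return spikes/s.
#' @export
rate_at <- function(fit, theta) {
  mu <- if (is.na(fit$mu)) 0 else fit$mu
  vm_curve(theta, fit$b, fit$a, fit$kappa, mu)
}

#' @export
coef.vonmises_fit <- function(object, ...)
  c(b = object$b, a = object$a, kappa = object$kappa, mu = object$mu)

#' @rdname rate_at
#' @param object a `"vonmises_fit"`.
#' @param newdata angles in degrees (defaults to the fitted bin centres).
#' @param ... unused.
#' @export
predict.vonmises_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$bin_centers
  rate_at(object, newdata)
}

#' @export
fitted.vonmises_fit <- function(object, ...) rate_at(object, object$bin_centers)

#' @export
residuals.vonmises_fit <- function(object, ...)
  object$rates - fitted(object)

#' @export
print.vonmises_fit <- function(x, ...) {
  cat("Bimodal (axial) von Mises tuning fit\n")
  if (!x$converged) {
    cat("  fit failed on all starts; falling back to the mean rate\n")
  } else {
    cat(sprintf("  rate(theta) = %.3f + %.3f * exp(%.3f * cos(2(theta - %s)))\n",
                x$b, x$a, x$kappa,
                if (x$mu_defined) sprintf("%.1f deg", x$mu) else "<undefined>"))
    cat(sprintf("  rss = %.4g over %d bins\n", x$rss, length(x$rates)))
  }
  invisible(x)
}

#' @export
plot.vonmises_fit <- function(x, ...) {
  grid <- seq(0, 180, by = 1)
  plot(x$bin_centers, x$rates, xlab = "AoP (deg)",
       ylab = "firing rate (sp/s)", pch = 16,
       ylim = range(c(x$rates, rate_at(x, grid))), ...)
  graphics::lines(grid, rate_at(x, grid), col = "firebrick")
  invisible(x)
}
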