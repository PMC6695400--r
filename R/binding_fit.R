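# Exact 1:1 equilibrium binding with ligand depletion, Kd estimation from
# titration data, bootstrap uncertainty. The classic modelling-idiom part of
# the package: fit_kd() returns a classed object with the usual methods.

#' Fraction of receptor bound under 1:1 mass action with ligand depletion
#'
#' Exact solution of `R + L <-> RL` at total concentrations `R` (labelled,
#' constant species) and `L` (titrated ligand):
#' `f = ((R + L + kd) - sqrt((R + L + kd)^2 - 4 R L)) / (2 R)`.
#' Unlike the simple hyperbola this remains correct when `R` is comparable
#' to `kd`, as in thermophoresis titrations of tight binders.
#'
#' @param R Total receptor concentration (molar, > 0).
#' @param L Total ligand concentration (molar, >= 0, vectorised).
#' @param kd Dissociation constant (molar, > 0).
#' @return Bound fraction in `[0, min(1, L/R)]`.
#' @export
fraction_bound <- function(R, L, kd) {
  stopifnot(R > 0, all(L >= 0), kd > 0)
  s <- R + L + kd
  disc <- s * s - 4 * R * L
  rl <- (s - sqrt(pmax(0, disc))) / 2
  pmin(pmax(rl / R, 0), 1)
}

#' Construct a titration data set
#'
#' @param ligand_conc Titrated ligand concentrations (molar, > 0).
#' @param signal Measured signal (arbitrary units).
#' @param receptor_conc Constant labelled-species concentration (molar).
#' @param replicate Optional replicate grouping.
#' @return data.frame of class `titration` with attribute `receptor_conc`.
#' @export
titration <- function(ligand_conc, signal, receptor_conc,
                      replicate = 1L) {
  stopifnot(length(ligand_conc) == length(signal), all(ligand_conc > 0),
            receptor_conc > 0)
  out <- data.frame(ligand_conc = ligand_conc, signal = signal,
                    replicate = rep_len(replicate, length(signal)))
  attr(out, "receptor_conc") <- receptor_conc
  class(out) <- c("titration", "data.frame")
  out
}

# run body under a local RNG stream; global .Random.seed untouched
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# profile fit: for fixed kd the model S = s_free + (s_bound - s_free) * f is
# linear in the endpoints; solve by least squares and return RSS
.profile_rss <- function(log_kd, L, S, R) {
  f <- fraction_bound(R, L, exp(log_kd))
  n <- length(S)
  sf <- sum(f)
  sff <- sum(f * f)
  sS <- sum(S)
  sfS <- sum(f * S)
  det <- n * sff - sf * sf
  if (det < 1e-30) {
    a <- mean(S)
    b <- 0
  } else {
    a <- (sff * sS - sf * sfS) / det
    b <- (n * sfS - sf * sS) / det
  }
  list(rss = sum((S - a - b * f)^2), coef = c(a, b))
}

.fit_kd_core <- function(L, S, R, n_grid = 25) {
  lo <- log(min(L) / 100)
  hi <- log(max(L) * 100)
  grid <- seq(lo, hi, length.out = n_grid)
  rss <- vapply(grid, function(g) .profile_rss(g, L, S, R)$rss, numeric(1))
  k <- which.min(rss)
  bracket <- c(grid[max(1, k - 1)], grid[min(n_grid, k + 1)])
  opt <- stats::optimize(function(g) .profile_rss(g, L, S, R)$rss,
                         interval = bracket, tol = 1e-10)
  best <- .profile_rss(opt$minimum, L, S, R)
  list(kd = exp(opt$minimum), s_free = unname(best$coef[1]),
       s_bound = unname(best$coef[1] + best$coef[2]),
       rss = best$rss)
}

#' Fit a dissociation constant to a titration
#'
#' Least-squares fit of `S(L) = s_free + (s_bound - s_free) *
#' fraction_bound(R, L, kd)`. The endpoints enter linearly, so the fit
#' profiles them out and searches `kd` on a log grid spanning
#' `[min(L)/100, max(L)*100]` followed by local refinement; this makes the
#' estimate invariant to affine rescaling of the signal. Uncertainty comes
#' from case-resampling bootstrap.
#'
#' @param data A [titration()] object.
#' @param n_bootstrap Bootstrap resamples (default 200).
#' @param seed Seed for the bootstrap resampling.
#' @param n_grid Size of the log-spaced kd search grid.
#' @return Object of class `kd_fit`: `kd`, `s_free`, `s_bound`, `kd_sd`
#'   (bootstrap s.d.), `kd_ci` (2.5/97.5% bootstrap quantiles),
#'   `residual_rms`, `no_binding` (TRUE when the lower confidence bound on
#'   kd exceeds the largest ligand concentration), plus data and bootstrap
#'   draws.
#' @export
fit_kd <- function(data, n_bootstrap = 200, seed = 1, n_grid = 25) {
  stopifnot(inherits(data, "titration"))
  L <- data$ligand_conc
  S <- data$signal
  R <- attr(data, "receptor_conc")
  if (length(L) < 6) stop("need at least 6 titration points")
  if (log10(max(L) / min(L)) < 2)
    stop("titration must span at least 2 log units of ligand concentration")
  if (diff(range(S)) == 0) stop("degenerate signal range: signal is constant")
  fit <- .fit_kd_core(L, S, R, n_grid)
  if (abs(fit$s_bound - fit$s_free) < 1e-9 * max(abs(S), 1))
    stop("degenerate fit: no signal amplitude")
  boot <- .with_seed(seed, {
    t(vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(length(L), replace = TRUE)
      if (length(unique(L[idx])) < 3) return(c(NA_real_, NA_real_))
      tryCatch({
        bf <- .fit_kd_core(L[idx], S[idx], R, n_grid)
        c(bf$kd, bf$s_bound - bf$s_free)
      }, error = function(e) c(NA_real_, NA_real_))
    }, numeric(2)))
  })
  boot_kd <- boot[is.finite(boot[, 1]), 1]
  boot_amp <- boot[is.finite(boot[, 2]), 2]
  kd_ci <- if (length(boot_kd)) stats::quantile(boot_kd, c(0.025, 0.975),
                                                names = FALSE)
           else c(NA_real_, NA_real_)
  amp <- fit$s_bound - fit$s_free
  # "no measurable binding": either the data pin kd above the titrated range,
  # or they carry no resolvable amplitude at all (flat titration), in which
  # case kd is unconstrained within the range
  amp_insig <- length(boot_amp) > 1 &&
    abs(amp) < 2 * stats::sd(boot_amp)
  structure(list(kd = fit$kd, s_free = fit$s_free, s_bound = fit$s_bound,
                 kd_sd = if (length(boot_kd)) stats::sd(boot_kd)
                         else NA_real_,
                 kd_ci = kd_ci,
                 residual_rms = sqrt(fit$rss / length(L)),
                 no_binding = (is.finite(kd_ci[1]) && kd_ci[1] > max(L)) ||
                   amp_insig,
                 bootstrap_kd = boot_kd, n_bootstrap = n_bootstrap,
                 data = data, receptor_conc = R, seed = seed),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  if (x$no_binding) {
    cat("kd_fit: no measurable binding within the titrated range (max",
        format(max(x$data$ligand_conc), digits = 3), "M)\n")
  } else {
    cat(sprintf("kd_fit: apparent Kd %.3g M (bootstrap s.d. %.2g M, n = %d)\n",
                x$kd, x$kd_sd, length(x$bootstrap_kd)))
  }
  invisible(x)
}

#' @export
summary.kd_fit <- function(object, ...) {
  cat(sprintf(
    "1:1 ligand-depletion binding fit\n  receptor: %.3g M, %d points\n",
    object$receptor_conc, nrow(object$data)))
  cat(sprintf("  Kd       : %.4g M  (s.d. %.3g, 95%% CI [%.3g, %.3g])\n",
              object$kd, object$kd_sd, object$kd_ci[1], object$kd_ci[2]))
  cat(sprintf("  endpoints: s_free %.4g, s_bound %.4g\n",
              object$s_free, object$s_bound))
  cat(sprintf("  residual rms: %.4g\n", object$residual_rms))
  if (object$no_binding) cat("  verdict: no measurable binding\n")
  invisible(object)
}

#' @export
coef.kd_fit <- function(object, ...) {
  c(kd = object$kd, s_free = object$s_free, s_bound = object$s_bound)
}

#' @export
predict.kd_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$data$ligand_conc
       else if (is.data.frame(newdata)) newdata$ligand_conc else newdata
  object$s_free + (object$s_bound - object$s_free) *
    fraction_bound(object$receptor_conc, L, object$kd)
}

#' @export
residuals.kd_fit <- function(object, ...) {
  object$data$signal - predict(object)
}

#' @export
plot.kd_fit <- function(x, ...) {
  L <- x$data$ligand_conc
  graphics::plot(L, x$data$signal, log = "x",
                 xlab = "ligand concentration (M)", ylab = "signal",
                 main = sprintf("apparent Kd = %.3g M", x$kd), ...)
  grid_L <- exp(seq(log(min(L)), log(max(L)), length.out = 200))
  graphics::lines(grid_L, predict(x, grid_L))
  graphics::abline(v = x$kd, lty = 3)
  invisible(x)
}
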