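#' Fit a power-law model of timescale on per-lineage substitutions
#'
#' The time-dependent rate phenomenon (TDRP) — the apparent decay of measured
#' viral substitution rates with the timescale of measurement — implies a
#' power-law relationship between total per-lineage substitutions `S`
#' (substitutions/site along a focal lineage) and evolutionary timescale `T`
#' (Myr). The model `T = 10^alpha * S^beta` is fitted by ordinary least
#' squares of `log10(T)` on `log10(S)`.
#'
#' @param S Per-lineage substitution estimates (substitutions/site), all > 0.
#' @param T Corresponding timescales (Myr), all > 0; same length as `S`,
#'   at least 3 points.
#' @return An object of class `power_law_fit`: a list with `alpha`
#'   (intercept), `beta` (slope), `r2`, `adjusted_r2`, `residual_se`,
#'   `n_points`, and the input `S`, `T`.
#' @examples
#' f <- fit_power_law(c(1, 2, 4), 10 * c(1, 2, 4)^2)
#' f$beta  # 2
#' @export
fit_power_law <- function(S, T) {
  S <- as.numeric(S); T <- as.numeric(T)
  if (length(S) != length(T)) stop("S and T must have equal length")
  n <- length(S)
  if (n < 3) stop("power-law fit requires >= 3 points (adjusted R^2 undefined below)")
  if (any(!is.finite(S)) || any(!is.finite(T)) || any(S <= 0) || any(T <= 0)) {
    stop("all S and T must be finite and > 0 (log10 undefined otherwise)")
  }
  x <- log10(S); y <- log10(T)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("all S identical: slope undefined")
  beta <- sum((x - mx) * (y - my)) / sxx
  alpha <- my - beta * mx
  resid <- y - (alpha + beta * x)
  rss <- sum(resid^2)
  tss <- sum((y - my)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  structure(list(
    alpha = alpha, beta = beta, r2 = r2, adjusted_r2 = adj,
    residual_se = sqrt(rss / (n - 2)), n_points = n,
    S = S, T = T, residuals = resid
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Power-law TDRP model: log10(T) = alpha + beta * log10(S)\n")
  cat(sprintf("  alpha = %.4f   beta = %.4f\n", x$alpha, x$beta))
  cat(sprintf("  adjusted R^2 = %.4f   residual SE = %.4f   n = %d\n",
              x$adjusted_r2, x$residual_se, x$n_points))
  invisible(x)
}

#' Extrapolate a node age from its substitution estimate
#'
#' Evaluates the fitted power law: `T = 10^(alpha + beta * log10(S))`.
#' Extrapolation beyond the calibration range is permitted (deep nodes are
#' exactly the use case); downstream summaries flag it.
#'
#' @param fit A `power_law_fit`.
#' @param S Substitutions/site, > 0 (vectorised).
#' @return Age(s) in Myr.
#' @export
extrapolate_age <- function(fit, S) {
  stopifnot(inherits(fit, "power_law_fit"))
  S <- as.numeric(S)
  if (any(!is.finite(S)) || any(S <= 0)) stop("S must be finite and > 0")
  10^(fit$alpha + fit$beta * log10(S))
}

#' Highest posterior density interval of a sample
#'
#' The shortest contiguous interval over the sorted sample containing at
#' least `ceiling(mass * n)` points; ties are broken toward the smallest low
#' endpoint.
#'
#' @param samples Numeric vector, length >= 1.
#' @param mass Probability mass in `(0, 1]` (default 0.95).
#' @return Numeric `c(low, high)`.
#' @examples
#' hpd_interval(c(rep(0, 97), 50, 99, 100))
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  samples <- as.numeric(samples)
  if (!length(samples)) stop("empty sample")
  if (any(!is.finite(samples))) stop("non-finite sample values")
  if (mass <= 0 || mass > 1) stop("mass must be in (0, 1]")
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1], s[n]))
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)  # first minimum = smallest low endpoint
  c(s[i], s[i + m - 1])
}

#' Read a calibration table (node, t_median, t_low, t_high, source)
#'
#' @param path TSV with header `node  t_median  t_low  t_high  source`
#'   (`source` optional). Times are Myr.
#' @return Data frame with at least `node`, `t_median`, `t_low`, `t_high`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("node", "t_median", "t_low", "t_high")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("calibration table missing column(s): ", paste(miss, collapse = ", "))
  .validate_calibration(df)
  df
}

.validate_calibration <- function(df) {
  with(df, {
    if (any(t_low > t_median | t_median > t_high)) {
      stop("calibration rows must satisfy t_low <= t_median <= t_high")
    }
    if (any(c(t_low, t_median, t_high) <= 0)) stop("calibration times must be > 0")
  })
  invisible(df)
}

## lognormal whose 2.5/97.5 percentiles match (low, high)
.lnorm_from_interval <- function(low, high) {
  z <- stats::qnorm(0.975)
  list(meanlog = (log(low) + log(high)) / 2,
       sdlog = pmax((log(high) - log(low)) / (2 * z), 0))
}

#' Date uncalibrated nodes across posterior tree samples
#'
#' For each posterior tree: the per-lineage substitution estimate `S` of
#' every calibration and target node is read off the focal lineage
#' ([lineage_depths()]); calibration timescales `T` are taken as fixed
#' medians (`t_sampling = "median"`) or drawn from a lognormal whose
#' 2.5/97.5 percentiles match the calibration interval
#' (`t_sampling = "interval"`); a power law is fitted and each target node's
#' age extrapolated. Per-target samples across trees are summarised by the
#' median and 95% HPD interval.
#'
#' @param trees A `multiPhylo`/list of rooted trees (posterior samples), or a
#'   single `phylo`.
#' @param focal_tip Label of the focal tip whose lineage houses all nodes.
#' @param calibration Data frame as from [read_calibration()]; >= 3 rows.
#' @param calib_specs Named list (calibration node name -> tip label set);
#'   names must cover `calibration$node`.
#' @param target_specs Named list (target node name -> tip label set).
#' @param t_sampling `"median"` (default, reproducible) or `"interval"`.
#' @param seed Integer seed (used by `"interval"` sampling).
#' @return Object of class `age_estimates`: list with `summary` (data frame:
#'   `node`, `median`, `hpd_low`, `hpd_high`, `n_samples`, `extrapolation`),
#'   `samples` (matrix trees x targets), and `fits` (per-tree
#'   `power_law_fit`s).
#' @export
posterior_dating <- function(trees, focal_tip, calibration, calib_specs,
                             target_specs, t_sampling = c("median", "interval"),
                             seed = 1L) {
  t_sampling <- match.arg(t_sampling)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("at least one tree required")
  .validate_calibration(calibration)
  miss <- setdiff(calibration$node, names(calib_specs))
  if (length(miss)) stop("no taxon-set spec for calibration node(s): ", paste(miss, collapse = ", "))
  if (!length(target_specs)) stop("no target nodes given")
  set.seed(as.integer(seed))
  cal_names <- calibration$node
  tgt_names <- names(target_specs)
  n_trees <- length(trees)
  samples <- matrix(NA_real_, n_trees, length(tgt_names),
                    dimnames = list(NULL, tgt_names))
  s_target <- matrix(NA_real_, n_trees, length(tgt_names))
  s_cal_rng <- matrix(NA_real_, n_trees, 2)
  fits <- vector("list", n_trees)
  ln <- .lnorm_from_interval(calibration$t_low, calibration$t_high)
  for (i in seq_len(n_trees)) {
    tr <- trees[[i]]
    prof <- lineage_depths(tr, focal_tip)
    s_of <- function(nm, tipset) {
      nd <- mrca_node(tr, tipset)
      k <- match(nd, prof$node)
      if (is.na(k)) {
        stop(sprintf("tree %d: node '%s' (MRCA of its taxon set) is not on the focal lineage of '%s'",
                     i, nm, focal_tip), call. = FALSE)
      }
      prof$S[k]
    }
    S_cal <- vapply(cal_names, function(nm) s_of(nm, calib_specs[[nm]]), numeric(1))
    S_tgt <- vapply(tgt_names, function(nm) s_of(nm, target_specs[[nm]]), numeric(1))
    T_cal <- if (t_sampling == "median") {
      calibration$t_median
    } else {
      stats::rlnorm(length(cal_names), meanlog = ln$meanlog, sdlog = ln$sdlog)
    }
    fit <- fit_power_law(S_cal, T_cal)
    fits[[i]] <- fit
    samples[i, ] <- extrapolate_age(fit, S_tgt)
    s_target[i, ] <- S_tgt
    s_cal_rng[i, ] <- range(S_cal)
  }
  summ <- do.call(rbind, lapply(seq_along(tgt_names), function(j) {
    hp <- hpd_interval(samples[, j])
    data.frame(node = tgt_names[j],
               median = stats::median(samples[, j]),
               hpd_low = hp[1], hpd_high = hp[2],
               n_samples = n_trees,
               extrapolation = mean(s_target[, j] < s_cal_rng[, 1] |
                                      s_target[, j] > s_cal_rng[, 2]) > 0.5)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, samples = samples, fits = fits,
                 focal_tip = focal_tip, t_sampling = t_sampling, seed = seed),
            class = "age_estimates")
}

#' @export
print.age_estimates <- function(x, ...) {
  cat(sprintf("Posterior TDRP dating (%d trees, focal tip '%s', T sampling: %s)\n",
              nrow(x$samples), x$focal_tip, x$t_sampling))
  print(transform(x$summary,
                  median = round(median, 2),
                  hpd_low = round(hpd_low, 2),
                  hpd_high = round(hpd_high, 2)))
  invisible(x)
}

#' Plot a fitted power-law TDRP model
#'
#' Log-log scatter of the calibration points with the fitted line, the usual
#' visual check that a single power law describes the substitution-time
#' relationship.
#'
#' @param x A `power_law_fit`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.power_law_fit <- function(x, ...) {
  plot(x$S, x$T, log = "xy",
       xlab = "Per-lineage substitutions S (subs/site)",
       ylab = "Timescale T (Myr)", pch = 19, ...)
  sg <- 10^seq(log10(min(x$S)) - 0.1, log10(max(x$S)) + 0.3, length.out = 100)
  graphics::lines(sg, extrapolate_age(x, sg), col = "grey40")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("T = 10^%.2f * S^%.2f  (adj R2 = %.3f)",
                                    x$alpha, x$beta, x$adjusted_r2))
  invisible(x)
}
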