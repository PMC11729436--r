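#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement, refits each replicate dataset
#' (initialized at the original estimates), and summarizes every parameter
#' by its median and 5th/95th percentiles. Replicates whose fit fails or
#' does not converge are excluded and counted; if more than `max_fail_frac`
#' of the replicates fail the result is flagged unreliable.
#'
#' @param data A [pk_dataset()].
#' @param spec A [pk_model_spec()].
#' @param fit Optional original [fit_population()] result (refitted here if
#'   omitted).
#' @param n_reps Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @param max_fail_frac Tolerated fraction of failed replicates.
#' @param control Passed to the replicate fits.
#' @return An object of class `pk_bootstrap`: `summary` (data frame with
#'   estimate, median, p5, p95 per parameter), `n_success`, `n_fail`,
#'   `reliable`, and the replicate estimates matrix.
#' @export
pk_bootstrap <- function(data, spec = pk_model_spec(), fit = NULL,
                         n_reps = 1000, seed = NULL, max_fail_frac = 0.2,
                         control = list()) {
  stopifnot(inherits(data, "pk_dataset"), n_reps >= 1)
  df <- as.data.frame(data)
  ids <- unique(df$ID)
  if (length(ids) < 2L)
    stop("bootstrap needs at least two subjects", call. = FALSE)
  if (is.null(fit))
    fit <- fit_population(data, spec, compute_se = FALSE, control = control)
  ## replicate fits start at the original estimates and only feed
  ## percentiles; a slightly looser tolerance is ample
  control <- utils::modifyList(list(rel.tol = 1e-5), control)
  run <- function() {
    reps <- matrix(NA_real_, n_reps, length(fit$estimates),
                   dimnames = list(NULL, names(fit$estimates)))
    for (b in seq_len(n_reps)) {
      take <- sample(ids, length(ids), replace = TRUE)
      pieces <- lapply(seq_along(take), function(k) {
        sub <- df[df$ID == take[k], , drop = FALSE]
        sub$ID <- sprintf("B%04d", k)     # clones become distinct subjects
        sub
      })
      bdat <- pk_dataset(do.call(rbind, pieces))
      ft <- tryCatch(fit_population(bdat, spec, init = fit$estimates,
                                    compute_se = FALSE, control = control),
                     error = function(e) NULL)
      if (!is.null(ft) && ft$converged) reps[b, ] <- ft$estimates
    }
    reps
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ok <- stats::complete.cases(reps)
  qs <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.05, 0.5, 0.95), names = FALSE)
  out <- data.frame(parameter = names(fit$estimates),
                    estimate = unname(fit$estimates),
                    p5 = qs[1, ], median = qs[2, ], p95 = qs[3, ])
  rownames(out) <- NULL
  structure(list(summary = out, n_success = sum(ok),
                 n_fail = sum(!ok),
                 reliable = mean(!ok) <= max_fail_frac,
                 replicates = reps[ok, , drop = FALSE], fit = fit),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d successful / %d failed replicates%s\n",
              x$n_success, x$n_fail,
              if (x$reliable) "" else "  [UNRELIABLE: too many failures]"))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the original design (same
#' subjects, covariates, dosing and sampling times) from the fitted
#' parameters, then compares observed percentiles with the simulation-based
#' confidence bands. Observations and simulations are prediction-corrected:
#' each value is scaled by (bin median population prediction) / (its own
#' population prediction), which removes the variability explained by dose
#' and covariates before percentiles are formed.
#'
#' @param data A [pk_dataset()].
#' @param fit A converged [fit_population()] result.
#' @param n_sim Number of simulated replicates.
#' @param seed Optional integer seed.
#' @param n_bins Number of bins.
#' @param bin_on `"time"` bins on time since first dose; `"time_after_dose"`
#'   on time since the most recent dose (troughs sampled on a fixed
#'   schedule all share the same time after dose, in which case binning on
#'   `"time"` is the informative choice).
#' @param probs Percentiles to check.
#' @param conf Level of the simulation band.
#' @return An object of class `pk_vpc`: a data frame `bins` with, per bin
#'   and percentile, the observed prediction-corrected percentile and its
#'   simulation band, plus the per-observation table.
#' @export
vpc <- function(data, fit, n_sim = 1000, seed = NULL, n_bins = 8,
                bin_on = c("time", "time_after_dose"),
                probs = c(0.05, 0.5, 0.95), conf = 0.95) {
  stopifnot(inherits(data, "pk_dataset"), inherits(fit, "pk_fit"))
  if (!fit$converged) stop("fit has not converged", call. = FALSE)
  bin_on <- match.arg(bin_on)
  struct <- compile_pkdata(data, fit$spec)
  theta <- as.list(fit$estimates)
  tt <- typical_obs(struct, theta)
  pred <- predict_f(struct, tt$tcl, tt$tv)$f      # population prediction
  df <- as.data.frame(data)
  obs_rows <- which(df$EVID == 0L & df$MDV == 0L)
  tad <- time_after_dose(df)[obs_rows]
  x <- if (bin_on == "time") df$TIME[obs_rows] else tad
  ## equal-count bins; falls back to the distinct values when few
  ux <- sort(unique(x))
  if (length(ux) <= n_bins) {
    breaks <- c(ux[1] - 1, ux)
  } else {
    breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                     names = FALSE))
    breaks[1] <- breaks[1] - 1
  }
  bin <- cut(x, breaks = breaks, labels = FALSE, include.lowest = TRUE)
  keep <- !is.na(bin)
  if (any(!keep)) warning("dropped ", sum(!keep), " observations in empty bins")

  pc_obs <- numeric(length(pred))
  med_pred <- tapply(pred, bin, stats::median)
  pc_obs <- struct$y * med_pred[as.character(bin)] / pred

  omega <- make_omega(theta$omega2_cl, theta$omega2_v)
  sim_one <- function() {
    eta1 <- stats::rnorm(struct$n_subj, 0, sqrt(theta$omega2_cl))
    eta2 <- stats::rnorm(struct$n_subj, 0, sqrt(theta$omega2_v))
    cl_o <- tt$tcl * exp(eta1[struct$obs_subj])
    v_o <- tt$tv * exp(eta2[struct$obs_subj])
    fsim <- predict_f(struct, cl_o, v_o)$f
    ysim <- pmax(fsim * (1 + stats::rnorm(length(fsim), 0,
                                          sqrt(theta$sigma2_prop))), 0.01)
    ysim * med_pred[as.character(bin)] / pred
  }
  run <- function() {
    sim_q <- array(NA_real_, c(n_sim, length(unique(bin[keep])), length(probs)))
    bins_u <- sort(unique(bin[keep]))
    for (s in seq_len(n_sim)) {
      pcs <- sim_one()
      for (bi in seq_along(bins_u)) {
        sel <- keep & bin == bins_u[bi]
        sim_q[s, bi, ] <- stats::quantile(pcs[sel], probs = probs,
                                          names = FALSE)
      }
    }
    sim_q
  }
  sim_q <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  bins_u <- sort(unique(bin[keep]))
  alpha <- (1 - conf) / 2
  rows <- list()
  for (bi in seq_along(bins_u)) {
    sel <- keep & bin == bins_u[bi]
    oq <- stats::quantile(pc_obs[sel], probs = probs, names = FALSE)
    for (pi in seq_along(probs)) {
      band <- stats::quantile(sim_q[, bi, pi], probs = c(alpha, 1 - alpha),
                              names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(bin = bins_u[bi],
                   x_median = stats::median(x[sel]),
                   n = sum(sel), percentile = probs[pi],
                   observed = oq[pi],
                   band_lower = band[1], band_upper = band[2],
                   inside = oq[pi] >= band[1] & oq[pi] <= band[2])
    }
  }
  structure(list(bins = do.call(rbind, rows),
                 observations = data.frame(x = x, bin = bin, pc_obs = pc_obs,
                                           pred = pred),
                 bin_on = bin_on, n_sim = n_sim, probs = probs, conf = conf),
            class = "pk_vpc")
}

time_after_dose <- function(df) {
  out <- rep(NA_real_, nrow(df))
  for (id in unique(df$ID)) {
    rows <- which(df$ID == id)
    last_dose <- NA_real_
    for (r in rows) {
      if (df$EVID[r] == 1L) last_dose <- df$TIME[r]
      out[r] <- df$TIME[r] - last_dose
    }
  }
  out
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("Prediction-corrected VPC (%d simulations, %s binning)\n",
              x$n_sim, x$bin_on))
  cat(sprintf("percentiles inside their %g%% band: %d / %d\n",
              100 * x$conf, sum(x$bins$inside), nrow(x$bins)))
  print(x$bins, digits = 4)
  invisible(x)
}

#' Plot a visual predictive check
#'
#' Observed percentile lines over shaded simulation bands, one ribbon per
#' checked percentile.
#'
#' @param x A [vpc()] result.
#' @param file Optional path; when given the plot is saved there.
#' @return The ggplot object, invisibly.
#' @export
plot_vpc <- function(x, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  b <- x$bins
  b$percentile <- factor(100 * b$percentile)
  p <- ggplot2::ggplot(b, ggplot2::aes(x = .data$x_median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lower,
                                      ymax = .data$band_upper,
                                      fill = .data$percentile), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = .data$percentile)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$percentile)) +
    ggplot2::labs(x = if (x$bin_on == "time") "time since first dose (h)"
                  else "time after dose (h)",
                  y = "prediction-corrected concentration (ng/mL)",
                  colour = "percentile", fill = "percentile") +
    ggplot2::theme_bw()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 7, height = 4.5)
  invisible(p)
}

#' Goodness-of-fit table
#'
#' Per-observation population predictions (random effects at zero),
#' individual predictions (at the empirical Bayes modes), residuals and
#' proportional-error weighted residuals.
#'
#' @param data A [pk_dataset()].
#' @param fit A converged [fit_population()] result for `data`.
#' @return Data frame with columns `id`, `time`, `dv`, `pred`, `ipred`,
#'   `res`, `wres`, `ires`, `iwres`.
#' @export
gof_table <- function(data, fit) {
  stopifnot(inherits(data, "pk_dataset"), inherits(fit, "pk_fit"))
  if (!fit$converged) stop("fit has not converged", call. = FALSE)
  struct <- compile_pkdata(data, fit$spec)
  theta <- as.list(fit$estimates)
  tt <- typical_obs(struct, theta)
  pred <- predict_f(struct, tt$tcl, tt$tv)$f
  eta <- fit$eta_modes
  cl_o <- tt$tcl * exp(eta[struct$obs_subj, 1L])
  v_o <- tt$tv * exp(eta[struct$obs_subj, 2L])
  ipred <- predict_f(struct, cl_o, v_o)$f
  sg <- sqrt(theta$sigma2_prop)
  df <- as.data.frame(data)
  obs_rows <- which(df$EVID == 0L & df$MDV == 0L)
  data.frame(id = df$ID[obs_rows], time = df$TIME[obs_rows],
             dv = struct$y,
             pred = pred, ipred = ipred,
             res = struct$y - pred,
             wres = (struct$y - pred) / (sg * pred),
             ires = struct$y - ipred,
             iwres = (struct$y - ipred) / (sg * ipred))
}
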