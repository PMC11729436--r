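#' Drop strongly correlated screening covariates before model building
#'
#' Computes pairwise Pearson correlations among candidate continuous
#' covariates and, for every pair with `|r|` above the threshold, keeps only
#' the higher-priority covariate so that near-collinear candidates (such as
#' body weight and body surface area) do not enter stepwise selection
#' together.
#'
#' @param covariate_table Data frame of continuous covariates (one row per
#'   subject, >= 2 columns).
#' @param threshold Absolute-correlation cutoff above which a pair is
#'   considered redundant.
#' @param priority Character vector ordering covariates from most to least
#'   clinically preferred; covariates not listed rank after listed ones in
#'   column order. Defaults to preferring albumin over total protein and
#'   body surface area over weight and body-mass index.
#' @return A list with `retained` (column names kept), `dropped` (names
#'   removed) and `pairs` (data frame of flagged pairs with their
#'   correlation and which member was dropped).
#' @export
correlation_prune <- function(covariate_table, threshold = 0.7,
                              priority = c("alb", "bsa", "weight", "bmi",
                                           "total_protein")) {
  covariate_table <- as.data.frame(covariate_table)
  if (ncol(covariate_table) < 2L)
    stop("need at least two covariates to prune", call. = FALSE)
  if (threshold <= 0) stop("'threshold' must be positive", call. = FALSE)
  nms <- names(covariate_table)
  rank_of <- function(nm) {
    i <- match(tolower(nm), tolower(priority))
    if (is.na(i)) length(priority) + match(nm, nms) else i
  }
  constant <- vapply(covariate_table, function(x) stats::sd(x) == 0, TRUE)
  if (any(constant))
    warning("constant covariate(s) skipped: ",
            paste(nms[constant], collapse = ", "))
  dropped <- character(0)
  pairs <- data.frame(cov1 = character(0), cov2 = character(0),
                      r = numeric(0), dropped = character(0))
  usable <- nms[!constant]
  for (i in seq_along(usable)) {
    for (j in seq_along(usable)) {
      if (j <= i) next
      a <- usable[i]; b <- usable[j]
      if (a %in% dropped || b %in% dropped) next
      r <- stats::cor(covariate_table[[a]], covariate_table[[b]])
      if (abs(r) > threshold) {
        loser <- if (rank_of(a) <= rank_of(b)) b else a
        dropped <- c(dropped, loser)
        pairs <- rbind(pairs, data.frame(cov1 = a, cov2 = b, r = r,
                                         dropped = loser))
      }
    }
  }
  list(retained = setdiff(nms, dropped), dropped = dropped, pairs = pairs)
}

#' Numeric coding of genotypes for covariate screening
#'
#' Maps minor-allele copy counts (0, 1, 2) to a covariate column under the
#' dominant (any copy), recessive (two copies) or additive (copy count)
#' inheritance model.
#'
#' @param genotypes Integer vector of minor-allele copies per subject.
#' @param model Inheritance model.
#' @return Numeric vector of the same length.
#' @export
genotype_coding <- function(genotypes,
                            model = c("dominant", "recessive", "additive")) {
  model <- match.arg(model)
  if (!all(genotypes %in% 0:2))
    stop("genotypes must be minor-allele copy counts in {0, 1, 2}",
         call. = FALSE)
  switch(model,
         dominant = as.numeric(genotypes >= 1),
         recessive = as.numeric(genotypes == 2),
         additive = as.numeric(genotypes))
}

#' Stepwise covariate modeling by forward inclusion / backward elimination
#'
#' Greedy forward phase: at each step every remaining candidate effect is
#' added to the current model and refitted; the candidate with the largest
#' drop in objective function value is accepted if the drop exceeds
#' `forward_dofv` (default the 1-df chi-square critical value at p = 0.05,
#' 3.84). Backward phase: each effect added in the forward phase is deleted
#' in turn and is removed permanently unless its deletion worsens the OFV by
#' more than `backward_dofv` (default the p = 0.01 value, 6.63). Candidates
#' whose inner fit fails are skipped and recorded, never silently accepted.
#'
#' @param data A [pk_dataset()].
#' @param base_spec The starting [pk_model_spec()] (typically without
#'   covariates).
#' @param candidates List of [cov_effect()] entries to screen.
#' @param forward_dofv,backward_dofv OFV-change thresholds.
#' @param control Passed to [fit_population()].
#' @return A list of class `scm_result`: `final_spec`, `final_fit`, and
#'   `trace` (data frame with phase, effect label, delta OFV, accepted/
#'   retained flag and any fit failure).
#' @export
scm <- function(data, base_spec, candidates,
                forward_dofv = scm_threshold(0.05),
                backward_dofv = scm_threshold(0.01),
                control = list()) {
  stopifnot(inherits(base_spec, "pk_model_spec"))
  trace <- data.frame(phase = character(0), effect = character(0),
                      delta_ofv = numeric(0), decision = character(0))
  note <- function(phase, eff, dofv, decision)
    trace <<- rbind(trace, data.frame(phase = phase, effect = eff,
                                      delta_ofv = dofv, decision = decision))
  fit0 <- fit_population(data, base_spec, compute_se = FALSE,
                         control = control)
  current_spec <- base_spec
  current_fit <- fit0
  remaining <- candidates
  added <- character(0)

  repeat {
    if (!length(remaining)) break
    best <- NULL
    results <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      eff <- remaining[[i]]
      sp <- spec_add(current_spec, eff)
      ## start the candidate coefficient off zero: the current optimum is a
      ## stationary-ish point in the new direction and a zero start can
      ## stall the line search there
      init_i <- c(current_fit$estimates,
                  stats::setNames(0.1, effect_label(eff)))
      ft <- tryCatch(fit_population(data, sp, init = init_i,
                                    compute_se = FALSE, control = control),
                     error = function(e) NULL)
      ## warm starts can under-converge on small cohorts; before declaring a
      ## candidate non-significant, give it a cold multistart fit and keep
      ## whichever optimum is better
      if (is.null(ft) || !ft$converged ||
          current_fit$ofv - ft$ofv <= forward_dofv) {
        ftc <- tryCatch(fit_population(data, sp, compute_se = FALSE,
                                       control = control),
                        error = function(e) NULL)
        if (!is.null(ftc) && ftc$converged &&
            (is.null(ft) || !ft$converged || ftc$ofv < ft$ofv))
          ft <- ftc
      }
      if (is.null(ft) || !ft$converged) {
        note("forward", effect_label(eff), NA, "fit failed, skipped")
        next
      }
      results[[i]] <- ft
      dofv <- current_fit$ofv - ft$ofv
      note("forward", effect_label(eff), dofv,
           if (dofv > forward_dofv) "candidate" else "not significant")
      ## ties resolved by declaration order: strict > keeps the earlier one
      if (dofv > forward_dofv && (is.null(best) || dofv > best$dofv))
        best <- list(i = i, dofv = dofv, fit = ft, spec = sp,
                     label = effect_label(eff))
    }
    if (is.null(best)) break
    note("forward", best$label, best$dofv, "accepted")
    current_spec <- best$spec
    current_fit <- best$fit
    added <- c(added, best$label)
    remaining <- remaining[-best$i]
  }

  repeat {
    removed_any <- FALSE
    for (lb in added) {
      sp <- spec_drop(current_spec, lb)
      ft <- tryCatch(fit_population(data, sp, init = current_fit$estimates,
                                    compute_se = FALSE, control = control),
                     error = function(e) NULL)
      ## same safeguard as the forward phase: an under-converged reduced fit
      ## overstates the cost of removal
      if (!is.null(ft) && ft$converged &&
          ft$ofv - current_fit$ofv > backward_dofv) {
        ftc <- tryCatch(fit_population(data, sp, compute_se = FALSE,
                                       control = control),
                        error = function(e) NULL)
        if (!is.null(ftc) && ftc$converged && ftc$ofv < ft$ofv) ft <- ftc
      }
      if (is.null(ft) || !ft$converged) {
        note("backward", lb, NA, "fit failed, retained")
        next
      }
      dofv <- ft$ofv - current_fit$ofv    # worsening caused by removal
      if (dofv > backward_dofv) {
        note("backward", lb, dofv, "retained")
      } else {
        note("backward", lb, dofv, "removed")
        current_spec <- sp
        current_fit <- ft
        added <- setdiff(added, lb)
        removed_any <- TRUE
        break
      }
    }
    if (!removed_any) break
  }

  structure(list(final_spec = current_spec, final_fit = current_fit,
                 base_ofv = fit0$ofv, trace = trace),
            class = "scm_result")
}

#' @export
print.scm_result <- function(x, ...) {
  cat("Stepwise covariate modeling\n")
  cat(sprintf("base OFV %.3f -> final OFV %.3f\n", x$base_ofv,
              x$final_fit$ofv))
  cat("final effects:",
      paste(vapply(x$final_spec$covariate_effects, effect_label, ""),
            collapse = ", "), "\n")
  print(x$trace)
  invisible(x)
}
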