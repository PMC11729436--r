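#' Longitudinal dosing/observation dataset
#'
#' NONMEM-style long format: one row per dosing event or trough observation.
#' Required columns:
#' \describe{
#'   \item{ID}{subject identifier}
#'   \item{TIME}{hours since the subject's first dose (non-negative,
#'     non-decreasing within subject)}
#'   \item{EVID}{1 for a dose row, 0 for an observation row}
#'   \item{AMT}{dose amount in mg (dose rows; NA on observations)}
#'   \item{DV}{observed concentration in ng/mL (observation rows; NA on doses)}
#'   \item{MDV}{1 when DV is missing/ignored, 0 otherwise}
#'   \item{SS}{1 on a dose row marks it as a steady-state dose of a regimen
#'     repeated every II hours; prediction for later observations uses the
#'     steady-state closed form for that regimen (any earlier history is
#'     replaced), plus any explicit doses given afterwards}
#'   \item{II}{interdose interval in h for SS rows (NA elsewhere)}
#'   \item{ALB, BSA, TAC}{covariates at the row's time}
#' }
#' Any further columns are carried along as screening covariates.
#'
#' @param df A data frame with the columns above.
#' @return The validated data frame with class `pk_dataset`.
#' @seealso [read_dataset()], [generate_dataset()]
#' @export
pk_dataset <- function(df) {
  df <- as.data.frame(df)
  rownames(df) <- NULL
  validate_pk_dataset(df)
  class(df) <- c("pk_dataset", "data.frame")
  df
}

pk_dataset_columns <- c("ID", "TIME", "EVID", "AMT", "DV", "MDV",
                        "SS", "II", "ALB", "BSA", "TAC")

validate_pk_dataset <- function(df) {
  miss <- setdiff(pk_dataset_columns, names(df))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("dataset has no rows", call. = FALSE)
  if (!all(df$EVID %in% c(0L, 1L)))
    stop("EVID must be 0 (observation) or 1 (dose)", call. = FALSE)
  if (any(!is.finite(df$TIME)) || any(df$TIME < 0))
    stop("TIME must be finite and non-negative", call. = FALSE)
  for (id in unique(df$ID)) {
    sub <- df[df$ID == id, , drop = FALSE]
    if (is.unsorted(sub$TIME))
      stop("TIME not non-decreasing within subject ", id, call. = FALSE)
    obs <- sub$EVID == 0L
    if (any(obs)) {
      first_obs <- min(sub$TIME[obs])
      doses <- sub$EVID == 1L & sub$TIME <= first_obs
      if (!any(doses))
        stop("subject ", id, " has an observation before any dose",
             call. = FALSE)
      if (anyNA(sub$ALB[obs]) || anyNA(sub$BSA[obs]) || anyNA(sub$TAC[obs]))
        stop("subject ", id, " has missing ALB/BSA/TAC at an observation",
             call. = FALSE)
      validate_covariates(data.frame(alb = sub$ALB[obs], bsa = sub$BSA[obs],
                                     tac = sub$TAC[obs]))
    }
    d <- sub$EVID == 1L
    if (any(d)) {
      if (anyNA(sub$AMT[d]) || any(sub$AMT[d] <= 0))
        stop("subject ", id, " has a dose row without a positive AMT",
             call. = FALSE)
      ss <- d & !is.na(sub$SS) & sub$SS == 1
      if (any(ss) && (anyNA(sub$II[ss]) || any(sub$II[ss] <= 0)))
        stop("subject ", id, " has an SS dose row without a positive II",
             call. = FALSE)
    }
  }
  obs <- df$EVID == 0L & df$MDV == 0L
  if (any(obs) && (anyNA(df$DV[obs]) || any(df$DV[obs] < 0)))
    stop("observation rows with MDV = 0 must carry a non-negative DV",
         call. = FALSE)
  invisible(df)
}

#' @export
print.pk_dataset <- function(x, ...) {
  n_obs <- sum(x$EVID == 0L & x$MDV == 0L)
  cat(sprintf("pk_dataset: %d subjects, %d observations, %d dose events\n",
              length(unique(x$ID)), n_obs, sum(x$EVID == 1L)))
  print(utils::head(as.data.frame(x), 8))
  invisible(x)
}

#' Read / write a dataset as delimited text
#'
#' Comma-separated with the fixed header documented in [pk_dataset()];
#' missing values are empty fields. `read_dataset()` validates all dataset
#' invariants and reports the offending line on failure; a write/read round
#' trip reproduces the dataset exactly.
#'
#' @param path File path.
#' @param data A `pk_dataset`.
#' @return `read_dataset()` returns a `pk_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- setdiff(names(df), "ID")
  for (nm in intersect(num, pk_dataset_columns)) {
    v <- df[[nm]]
    if (!is.numeric(v) && !all(is.na(v))) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(conv))
      if (length(bad))
        stop("malformed value in column ", nm, " at line ", bad[1] + 1L,
             " of ", path, call. = FALSE)
      df[[nm]] <- conv
    }
  }
  pk_dataset(df)
}

#' @rdname read_dataset
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "pk_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Linearly harmonize assay concentrations
#'
#' Maps concentrations measured on one assay platform onto the scale of
#' another (e.g. immunoassay onto LC-MS/MS) with a linear transform
#' `slope * conc + intercept`, floored at zero. The default is the identity:
#' conversion coefficients are assay- and laboratory-specific and must be
#' supplied by the user.
#'
#' @param conc Concentrations, ng/mL.
#' @param slope Positive multiplicative factor.
#' @param intercept Additive offset, ng/mL.
#' @return Harmonized concentrations, ng/mL.
#' @export
assay_harmonize <- function(conc, slope = 1, intercept = 0) {
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0)
    stop("'slope' must be a single positive number", call. = FALSE)
  pmax(slope * conc + intercept, 0)
}
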