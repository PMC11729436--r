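#' Read or write a model specification as a flat text file
#'
#' One declaration per line. `ka = <value>` fixes the absorption rate
#' constant, `ref_<covariate> = <value>` sets a normalization reference, and
#' each `effect = <parameter> <covariate> <form>` line adds one covariate
#' effect (e.g. `effect = cl alb power`). Blank lines and `#` comments are
#' ignored; a write/read round trip reproduces the specification.
#'
#' @param spec A [pk_model_spec()].
#' @param path File path.
#' @return `read_model_spec()` returns a `pk_model_spec`;
#'   `write_model_spec()` returns `path` invisibly.
#' @examples
#' f <- tempfile()
#' write_model_spec(pk_model_spec(), f)
#' identical(read_model_spec(f), pk_model_spec())
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "pk_model_spec"))
  lines <- c(sprintf("ka = %s", format(spec$ka, digits = 15)),
             sprintf("ref_%s = %s", names(spec$refs),
                     vapply(spec$refs, function(v) format(v, digits = 15), "")),
             vapply(spec$covariate_effects, function(e)
               sprintf("effect = %s %s %s", e$param, e$covariate, e$form), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ka <- 0.647
  refs <- c()
  effects <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed specification line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key == "ka") {
      ka <- as.numeric(val)
      if (is.na(ka)) stop("non-numeric ka: ", val, call. = FALSE)
    } else if (startsWith(key, "ref_")) {
      v <- as.numeric(val)
      if (is.na(v)) stop("non-numeric reference: ", ln, call. = FALSE)
      refs[sub("^ref_", "", key)] <- v
    } else if (key == "effect") {
      parts <- strsplit(val, "[[:space:]]+")[[1]]
      if (length(parts) != 3L)
        stop("effect lines need '<parameter> <covariate> <form>': ", ln,
             call. = FALSE)
      effects <- c(effects, list(cov_effect(parts[1], parts[2], parts[3])))
    } else {
      stop("unknown specification key: ", key, call. = FALSE)
    }
  }
  pk_model_spec(covariate_effects = effects, ka = ka, refs = refs)
}
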