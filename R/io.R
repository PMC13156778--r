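#' Read and write factor tables and surface specs as YAML
#'
#' Plain-text round-trip for the two configuration objects: a factor table
#' (list of `name`/`units`/`center`/`step`/`decimals` entries) and a
#' quadratic surface (`intercept`, `linear`, `interaction`, `quadratic`,
#' `noise_sd`).
#'
#' @param path File path.
#' @param factors Factor tibble (see [factor_spec()]).
#' @param spec A [surface_spec()].
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name yaml-io
NULL

#' @rdname yaml-io
#' @export
write_factors_yaml <- function(factors, path) {
  yaml::write_yaml(
    lapply(seq_len(nrow(factors)), function(i) as.list(factors[i, ])),
    path, precision = 15
  )
  invisible(path)
}

#' @rdname yaml-io
#' @export
read_factors_yaml <- function(path) {
  entries <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(entries, function(e) {
    factor_spec(e$name, e$units, e$center, e$step, e$decimals)
  }))
}

#' @rdname yaml-io
#' @export
write_surface_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "surface_spec"))
  yaml::write_yaml(unclass(spec)[c("intercept", "linear", "interaction",
                                   "quadratic", "noise_sd")], path,
                   precision = 15)
  invisible(path)
}

#' @rdname yaml-io
#' @export
read_surface_yaml <- function(path) {
  s <- yaml::read_yaml(path)
  surface_spec(s$intercept, s$linear, s$interaction, s$quadratic,
               noise_sd = s$noise_sd %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
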