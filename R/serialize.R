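# Flat-file round trip for parameter sets: model name + named constants,
# as YAML or JSON depending on the file extension.

PARAM_CONSTRUCTORS <- c(core_params = "core_params",
                        ttfl_params = "ttfl_params",
                        kim_forger_params = "kim_forger_params",
                        phospholock_params = "phospholock_params",
                        neurospora_params = "neurospora_params",
                        detailed_params = "detailed_params")

#' Write / read a parameter set as flat YAML or JSON
#'
#' Serialises any clock parameter object to a flat schema -- the model
#' name plus its named constants -- and reconstructs it through the
#' matching validating constructor on read (derived fields such as
#' `Kd = k1r/k1f` are recomputed, not trusted from the file).  The format
#' is chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param p a `clock_params` object.
#' @param file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_params` returns the reconstructed parameter object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_params(core_params(k1 = 0.3), f)
#' read_params(f)$k1
#' @export
write_params <- function(p, file) {
  stopifnot(inherits(p, "clock_params"))
  model <- class(p)[1]
  if (!model %in% names(PARAM_CONSTRUCTORS))
    stop_domain("no serialiser for class '", model, "'")
  keep <- names(formals(get(PARAM_CONSTRUCTORS[[model]])))
  flat <- p[intersect(keep, names(p))]
  doc <- c(list(model = model), flat)
  if (grepl("\\.ya?ml$", file)) {
    yaml::write_yaml(doc, file)
  } else if (grepl("\\.json$", file)) {
    jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
  } else stop_domain("unsupported extension: use .yaml, .yml or .json")
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  doc <- if (grepl("\\.ya?ml$", file)) {
    yaml::read_yaml(file)
  } else if (grepl("\\.json$", file)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else stop_domain("unsupported extension: use .yaml, .yml or .json")
  model <- doc$model
  if (is.null(model) || !model %in% names(PARAM_CONSTRUCTORS))
    stop_domain("file does not name a known model")
  ctor <- get(PARAM_CONSTRUCTORS[[model]])
  args <- doc[intersect(names(formals(ctor)), names(doc))]
  do.call(ctor, args)
}
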