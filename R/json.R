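# JSON import/export: model definitions from structured config files
# (symbol lists plus expression strings in the documented infix grammar),
# and certificates/parametrisations exported with expression strings.

#' Read a model definition from a JSON config
#'
#' The config holds \code{states}, \code{inputs}, \code{flucts} (arrays of
#' symbol names), \code{rhs} and \code{outputs} (objects mapping names to
#' expression strings in the infix grammar: arithmetic, powers and
#' elementary functions over declared symbols and fluctuation jets
#' \code{<name>_d<k>}), \code{params} (name to number) and \code{name}.
#'
#' @param path file path (or a literal JSON string).
#' @return a \code{"flat_model"}.
#' @export
model_from_json <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("states", "inputs", "rhs")) {
    if (is.null(cfg[[field]])) stop("config lacks `", field, "`.")
  }
  control_affine_model(
    states = cfg$states,
    inputs = cfg$inputs,
    flucts = cfg$flucts %||% character(),
    rhs = as.list(cfg$rhs),
    outputs = as.list(cfg$outputs %||% list()),
    params = as.list(cfg$params %||% list()),
    name = cfg$name %||% "model"
  )
}

#' Write a model definition to JSON
#'
#' @param model a \code{"flat_model"}.
#' @param path output file; with \code{path = NULL} the JSON string is
#'   returned.
#' @return the path (invisibly) or the JSON string.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "flat_model"))
  obj <- list(
    name = model$name,
    states = model$states,
    inputs = model$inputs,
    flucts = model$flucts,
    rhs = lapply(model$rhs, deparse1),
    outputs = lapply(model$outputs, deparse1),
    params = model$params
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Export a flatness certificate to JSON
#'
#' @param cert a \code{"flat_certificate"}.
#' @param path output file; with \code{path = NULL} the JSON string is
#'   returned.
#' @return the path (invisibly) or the JSON string.
#' @export
certificate_to_json <- function(cert, path = NULL) {
  stopifnot(inherits(cert, "flat_certificate"))
  m <- length(cert$omega)
  obj <- list(
    model = cert$model$name,
    flat = cert$flat,
    reason = cert$reason,
    components = lapply(seq_len(m), function(i) {
      list(
        name = cert$omega_names[i],
        expression = deparse1(cert$omega[[i]]),
        kappa = cert$kappa[i],
        chain = vapply(cert$chains[[i]], deparse1, character(1L)),
        gamma = deparse1(cert$gamma[[i]]),
        drift = deparse1(cert$b[[i]])
      )
    }),
    decoupling_matrix = apply(cert$A, c(1, 2), function(e) deparse1(e[[1L]]))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Export a functional parametrisation to JSON
#'
#' @param par a \code{"flat_parametrisation"}.
#' @param path output file; with \code{path = NULL} the JSON string is
#'   returned.
#' @return the path (invisibly) or the JSON string.
#' @export
parametrisation_to_json <- function(par, path = NULL) {
  stopifnot(inherits(par, "flat_parametrisation"))
  obj <- list(
    model = par$model$name,
    omega = par$omega_names,
    kappa = par$kappa,
    states = lapply(par$states, deparse1),
    inputs = lapply(par$inputs, deparse1)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
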