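# Versioned, self-describing JSON serialization for trained models.
# Numeric payloads (weights, forests, training matrices) are encoded with a
# small tagged codec so matrices and integer vectors survive the round trip.

encode_payload <- function(x) {
  if (is.matrix(x)) {
    list(`_kind` = "matrix", dim = dim(x), dimnames = dimnames(x),
         data = as.numeric(x))
  } else if (is.list(x)) {
    list(`_kind` = "list", names = names(x),
         items = lapply(unname(x), encode_payload))
  } else if (is.integer(x)) {
    list(`_kind` = "int", data = unname(x))
  } else if (is.numeric(x)) {
    list(`_kind` = "num", data = unname(x), names = names(x))
  } else if (is.character(x) || is.logical(x) || is.null(x)) {
    list(`_kind` = "atom", data = unname(x))
  } else {
    abort_parse(sprintf("cannot serialize object of class %s", class(x)[1L]))
  }
}

decode_payload <- function(x) {
  kind <- x[["_kind"]]
  switch(kind,
    matrix = {
      m <- matrix(as.numeric(unlist(x$data)), nrow = x$dim[[1L]])
      if (!is.null(x$dimnames))
        dimnames(m) <- lapply(x$dimnames, function(d) unlist(d))
      m
    },
    list = {
      out <- lapply(x$items, decode_payload)
      if (!is.null(x$names)) names(out) <- unlist(x$names)
      out
    },
    int = as.integer(unlist(x$data)),
    num = {
      v <- as.numeric(unlist(x$data))
      if (!is.null(x$names)) names(v) <- unlist(x$names)
      v
    },
    atom = if (length(x$data) == 0L) NULL else unlist(x$data),
    abort_parse(sprintf("unknown payload kind '%s'", kind)))
}

#' Save a trained model to a versioned JSON file
#'
#' Works for both binary models ([train_binary()]) and sequential models
#' ([sequential_model()]).
#'
#' @param model a `crt_binary_model` or `crt_sequential_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  doc <- if (inherits(model, "crt_sequential_model")) {
    list(format = "crt_sequential_model/1", order = model$order,
         to_model = binary_model_doc(model$to_model),
         mi_model = binary_model_doc(model$mi_model))
  } else if (inherits(model, "crt_binary_model")) {
    binary_model_doc(model)
  } else abort_parse("save_model expects a crt model object")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

binary_model_doc <- function(model) {
  list(format = "crt_binary_model/1",
       algorithm = model$algorithm,
       feature_genes = as.list(model$feature_genes),
       fs_type = model$fs_type,
       target_class = model$contrast$target_class,
       training_seed = model$training_seed,
       fitted_state = encode_payload(model$fitted_state))
}

#' Load a model saved by [save_model()]
#' @param path JSON file path.
#' @return the reconstructed model object.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path)
  fmt <- doc$format
  if (identical(fmt, "crt_sequential_model/1")) {
    sequential_model(binary_model_undoc(doc$to_model),
                     binary_model_undoc(doc$mi_model),
                     order = doc$order)
  } else if (identical(fmt, "crt_binary_model/1")) {
    binary_model_undoc(doc)
  } else abort_parse(sprintf("unrecognized model format '%s'", fmt))
}

binary_model_undoc <- function(doc) {
  state <- decode_payload(doc$fitted_state)
  # forest trees decode as a plain list of matrices, as .rf_predict_cpp expects
  structure(list(format = doc$format, algorithm = doc$algorithm,
                 feature_genes = unlist(doc$feature_genes),
                 fs_type = if (is.null(doc$fs_type)) NA_character_ else doc$fs_type,
                 contrast = binary_contrast(doc$target_class),
                 fitted_state = state,
                 training_seed = as.integer(doc$training_seed)),
            class = "crt_binary_model")
}
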