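# JSON (de)serialization of trained models. Matrices are stored with their
# dimensions so the round trip restores shapes exactly.

mat_out <- function(m) list(dim = dim(m), data = as.numeric(m))
mat_in <- function(l) {
  d <- unlist(l$dim)
  matrix(as.numeric(unlist(l$data)), d[1], d[2])
}

model_to_list <- function(model) {
  switch(model$kind,
    mlp = list(kind = "mlp", w1 = mat_out(model$w1), b1 = model$b1,
               w2 = mat_out(model$w2), b2 = model$b2,
               n_inputs = model$n_inputs, losses = model$losses),
    rbf = list(kind = "rbf", centers = mat_out(model$centers),
               sigma = model$sigma, weights = as.numeric(model$weights),
               n_inputs = model$n_inputs, losses = model$losses),
    anfis = list(kind = "anfis", centers = mat_out(model$centers),
                 sigma = mat_out(model$sigma), theta = as.numeric(model$theta),
                 n_inputs = model$n_inputs, losses = model$losses),
    stop("unknown model kind: ", model$kind, call. = FALSE)
  )
}

list_to_model <- function(l) {
  kind <- l$kind
  num <- function(v) as.numeric(unlist(v))
  out <- switch(kind,
    mlp = list(kind = "mlp", w1 = mat_in(l$w1), b1 = num(l$b1),
               w2 = mat_in(l$w2), b2 = num(l$b2),
               n_inputs = as.integer(l$n_inputs),
               losses = num(l$losses)),
    rbf = list(kind = "rbf", centers = mat_in(l$centers),
               sigma = num(l$sigma), weights = num(l$weights),
               n_inputs = as.integer(l$n_inputs),
               losses = num(l$losses)),
    anfis = list(kind = "anfis", centers = mat_in(l$centers),
                 sigma = mat_in(l$sigma), theta = num(l$theta),
                 n_inputs = as.integer(l$n_inputs),
                 losses = num(l$losses)),
    stop("unknown model kind: ", kind, call. = FALSE)
  )
  structure(out, class = c(paste0(kind, "_model"), "regressor"))
}

#' Serialize a trained model or ensemble to JSON
#'
#' Writes a versioned, plain-JSON description of the learned parameters;
#' [read_model()] restores an object whose predictions match the original
#' to full double precision.
#'
#' @param model A fitted regressor or `bagged_ensemble`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- if (inherits(model, "bagged_ensemble")) {
    list(schema = "chrysfoa-model/1", kind = "bagged_ensemble",
         B = model$B, seed = model$seed, fusion = model$fusion,
         weights = as.list(model$weights), oob_mse = as.list(model$oob_mse),
         members = lapply(model$members, function(bag) {
           lapply(bag, model_to_list)
         }))
  } else {
    c(list(schema = "chrysfoa-model/1"), model_to_list(model))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(l$schema, "chrysfoa-model/1")) {
    stop("unrecognized model schema in ", path, call. = FALSE)
  }
  if (identical(l$kind, "bagged_ensemble")) {
    structure(
      list(members = lapply(l$members, function(bag) {
             lapply(bag, list_to_model)
           }),
           weights = unlist(l$weights), oob_mse = unlist(l$oob_mse),
           fusion = l$fusion,
           B = as.integer(l$B), seed = as.integer(l$seed)),
      class = "bagged_ensemble")
  } else {
    list_to_model(l)
  }
}
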