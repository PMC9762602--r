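#' Serialize an MTLR fit to JSON
#'
#' Stores the time grid, weight matrix, biases, hyperparameters and fitted
#' column names so a fit can be reloaded without the training data.
#'
#' @param fit An \code{mtlr_fit}.
#' @param path JSON output path.
#' @export
mtlr_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "mtlr_fit"))
  obj <- list(tau = fit$tau, theta = fit$theta, bias = fit$bias,
              C = fit$C, smoothness = fit$smoothness,
              columns = fit$columns)
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname mtlr_to_json
#' @export
mtlr_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- obj$theta
  if (is.null(dim(theta)))
    theta <- matrix(theta, nrow = length(obj$tau))
  structure(list(tau = obj$tau, theta = theta, bias = obj$bias,
                 C = obj$C, smoothness = obj$smoothness,
                 columns = obj$columns, value = NA_real_,
                 convergence = NA_integer_, loss_trace = NULL),
            class = "mtlr_fit")
}

#' Serialize a fitted transform to JSON
#'
#' @param transform A \code{design_transform}.
#' @param path JSON output path.
#' @export
transform_to_json <- function(transform, path) {
  stopifnot(inherits(transform, "design_transform"))
  jsonlite::write_json(transform, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname transform_to_json
#' @export
transform_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(params = obj$params, scale = obj$scale),
            class = "design_transform")
}
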