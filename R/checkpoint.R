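# Single-file model checkpoints: the weight tree plus an embedded JSON
# manifest describing the architecture, so a checkpoint is self-describing.

#' Save a model checkpoint
#'
#' @param model an [mvnn_model][mvnn_init()] or [train_branch()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  spec <- model$spec
  manifest <- list(package = "mvnn", format = 1L,
                   kind = class(model)[1L],
                   task = model$task,
                   hidden = model$hidden,
                   spec = unclass(spec))
  saveRDS(list(manifest_json = jsonlite::toJSON(manifest, auto_unbox = TRUE),
               model = model), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_model()].
#' @return the stored model, with its manifest attached as attribute
#'   `"manifest"`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$manifest_json))
    stop("not a model checkpoint: missing manifest")
  manifest <- jsonlite::fromJSON(obj$manifest_json)
  if (!identical(manifest$package, "mvnn"))
    stop("checkpoint was not written by this package")
  model <- obj$model
  attr(model, "manifest") <- manifest
  model
}
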