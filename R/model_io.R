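# Versioned JSON serialization for ISE models. Numbers are written at full
# precision so that identical (data, config, seed) runs serialize
# byte-identically.

MODEL_FORMAT_VERSION <- "1"

#' Write an ISE model to versioned JSON
#'
#' @param model An \code{"ise_model"}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_ise_model <- function(model, path) {
  filters <- lapply(seq_len(nrow(model$filters)), function(i) {
    f <- model$filters[i, ]
    r <- model$filters$ranges[[i]]
    list(size = unname(f$size), tp = unname(f$tp), fp = unname(f$fp),
         tn = unname(f$tn), fn = unname(f$fn), mcc = unname(f$mcc),
         ranges = lapply(seq_len(nrow(r)), function(k)
           list(descriptor = r$descriptor[k], lo = r$lo[k], hi = r$hi[k])))
  })
  obj <- list(format_version = MODEL_FORMAT_VERSION,
              descriptors = as.list(model$descriptors),
              seed = model$seed,
              config = unclass(model$config),
              filters = filters)
  if (!is.null(model$holdout))
    obj$holdout <- list(id = as.list(model$holdout$id),
                        fold = as.list(model$holdout$fold),
                        label = as.list(model$holdout$label),
                        mbi = as.list(model$holdout$mbi))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, always_decimal = FALSE)
  invisible(path)
}

#' Read an ISE model from JSON
#'
#' @param path File written by \code{\link{write_ise_model}}.
#' @return An \code{"ise_model"}.
#' @export
read_ise_model <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION))
    stop("unsupported model format version: ", obj$format_version)
  stats <- do.call(rbind, lapply(obj$filters, function(f)
    data.frame(size = f$size, tp = f$tp, fp = f$fp, tn = f$tn, fn = f$fn,
               mcc = f$mcc)))
  ranges <- lapply(obj$filters, function(f)
    do.call(rbind, lapply(f$ranges, function(r)
      data.frame(descriptor = r$descriptor, lo = r$lo, hi = r$hi,
                 stringsAsFactors = FALSE))))
  ens <- stats
  ens$ranges <- ranges
  class(ens) <- c("ise_ensemble", "data.frame")
  cfg <- obj$config
  cfg$filter_sizes <- as.integer(unlist(cfg$filter_sizes))
  cfg <- do.call(ise_config, cfg[names(cfg) %in% names(formals(ise_config))])
  model <- list(filters = ens,
                descriptors = unlist(obj$descriptors),
                config = cfg, seed = obj$seed)
  if (!is.null(obj$holdout))
    model$holdout <- data.frame(id = unlist(obj$holdout$id),
                                fold = unlist(obj$holdout$fold),
                                label = unlist(obj$holdout$label),
                                mbi = unlist(obj$holdout$mbi),
                                stringsAsFactors = FALSE)
  structure(model, class = "ise_model")
}
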