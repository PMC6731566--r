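# Checkpoints: a versioned JSON container of named parameter blocks with a
# shape manifest, supporting partial loads by block address.

get_block <- function(bundle, address) {
  parts <- strsplit(address, ".", fixed = TRUE)[[1]]
  x <- bundle
  for (p in parts) x <- x[[p]]
  x
}

set_block <- function(bundle, address, value) {
  parts <- strsplit(address, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, p) call("[[", acc, p), parts, quote(bundle))
  eval(call("<-", expr, quote(value)))
  bundle
}

block_to_json <- function(x) {
  list(dim = dim(x) %||% length(x), values = as.numeric(x))
}

block_from_json <- function(b) {
  d <- unlist(b$dim)
  v <- as.numeric(unlist(b$values))
  if (length(d) > 1) array(v, dim = d) else v
}

#' Save a trained model as a JSON checkpoint
#'
#' The file holds a manifest (format version, block addresses and shapes,
#' tag inventory, configurations), every parameter block addressed by
#' `layer.block` path, and the vocabularies — everything needed to rebuild
#' the model for prediction or to copy individual blocks.
#'
#' @param model a `trignet_model`
#' @param path output `.json` file
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(model, path) {
  addrs <- bundle_block_addresses(model$bundle)$address
  blocks <- lapply(stats::setNames(addrs, addrs), function(a) {
    block_to_json(get_block(model$bundle, a))
  })
  fcfg <- model$feature_cfg
  obj <- list(
    manifest = list(
      format = "trignet-checkpoint",
      version = 1L,
      package_version = as.character(utils::packageVersion("trignet")),
      blocks = lapply(blocks, function(b) b$dim),
      tags = model$bundle$meta$tags,
      negative = model$labels$negative,
      feature_cfg = list(dims = as.list(fcfg$dims), channels = fcfg$channels,
                         dim_char_input = fcfg$dim_char_input),
      net_cfg = unclass(model$net_cfg)
    ),
    vocab = lapply(model$vocab, function(m) as.list(m)),
    blocks = blocks
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint
#'
#' @param path checkpoint file from [save_checkpoint()]
#' @param blocks optional character vector of block addresses: load only
#'   these into `into` (a bundle) and return the updated bundle
#' @param into bundle receiving a partial load
#' @return a `trignet_model`, or the updated bundle for a partial load
#' @export
load_checkpoint <- function(path, blocks = NULL, into = NULL) {
  obj <- jsonlite::read_json(path)
  man <- obj$manifest
  if (!identical(man$format, "trignet-checkpoint")) {
    trignet_abort("not a trignet checkpoint", class = "trignet_io_error")
  }
  if (!is.null(blocks)) {
    if (is.null(into)) trignet_abort("partial load needs a target bundle ('into')")
    for (a in blocks) {
      if (is.null(obj$blocks[[a]])) {
        trignet_abort(sprintf("block '%s' not in checkpoint", a),
                      class = "trignet_io_error")
      }
      into <- set_block(into, a, block_from_json(obj$blocks[[a]]))
    }
    return(into)
  }
  vocab <- structure(lapply(obj$vocab, function(m) {
    stats::setNames(as.integer(unlist(m)), names(m))
  }), class = "trig_vocab")
  tags <- as.character(unlist(man$tags))
  negative <- man$negative
  labels <- label_set(setdiff(tags, negative), negative = negative)
  fcl <- man$feature_cfg
  dims <- unlist(fcl$dims)
  fcfg <- feature_config(dim_word = dims[["word"]], dim_char = dims[["char"]],
                         dim_pos = dims[["pos"]], dim_entity = dims[["entity"]],
                         dim_dep = dims[["dep"]],
                         dim_char_input = fcl$dim_char_input,
                         channels = as.character(unlist(fcl$channels)))
  ncl <- man$net_cfg
  ncfg <- network_config(hidden_size = ncl$hidden_size, fc_dim = ncl$fc_dim,
                         peephole = ncl$peephole, init_range = ncl$init_range)
  bundle <- init_bundle(vocab, labels, fcfg, ncfg)
  for (a in names(obj$blocks)) {
    bundle <- set_block(bundle, a, block_from_json(obj$blocks[[a]]))
  }
  new_trignet_model(bundle, vocab, labels, fcfg, ncfg, NULL)
}
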