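# Broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
NULL

#' Tidy a fitted tagger: one row per parameter block
#'
#' @param x a `trignet_model`
#' @param ... unused
#' @return tibble with columns `layer`, `block`, `n_params`
#' @export
tidy.trignet_model <- function(x, ...) {
  addr <- bundle_block_addresses(x$bundle)
  parts <- strsplit(addr$address, ".", fixed = TRUE)
  tibble::tibble(
    layer = vapply(parts, `[[`, "", 1),
    block = vapply(parts, function(p) paste(p[-1], collapse = "."), ""),
    n_params = addr$n_params
  )
}

#' One-row model summary
#'
#' @param x a `trignet_model`
#' @param ... unused
#' @return tibble with the tag count, parameter count, epochs trained, final
#'   loss and best dev F1
#' @export
glance.trignet_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_tags = length(x$bundle$meta$tags),
    n_params = bundle_n_params(x$bundle),
    epochs = if (is.null(h)) NA_integer_ else nrow(h),
    final_loss = if (is.null(h) || !nrow(h)) NA_real_ else h$loss[nrow(h)],
    best_dev_f1 = if (is.null(h) || all(is.na(h$dev_f1))) NA_real_ else
      max(h$dev_f1, na.rm = TRUE),
    best_epoch = x$best_epoch
  )
}

#' @export
tidy.trignet_transfer <- function(x, ...) {
  if (is.null(x$audit)) {
    return(tibble::tibble(layer = character(), block = character(),
                          detail = character(), n_copied = integer()))
  }
  x$audit
}

#' @export
glance.trignet_transfer <- function(x, ...) {
  tibble::tibble(
    variant = x$plan$variant,
    shared_labels = length(x$plan$overlap$shared),
    shared_channels = length(x$plan$shared_channels),
    blocks_transferred = if (is.null(x$audit)) 0L else nrow(x$audit),
    params_transferred = if (is.null(x$audit)) 0L else sum(x$audit$n_copied)
  )
}

#' Training-curve plot for a fitted tagger
#'
#' Loss per epoch, with development-set micro F1 on a second panel when it
#' was tracked.
#'
#' @param object a `trignet_model`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.trignet_model <- function(object, ...) {
  h <- object$history
  if (is.null(h) || !nrow(h)) trignet_abort("model has no training history")
  long <- tidyr::pivot_longer(h, dplyr::any_of(c("loss", "dev_f1")),
                              names_to = "metric", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Ratio-effect curve
#'
#' Mean development-set F1 against the source-data ratio, with one standard
#' deviation around the mean when several seeds were run.
#'
#' @param object a [run_ratio_sweep()] result
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.trignet_ratio_sweep <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$ratio, y = .data$mean_f1))
  if (any(object$n_seeds > 1)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_f1 - .data$sd_f1,
                   ymax = .data$mean_f1 + .data$sd_f1),
      alpha = 0.2)
  }
  p + ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "source-data ratio", y = "dev micro F1 (%)") +
    ggplot2::theme_minimal()
}

#' Per-type metric bar chart
#'
#' @param object a [compute_metrics()] report
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.trig_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("precision", "recall", "f1"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$type, y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}
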