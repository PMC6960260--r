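#' Network architecture configuration
#'
#' Hyperparameters of the hybrid architecture: a single convolution layer
#' (the motif-scanning filter bank), ReLU, non-overlapping max pooling,
#' dropout, a bidirectional GRU over the pooled positions, a 32-unit dense
#' layer and a sigmoid output.
#'
#' @param filter_number number of convolution filters (default 64).
#' @param filter_length filter width in bp (default 23).
#' @param pool_size non-overlapping max-pool width in pooled positions
#'   (default 8); remainder positions are truncated.
#' @param gru_units units per GRU direction (default 32).
#' @param dense_units dense-layer width (fixed at 32 in the reference
#'   architecture).
#' @param dropout_rate dropout fraction applied to the pooled features during
#'   training (default 0.2).
#' @param input_length sequence length in bp the network consumes (default
#'   1000).
#' @return An object of class `network_config`.
#' @export
network_config <- function(filter_number = 64L, filter_length = 23L,
                           pool_size = 8L, gru_units = 32L,
                           dense_units = 32L, dropout_rate = 0.2,
                           input_length = 1000L) {
  cfg <- list(filter_number = as.integer(filter_number),
              filter_length = as.integer(filter_length),
              pool_size = as.integer(pool_size),
              gru_units = as.integer(gru_units),
              dense_units = as.integer(dense_units),
              dropout_rate = as.numeric(dropout_rate),
              input_length = as.integer(input_length))
  with(cfg, {
    stopifnot(filter_number >= 1L, filter_length >= 1L, pool_size >= 1L,
              gru_units >= 1L, dense_units >= 1L, input_length >= 1L)
    if (dropout_rate < 0 || dropout_rate >= 1) {
      stop("dropout_rate must be in [0, 1)")
    }
    if (filter_length > input_length) {
      stop("filter_length (", filter_length, ") exceeds input_length (",
           input_length, ")")
    }
  })
  if (pooled_length(cfg) < 1L) {
    stop("pool_size ", cfg$pool_size, " exceeds the convolution output ",
         "length ", cfg$input_length - cfg$filter_length + 1L)
  }
  structure(cfg, class = "network_config")
}

#' Pooled sequence length implied by a configuration
#'
#' `floor((L - m + 1) / p)`: the number of positions the GRU consumes.
#'
#' @param cfg a `network_config`.
#' @return Integer pooled length.
#' @export
pooled_length <- function(cfg) {
  (cfg$input_length - cfg$filter_length + 1L) %/% cfg$pool_size
}

#' @export
print.network_config <- function(x, ...) {
  cat("network config: ", x$filter_number, " filters x ", x$filter_length,
      " bp, pool ", x$pool_size, ", ", x$gru_units,
      " GRU units/direction, dense ", x$dense_units, ", dropout ",
      x$dropout_rate, ", input ", x$input_length, " bp\n", sep = "")
  invisible(x)
}

glorot <- function(nrow, ncol, fan_in = nrow, fan_out = ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

gru_dir_init <- function(f, h) {
  list(Wz = glorot(f, h), Wr = glorot(f, h), Wh = glorot(f, h),
       Uz = glorot(h, h), Ur = glorot(h, h), Uh = glorot(h, h),
       bz = numeric(h), br = numeric(h), bh = numeric(h))
}

#' Initialize network parameters
#'
#' Glorot-uniform initialization of all weight matrices, zero biases.
#' Parameters fall into three penalized groups: the filter bank `M`, the
#' recurrent weight matrices `WU` (both directions, input and recurrent parts
#' of the update gate, reset gate and candidate memory) and the dense weights
#' `WM`; biases and the final scalar projection are unpenalized.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed; the same seed gives bitwise-identical
#'   parameters.
#' @return An object of class `network_params`.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(as.integer(seed))
  m <- cfg$filter_length; f <- cfg$filter_number
  h <- cfg$gru_units; d <- cfg$dense_units
  lim <- sqrt(6 / (m * 4 + f))
  params <- list(
    M = array(stats::runif(m * 4 * f, -lim, lim), dim = c(m, 4L, f)),
    conv_b = numeric(f),
    gru_fwd = gru_dir_init(f, h),
    gru_bwd = gru_dir_init(f, h),
    dense_W = glorot(2L * h, d),
    dense_b = numeric(d),
    out_w = as.numeric(glorot(d, 1L)),
    out_b = 0)
  structure(params, class = "network_params", config = cfg,
            format_version = 1L)
}

#' @export
print.network_params <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("network parameters (", format(n_params(x), big.mark = ","),
      " values) for:\n", sep = "")
  print(cfg)
  invisible(x)
}

#' Total number of learnable parameter values
#' @param params a `network_params` object.
#' @return Integer count.
#' @export
n_params <- function(params) {
  length(unlist(params, use.names = FALSE))
}

#' Forward pass
#'
#' Pipeline: convolution (valid, stride 1) over the one-hot sequence, ReLU,
#' non-overlapping max pooling, dropout (only when `train_mode`), a
#' bidirectional GRU over the pooled positions whose final hidden states are
#' concatenated, a dense ReLU layer, and a scalar sigmoid output. With
#' `train_mode = FALSE` the output is a pure function of parameters and
#' input.
#'
#' @param params a `network_params` object.
#' @param batch an `encoded_batch` (or a `sequence_set`, encoded on the fly).
#' @param train_mode apply dropout?
#' @return Numeric vector of scores strictly inside (0, 1).
#' @export
forward <- function(params, batch, train_mode = FALSE) {
  cfg <- attr(params, "config")
  x <- batch_cube(batch, cfg)
  mask <- NULL
  if (train_mode && cfg$dropout_rate > 0) {
    mask <- dropout_mask(cfg, dim(x)[[3L]])
  }
  res <- .cpp_nn_run(unclass(params), cfg$pool_size, x, mask, NULL, FALSE)
  as.numeric(res$scores)
}

batch_cube <- function(batch, cfg) {
  if (inherits(batch, "sequence_set")) batch <- encode_batch(batch)
  if (inherits(batch, "encoded_batch")) {
    x <- aperm(batch$x, c(2L, 3L, 1L))
  } else if (is.array(batch) && length(dim(batch)) == 3L) {
    x <- batch   # already (L, 4, N)
  } else {
    stop("batch must be an encoded_batch, sequence_set or (L, 4, N) array")
  }
  if (dim(x)[[1L]] != cfg$input_length) {
    stop("batch length ", dim(x)[[1L]], " does not match configured ",
         "input_length ", cfg$input_length)
  }
  x
}

# Inverted dropout mask over the pooled feature cube, drawn from the R RNG
# so training runs are reproducible from a single seed.
dropout_mask <- function(cfg, n) {
  t_len <- pooled_length(cfg)
  rate <- cfg$dropout_rate
  keep <- stats::rbinom(n * cfg$filter_number * t_len, 1L, 1 - rate)
  array(keep / (1 - rate), dim = c(n, cfg$filter_number, t_len))
}

#' L1 norms of the penalized parameter groups
#'
#' Sums of absolute values over the filter bank `M`, the twelve recurrent
#' weight matrices `WU` (input and recurrent parts of three gates, two
#' directions) and the dense weights `WM`. Biases and the output projection
#' belong to no group and are never penalized.
#'
#' @param params a `network_params` object.
#' @return Named numeric vector `c(M=, WU=, WM=)`.
#' @export
l1_norms <- function(params) {
  wu <- sum(vapply(list(params$gru_fwd, params$gru_bwd), function(g) {
    sum(abs(g$Wz)) + sum(abs(g$Wr)) + sum(abs(g$Wh)) +
      sum(abs(g$Uz)) + sum(abs(g$Ur)) + sum(abs(g$Uh))
  }, numeric(1)))
  c(M = sum(abs(params$M)), WU = wu, WM = sum(abs(params$dense_W)))
}

# Apply f elementwise across parallel nested parameter lists, preserving
# shapes. Used by the optimizer and the freeze logic.
map_params <- function(f, ...) {
  lists <- list(...)
  first <- lists[[1L]]
  if (is.list(first)) {
    out <- lapply(seq_along(first), function(i) {
      do.call(map_params, c(list(f), lapply(lists, `[[`, i)))
    })
    names(out) <- names(first)
    out
  } else {
    do.call(f, lists)
  }
}

zero_like <- function(params) map_params(function(p) p * 0, unclass(params))

#' Save a model checkpoint
#'
#' A checkpoint stores the configuration, every parameter group and a format
#' version; [load_checkpoint()] fails loudly on version or structure
#' mismatch.
#'
#' @param params a `network_params` object.
#' @param path output path.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "network_params"))
  saveRDS(list(format_version = 1L, config = unclass(attr(params, "config")),
               params = unclass(params)), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path a path written by [save_checkpoint()].
#' @return A `network_params` object.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format_version)) {
    stop("'", path, "' is not a checkpoint file")
  }
  if (obj$format_version != 1L) {
    stop("unsupported checkpoint format version ", obj$format_version)
  }
  needed <- c("M", "conv_b", "gru_fwd", "gru_bwd", "dense_W", "dense_b",
              "out_w", "out_b")
  if (!all(needed %in% names(obj$params))) {
    stop("checkpoint is missing parameter group(s): ",
         paste(setdiff(needed, names(obj$params)), collapse = ", "))
  }
  cfg <- do.call(network_config, obj$config)
  structure(obj$params, class = "network_params", config = cfg,
            format_version = 1L)
}
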