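.deepMerge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .deepMerge(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Model and training configuration
#'
#' Returns the full configuration of the localization network with the
#' published defaults; any component can be overridden by passing nested
#' lists, e.g. \code{locNetConfig(train = list(lr = 1e-3, epochs = 15))}.
#'
#' Components: \code{cm} (kernel sizes 3/5, stage filters 64/64/32, adaptive
#' pool targets 512/256/128, dropout 0.5), \code{lsta} (6 heads, window 128,
#' projection rank 4, per-head width 6, attention dropout 0.65),
#' \code{bilstm} (hidden 16, dropout 0.5), \code{textcnn} (kernel sizes
#' 1/3/5, 64 filters each, padding 0, stride 1, pre-output dropout 0.05),
#' \code{loss} (focal: alpha 1, gamma 2; multi-label per-class alphas),
#' \code{train} (AdamW, lr 2e-4, weight decay 1e-3, batch 256, epochs 60,
#' early-stopping patience 10).
#'
#' @param ... Named nested lists of overrides.
#' @return A validated configuration list.
#' @examples
#' cfg <- locNetConfig(lsta = list(heads = 4))
#' cfg$lsta$heads
#' @export
locNetConfig <- function(...) {
  cfg <- list(
    cm = list(kernel_sizes = c(3L, 5L), stage_filters = c(64L, 64L, 32L),
              pool_targets = c(512L, 256L, 128L), dropout = 0.5),
    lsta = list(heads = 6L, window = 128L, rank = 4L, d_k = 6L,
                dropout = 0.65),
    bilstm = list(hidden = 16L, dropout = 0.5),
    textcnn = list(kernel_sizes = c(1L, 3L, 5L), filters = 64L,
                   padding = 0L, stride = 1L, dropout = 0.05),
    loss = list(alpha = 1, gamma = 2,
                alpha_vec = c(0.4, 0.03, 0.92, 0.6, 0.9, 0.95),
                eps = 1e-8),
    train = list(lr = 2e-4, weight_decay = 1e-3, batch_size = 256L,
                 epochs = 60L, patience = 10L, clip = 5, seed = 1L)
  )
  over <- list(...)
  if (length(over)) cfg <- .deepMerge(cfg, over)
  .validateLocNetConfig(cfg)
  cfg
}

.validateLocNetConfig <- function(cfg) {
  cm <- cfg$cm
  .assert(length(cm$stage_filters) == 3L && all(cm$stage_filters >= 1),
          "cm$stage_filters must be three positive integers")
  .assert(length(cm$pool_targets) == 3L && all(diff(cm$pool_targets) < 0),
          "cm$pool_targets must be three strictly decreasing integers")
  .assert(all(cm$kernel_sizes >= 1), "cm$kernel_sizes must be positive")
  .assert(cfg$lsta$heads >= 1 && cfg$lsta$d_k >= 1 && cfg$lsta$window >= 1,
          "lsta heads, d_k and window must be >= 1")
  .assert(cfg$lsta$rank >= 0, "lsta rank must be >= 0")
  for (p in c(cfg$cm$dropout, cfg$lsta$dropout, cfg$bilstm$dropout,
              cfg$textcnn$dropout))
    .assert(p >= 0 && p < 1, "dropout rates must be in [0, 1)")
  .assert(length(cfg$textcnn$kernel_sizes) == 3L,
          "textcnn needs exactly three kernel sizes")
  .assert(cfg$train$lr > 0 || cfg$train$lr == 0,
          "train$lr must be numeric")  # lr 0 allowed (no-op updates)
  .assert(cfg$train$batch_size >= 1, "train$batch_size must be >= 1")
  .assert(cfg$loss$gamma >= 0, "loss$gamma must be >= 0")
  invisible(cfg)
}

#' Read a YAML model configuration
#'
#' Keys mirror \code{\link{locNetConfig}} components (\code{cm:},
#' \code{lsta:}, \code{bilstm:}, \code{textcnn:}, \code{loss:},
#' \code{train:}); missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
readLocNetConfig <- function(path) {
  .assert(file.exists(path), "config file not found: %s", path)
  over <- yaml::read_yaml(path)
  cfg <- .deepMerge(locNetConfig(), over)
  .validateLocNetConfig(cfg)
  cfg
}

#' Write a configuration to YAML
#' @param cfg Configuration list.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeLocNetConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
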