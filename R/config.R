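## Run configuration shared by every pipeline stage.

#' Default run configuration
#'
#' Every hyperparameter of the pipeline with its default. Activation Tanh,
#' learning rate 0.001, 1000 epochs, dropout 0.4 and batch size 64 are the
#' published final configuration of the model; attention heads K = 4 with 64
#' dimensions per head, 2 residual convolution blocks, fusion attention
#' dimension 128 and factor rank k = 64 are package defaults (the
#' convolution channel width is tied to `nHeads * headDim` so the two
#' channels can be averaged). `batchSize` only takes effect when
#' `pairSampling` is switched on; by default the loss is full-matrix, which
#' is what the weighted reconstruction objective describes.
#'
#' @param seed integer seed driving every source of randomness.
#' @param ... named overrides of any configuration field.
#' @return named list.
#' @export
defaultRunConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    ## encoder architecture
    nHeads = 4L, headDim = 64L, gatLayers = 1L, gcnResBlocks = 2L,
    attDim = 128L, rank = 64L,
    activation = "tanh", leakySlope = 0.2,
    ## optimisation (published final configuration)
    learningRate = 1e-3, epochs = 1000L, dropout = 0.4,
    batchSize = 64L, pairSampling = FALSE,
    ## loss
    alpha = 0.5,
    ## channels: "both", "gat" (attention only), "gcn" (convolution only)
    channels = "both",
    ## graph construction
    simThreshold = 0.5, selfLoops = TRUE,
    ## evaluation protocol
    nFolds = 10L, mccThreshold = 0.5,
    recallK = c(5, 10, 15, 20, 30),
    aurocDeltas = c(0.9, 0.8, 0.7),
    auprDeltas = c(0.8, 0.5, 0.3)
  )
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  cfg[names(override)] <- override
  .validateRunConfig(cfg)
  cfg
}

.validateRunConfig <- function(cfg) {
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("configuration field 'alpha' must lie strictly in (0, 1)")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("configuration field 'dropout' must lie in [0, 1)")
  if (cfg$leakySlope <= 0)
    stop("configuration field 'leakySlope' must be positive")
  if (!cfg$channels %in% c("both", "gat", "gcn"))
    stop("configuration field 'channels' must be 'both', 'gat' or 'gcn'")
  for (f in c("nHeads", "headDim", "gcnResBlocks", "attDim", "rank",
              "epochs", "nFolds"))
    if (cfg[[f]] < 0) stop("configuration field '", f, "' must be >= 0")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' Unknown keys are rejected so a manifest cannot silently drift from the
#' configuration schema. Round-trips unchanged.
#'
#' @param path file path.
#' @return for `readRunConfig`, the configuration list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(defaultRunConfig, c(list(seed = raw$seed %||% 1L),
                              raw[setdiff(names(raw), "seed")]))
}

#' @rdname readRunConfig
#' @param cfg configuration list.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
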