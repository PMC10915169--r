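# Checkpoints: a directory with config.json (configs, metadata, training
# log, schema version) and params.txt, a single-file text archive of all
# arrays at %.17g precision, which round-trips IEEE doubles bit-exactly.

CHECKPOINT_SCHEMA <- "ribocast-checkpoint-1"

format_array_line <- function(name, x) {
  dims <- dim(x) %||% length(x)
  paste(name, paste(dims, collapse = ","),
        paste(sprintf("%.17g", as.vector(x)), collapse = " "),
        sep = "\t")
}

parse_array_line <- function(line) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  dims <- as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  vals <- as.numeric(strsplit(parts[3], " ", fixed = TRUE)[[1]])
  x <- if (length(dims) > 1L) array(vals, dims) else vals
  list(name = parts[1], value = x)
}

#' Save a model checkpoint
#'
#' @param model a `ribocast_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [load_model()]
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(schema = CHECKPOINT_SCHEMA,
              config = unclass(model$config),
              train_config = unclass(model$train_config),
              meta = model$meta,
              mask_ref = model$mask_ref,
              best_epoch = model$best_epoch,
              stop_epoch = model$stop_epoch,
              log = model$log)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  lines <- c(
    vapply(names(model$params), function(nm) {
      format_array_line(paste0("param:", nm), model$params[[nm]])
    }, character(1)),
    unlist(lapply(names(model$bn), function(nm) {
      c(format_array_line(paste0("bn_mean:", nm), model$bn[[nm]]$mean),
        format_array_line(paste0("bn_var:", nm), model$bn[[nm]]$var))
    }), use.names = FALSE)
  )
  writeLines(lines, file.path(dir, "params.txt"))
  invisible(dir)
}

#' Load a model checkpoint
#'
#' Validates the schema version string and reconstructs the model; loaded
#' models predict bit-identically to the saved one.
#'
#' @param dir checkpoint directory written by [save_model()].
#' @return a `ribocast_model`.
#' @export
load_model <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  par_path <- file.path(dir, "params.txt")
  abort_if(!file.exists(cfg_path) || !file.exists(par_path),
           "not a checkpoint directory: ", dir)
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  abort_if(!identical(cfg$schema, CHECKPOINT_SCHEMA),
           "unsupported checkpoint schema: ", cfg$schema %||% "<missing>")
  params <- list()
  bn <- list()
  for (line in readLines(par_path)) {
    rec <- parse_array_line(line)
    if (startsWith(rec$name, "param:")) {
      params[[sub("^param:", "", rec$name)]] <- rec$value
    } else if (startsWith(rec$name, "bn_mean:")) {
      nm <- sub("^bn_mean:", "", rec$name)
      bn[[nm]]$mean <- rec$value
    } else if (startsWith(rec$name, "bn_var:")) {
      nm <- sub("^bn_var:", "", rec$name)
      bn[[nm]]$var <- rec$value
    }
  }
  mc <- do.call(model_config, cfg$config[c("W", "embed_dim", "conv_blocks",
                                           "conv_kernel", "filters",
                                           "attention_heads", "key_dim",
                                           "dropout")])
  tc <- do.call(train_config, cfg$train_config)
  structure(list(config = mc, train_config = tc, params = params, bn = bn,
                 mask_ref = isTRUE(cfg$mask_ref),
                 meta = cfg$meta,
                 log = as.data.frame(cfg$log),
                 best_epoch = cfg$best_epoch, stop_epoch = cfg$stop_epoch),
            class = "ribocast_model")
}
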