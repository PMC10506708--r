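#' Deterministic child seeds
#'
#' Derives a reproducible child seed from a master seed and up to three
#' integer stream identifiers (e.g. velocity index, run, trial), by mixing
#' them through a fixed linear-congruential map modulo `2^31 - 1`. All
#' arithmetic stays exact in doubles, and the result is a valid
#' `set.seed()` input. Identifiers should be modest integers (below ~1e6).
#'
#' @param master Master seed (integer).
#' @param id1,id2,id3 Stream identifiers.
#' @return A positive integer seed below `2^31 - 1`.
#' @export
seed_stream <- function(master, id1 = 0, id2 = 0, id3 = 0) {
  m <- 2147483647  # 2^31 - 1
  x <- (as.numeric(master) %% m) * 48271 %% m
  x <- (x + as.numeric(id1) * 2654435 + as.numeric(id2) * 97531 +
          as.numeric(id3) * 7919) %% m
  x <- (x * 16807) %% m
  as.integer(x %% (m - 1) + 1)
}

# md5 of a canonical JSON rendering of an R object (via a temp file)
content_hash <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Hash of a configuration
#'
#' Stable content hash of the parameter set, recorded in run manifests so
#' that results can be matched to the configuration that produced them.
#'
#' @param config An `stdpnet_config`.
#' @return A hex string.
#' @export
config_hash <- function(config) {
  content_hash(unclass(config))
}

#' Persist a weight tensor as portable text
#'
#' Writes `<stem>.tsv` (columns `block`, `post`, `pre`, `w`) plus a JSON
#' manifest `<stem>.json` carrying the dimensions, realized `n_w`,
#' per-block maximum starting weights, velocity/trained flags, any
#' caller-supplied metadata, and the md5 hash of the table file.
#'
#' @param weights An `stdpnet_weights`.
#' @param stem Output path without extension.
#' @param meta Optional named list of extra metadata (e.g. config hash,
#'   seed, training step).
#' @return `stem`, invisibly.
#' @export
save_weights <- function(weights, stem, meta = list()) {
  tab <- do.call(rbind, lapply(seq_along(weights$blocks), function(bi) {
    b <- weights$blocks[[bi]]
    # 17 significant digits keep the double round-trip bitwise exact
    data.frame(block = bi, post = b$post, pre = b$pre,
               w = sprintf("%.17g", b$w))
  }))
  tsv <- paste0(stem, ".tsv")
  utils::write.table(tab, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  manifest <- c(list(
    n_neurons = weights$n_neurons, n_layers = weights$n_layers,
    n_w = weights$n_w, w_max_init = weights$w_max_init,
    velocity = weights$velocity, trained = weights$trained,
    table_md5 = unname(tools::md5sum(tsv)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), meta)
  jsonlite::write_json(manifest, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}

#' Load a persisted weight tensor
#'
#' Reads the pair written by [save_weights()], verifying the stored content
#' hash (a mismatch produces a warning with both hashes, not an error).
#'
#' @param stem Path stem used at save time.
#' @return An `stdpnet_weights` with the manifest attached as attribute
#'   `"manifest"`.
#' @export
load_weights <- function(stem) {
  tsv <- paste0(stem, ".tsv")
  manifest <- jsonlite::read_json(paste0(stem, ".json"),
                                  simplifyVector = TRUE)
  observed <- unname(tools::md5sum(tsv))
  if (!identical(observed, manifest$table_md5))
    warning(sprintf("weight table hash mismatch for %s: stored %s, observed %s",
                    tsv, manifest$table_md5, observed))
  tab <- utils::read.table(tsv, header = TRUE, sep = "\t")
  blocks <- lapply(sort(unique(tab$block)), function(bi) {
    sub <- tab[tab$block == bi, ]
    list(pre = as.integer(sub$pre), post = as.integer(sub$post),
         w = as.numeric(sub$w))
  })
  wt <- list(blocks = blocks,
             w_max_init = as.numeric(manifest$w_max_init),
             n_w = manifest$n_w,
             n_neurons = as.integer(manifest$n_neurons),
             n_layers = as.integer(manifest$n_layers),
             velocity = manifest$velocity,
             trained = isTRUE(manifest$trained))
  class(wt) <- "stdpnet_weights"
  attr(wt, "manifest") <- manifest
  wt
}

#' Persist a spike record or results table as TSV
#'
#' @param x A data.frame or matrix (e.g. a trial's spike table or a sweep
#'   results table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a table written by [save_table()]
#'
#' @param path Input path.
#' @return A data.frame.
#' @export
load_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Assemble a run manifest
#'
#' Collects the configuration snapshot and hash, the master seed, derived
#' seeds, content hashes of produced artifact files, a scale tag and a
#' timestamp into one structure, and optionally writes it as JSON.
#'
#' @param config An `stdpnet_config`.
#' @param seed Master seed used.
#' @param derived_seeds Named list/vector of child seeds.
#' @param artifacts Character vector of file paths to hash.
#' @param scale `"full"` or `"reduced"`.
#' @param path Optional JSON output path.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(config, seed, derived_seeds = list(),
                         artifacts = character(0),
                         scale = c("full", "reduced"), path = NULL) {
  scale <- match.arg(scale)
  hashes <- if (length(artifacts) > 0)
    as.list(tools::md5sum(artifacts)) else list()
  manifest <- list(config = unclass(config),
                   config_hash = config_hash(config),
                   master_seed = seed, derived_seeds = derived_seeds,
                   artifact_hashes = hashes, scale = scale,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
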