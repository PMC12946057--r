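# Artifact IO: JSON checkpoints (named parameter arrays + embedded config),
# score-table CSVs, prune-mask JSON, cost-report JSON/CSV, image-set
# writers/loaders.

encode_array <- function(a) {
  if (is.matrix(a)) list(dim = dim(a), data = as.vector(a)) else
    list(dim = length(a), data = as.vector(a))
}

decode_array <- function(e) {
  d <- unlist(e$dim)
  v <- unlist(e$data)
  if (length(d) == 2L) matrix(v, d[1], d[2]) else v
}

#' Save a model checkpoint
#'
#' Single-file JSON archive of all named parameter arrays with the model
#' config embedded as metadata.
#'
#' @param model A `taha_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "taha_checkpoint_v1",
              config = unclass(model$config),
              params = lapply(model$params, encode_array))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A `taha_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg <- model_config(cfg$image_size, cfg$patch_size, cfg$channels,
                      cfg$depth, cfg$heads_per_layer, cfg$embed_dim,
                      cfg$head_dim, cfg$mlp_dim, cfg$n_classes,
                      cfg$use_cls_token)
  params <- lapply(obj$params, decode_array)
  structure(list(config = cfg, params = params), class = "taha_model")
}

#' Write a head score table as CSV
#'
#' Columns `layer,head,dal,corr,hts`.
#'
#' @param table A `taha_head_scores` data frame.
#' @param path Output CSV path.
#' @export
write_score_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("layer", "head", "dal",
                                            "corr", "hts")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a prune mask as JSON
#'
#' Layout: `{"tau": t, "beta": b, "layers": {"1": [retained...]},
#' "forced": [[layer, head], ...]}`.
#'
#' @param mask A `taha_prune_mask`.
#' @param path Output path; `NULL` returns the JSON string instead.
#' @export
write_prune_mask <- function(mask, path = NULL) {
  d <- mask$decisions
  layers <- lapply(split(d, d$layer), function(s) sort(s$head[s$retain]))
  forced <- d[d$forced, c("layer", "head")]
  obj <- list(tau = mask$tau, beta = mask$beta, pooling = mask$pooling,
              layers = layers,
              forced = unname(apply(forced, 1L, as.list)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Write a cost report
#'
#' JSON with the raw fields plus a CSV in table shape
#' (`component,full,pruned,reduction_pct`).
#'
#' @param report A `taha_cost_report`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @export
write_cost_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report)[c("heads_full", "heads_pruned_avg",
                                           "params_full", "params_pruned",
                                           "macs_full", "macs_pruned",
                                           "reductions", "valid")],
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$table, csv_path, row.names = FALSE)
  }
  invisible(report)
}

#' Write an image set to a directory of PNGs
#'
#' One RGB PNG per image plus a `labels.csv` with columns
#' `filename,label,labeled`.
#'
#' @param set A `taha_image_set`.
#' @param dir Output directory (created if needed).
#' @export
write_image_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(set$labels)
  fn <- sprintf("img_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(set$images[i, , , ], file.path(dir, fn[i]))
  }
  utils::write.csv(data.frame(filename = fn, label = set$labels,
                              labeled = set$labeled_mask),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load an image set from a directory of PNGs
#'
#' Expects the layout written by [write_image_set()] (also suitable for
#' user-supplied data: any PNG directory with a `labels.csv`).
#'
#' @param dir Directory containing PNGs and `labels.csv`.
#' @return A `taha_image_set` (with a minimal spec stub).
#' @export
load_image_dir <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  n <- nrow(lab)
  first <- png::readPNG(file.path(dir, lab$filename[1]))
  S <- dim(first)[1]
  C <- if (length(dim(first)) == 3L) dim(first)[3] else 1L
  images <- array(0, c(n, S, S, C))
  for (i in seq_len(n)) {
    img <- png::readPNG(file.path(dir, lab$filename[i]))
    if (length(dim(img)) == 2L) img <- array(img, c(S, S, 1L))
    images[i, , , ] <- img[, , seq_len(C)]
  }
  structure(list(images = images, labels = as.integer(lab$label),
                 labeled_mask = as.logical(lab$labeled),
                 spec = list(species_id = basename(dir), image_size = S)),
            class = "taha_image_set")
}
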