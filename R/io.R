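# Readers and writers for the pipeline's on-disk formats. Human-readable
# artifacts are TSV; tile-level matrices live in a directory-based bag
# container (one sub-directory per slide with `features.tsv` and
# `coords.tsv` plus a top-level manifest).

#' Write tile bags to a directory container
#'
#' Layout: `<dir>/manifest.tsv` (slide_id, patient_id, cohort, n_tiles,
#' feature_dim) and `<dir>/slides/<slide_id>/{coords.tsv,features.tsv}`.
#'
#' @param bags list of `tile_bag`s.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_bags <- function(bags, dir) {
  dir.create(file.path(dir, "slides"), recursive = TRUE,
             showWarnings = FALSE)
  man <- lapply(bags, function(b) {
    data.frame(slide_id = b$slide_id, patient_id = b$patient_id,
               cohort = b$cohort, n_tiles = nrow(b$features),
               feature_dim = ncol(b$features))
  })
  data.table::fwrite(do.call(rbind, unname(man)),
                     file.path(dir, "manifest.tsv"), sep = "\t")
  for (b in bags) {
    sd <- file.path(dir, "slides", b$slide_id)
    dir.create(sd, showWarnings = FALSE)
    data.table::fwrite(data.frame(x = b$coords[, 1L], y = b$coords[, 2L]),
                       file.path(sd, "coords.tsv"), sep = "\t")
    data.table::fwrite(as.data.frame(b$features),
                       file.path(sd, "features.tsv"), sep = "\t")
  }
  invisible(dir)
}

#' Read tile bags from a directory container
#'
#' @param dir container directory written by [write_bags()].
#' @return named list of `tile_bag`s.
#' @export
read_bags <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop_data("no manifest.tsv under ", dir)
  man <- data.table::fread(man_path, sep = "\t", data.table = FALSE)
  bags <- lapply(seq_len(nrow(man)), function(i) {
    sd <- file.path(dir, "slides", man$slide_id[i])
    coords <- data.table::fread(file.path(sd, "coords.tsv"), sep = "\t",
                                data.table = FALSE)
    feats <- data.table::fread(file.path(sd, "features.tsv"), sep = "\t",
                               data.table = FALSE)
    tile_bag(man$slide_id[i], man$patient_id[i], man$cohort[i],
             as.matrix(coords), as.matrix(feats))
  })
  names(bags) <- man$slide_id
  bags
}

#' Write / read an expression matrix as TSV
#'
#' Rows = samples (first column `sample_id`), columns = genes, raw values.
#'
#' @param expr an [expression_matrix()].
#' @param path TSV path.
#' @return invisibly `path` / an `expression_matrix`.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(sample_id = sample_ids(expr), expr$raw,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  expression_matrix(m)
}

#' Write / read a patient label table
#' @param labels data frame with `patient_id` and `label` columns.
#' @param path TSV path.
#' @return invisibly `path` / a data frame.
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(labels, path, sep = "\t")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE)
}

#' Save / load a trained model checkpoint
#'
#' Single JSON file with the architecture and aggregation manifest embedded
#' alongside the weights (text format; adequate at the model sizes this
#' package trains).
#'
#' @param model a `tile_model`.
#' @param path output path.
#' @return invisibly `path` / a `tile_model`.
#' @export
write_checkpoint <- function(model, path) {
  payload <- list(
    format = "bagexpr_checkpoint_v1",
    spec = unclass(model$spec),
    agg = unclass(model$agg),
    genes = model$genes,
    best_epoch = model$best_epoch,
    acts = model$net$acts,
    sizes = model$net$sizes,
    W = lapply(model$net$W, function(w)
      list(nrow = nrow(w), ncol = ncol(w), data = as.vector(w))),
    b = model$net$b)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) NULL)
  if (is.null(p) || is.null(p$format) ||
      !identical(p$format, "bagexpr_checkpoint_v1")) {
    stop_data("not a bagexpr checkpoint: ", path)
  }
  W <- lapply(p$W, function(w)
    matrix(as.numeric(unlist(w$data)), as.integer(w$nrow),
           as.integer(w$ncol)))
  net <- structure(list(W = W,
                        b = lapply(p$b, function(v) as.numeric(unlist(v))),
                        acts = as.character(unlist(p$acts)),
                        sizes = as.integer(unlist(p$sizes))),
                   class = "mlp")
  spec <- model_spec(as.integer(p$spec$input_dim),
                     as.integer(p$spec$n_genes),
                     hidden = as.integer(unlist(p$spec$hidden)),
                     dropout = as.numeric(p$spec$dropout))
  agg <- structure(list(L = as.integer(unlist(p$agg$L)),
                        mode = as.character(p$agg$mode)),
                   class = "aggregation_spec")
  structure(list(net = net, spec = spec, agg = agg,
                 genes = as.character(unlist(p$genes)),
                 best_epoch = p$best_epoch, history = NULL),
            class = "tile_model")
}

#' Write a run manifest next to outputs
#'
#' Records inputs, a config hash, the seed and package version so a run can
#' be re-executed.
#'
#' @param dir output directory.
#' @param config the configuration list used.
#' @param inputs named character vector of input paths.
#' @param seed the seed in force.
#' @return invisibly the manifest path.
#' @export
write_run_manifest <- function(dir, config, inputs = character(),
                               seed = NULL) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(config, tmp, digits = NA, auto_unbox = TRUE)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(config = config, config_hash = hash,
                   inputs = as.list(inputs), seed = seed,
                   package_version =
                     as.character(utils::packageVersion("bagexpr")),
                   r_version = R.version.string)
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Write a gene significance table as TSV
#' @param tab a [gene_significance()] table.
#' @param path TSV path.
#' @return invisibly `path`.
#' @export
write_significance <- function(tab, path) {
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
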