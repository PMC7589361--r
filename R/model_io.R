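# Versioned plain-text (JSON) model archives for both model families.

ARCHIVE_VERSION <- "1"

#' Save or load a trained model archive
#'
#' Models are stored as a single versioned JSON file (metadata plus all
#' parameters/trees), portable across sessions.
#'
#' @param model An `ensemble_model` or `adalstm_model`.
#' @param path Archive path (.json).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  kind <- if (inherits(model, "ensemble_model")) "ensemble"
  else if (inherits(model, "adalstm_model")) "adalstm"
  else if (inherits(model, "baseline_model")) "baseline"
  else stop("unsupported model class")
  strip <- function(x) {
    if (is.list(x)) structure(lapply(x, strip), names = names(x))
    else x
  }
  payload <- list(archive_version = ARCHIVE_VERSION, kind = kind,
                  model = strip(unclass(model)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

relist_matrix <- function(x) {
  if (is.list(x)) lapply(x, relist_matrix) else x
}

as_num <- function(x) as.numeric(unlist(x))
as_int <- function(x) as.integer(unlist(x))
as_mat <- function(x) {
  if (is.matrix(x)) return(x)
  do.call(rbind, lapply(x, as_num))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  # read unsimplified: the nested heterogeneous lists (tree nodes, layer
  # parameters) do not survive jsonlite's auto-simplification
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(as.character(payload$archive_version), ARCHIVE_VERSION))
    stop("unsupported archive version: ", payload$archive_version)
  m <- payload$model
  if (payload$kind == "ensemble") {
    out <- list(
      trees = lapply(m$trees, function(tr) list(
        tree = list(
          nodes = lapply(tr$tree$nodes, function(nd) {
            if (isTRUE(nd$leaf))
              list(leaf = TRUE, counts = as_num(nd$counts),
                   pred = as_int(nd$pred))
            else
              list(leaf = FALSE, feature = as_int(nd$feature),
                   threshold = as_num(nd$threshold), gain = as_num(nd$gain),
                   left = as_int(nd$left), right = as_int(nd$right))
          }),
          root = as_int(tr$tree$root)),
        features = as_int(tr$features),
        bootstrap = as_int(tr$bootstrap))),
      n_trees = as_int(m$n_trees), p = as_int(m$p),
      label_vocabulary = as.character(unlist(m$label_vocabulary)),
      seed = as_num(m$seed), mtry = as_int(m$mtry))
    return(structure(out, class = "ensemble_model"))
  }
  if (payload$kind == "adalstm") {
    cfg <- m$config
    for (f in c("hidden_units", "max_epochs", "batch_size",
                "drop_every_epochs", "seed"))
      cfg[[f]] <- as_int(cfg[[f]])
    for (f in c("initial_lr", "squared_grad_decay", "drop_factor"))
      cfg[[f]] <- as_num(cfg[[f]])
    cfg$classes <- as.character(unlist(cfg$classes))
    cfg$fc_hidden <- as_int(cfg$fc_hidden)
    cfg$lr_schedule <- unlist(cfg$lr_schedule)
    out <- list(
      config = structure(cfg, class = "adalstm_config"),
      fwd = list(Wx = as_mat(m$fwd$Wx), Wh = as_mat(m$fwd$Wh),
                 b = as_num(m$fwd$b)),
      bwd = list(Wx = as_mat(m$bwd$Wx), Wh = as_mat(m$bwd$Wh),
                 b = as_num(m$bwd$b)),
      fc = lapply(m$fc, function(l) list(W = as_mat(l$W), b = as_num(l$b))),
      trained = isTRUE(unlist(m$trained)))
    return(structure(out, class = "adalstm_model"))
  }
  if (payload$kind == "baseline") {
    kind <- unlist(m$kind)
    fit <- if (kind == "lda_means")
      list(means = as_mat(m$fit$means), Winv = as_mat(m$fit$Winv),
           priors = as_num(m$fit$priors))
    else
      list(W = as_mat(m$fit$W), b = as_num(m$fit$b),
           center = as_num(m$fit$center), scale = as_num(m$fit$scale))
    return(structure(list(kind = kind, fit = fit,
                          label_vocabulary =
                            as.character(unlist(m$label_vocabulary))),
                     class = "baseline_model"))
  }
  stop("unknown archive kind: ", payload$kind)
}

#' Write an importance report as CSV
#'
#' @param report A [feature_importance] result.
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_importance_report <- function(report, path) {
  df <- data.frame(
    feature = names(report$importance) %||%
      paste0("f", seq_along(report$importance)),
    importance = as.numeric(report$importance),
    rank = match(seq_along(report$importance), report$ranking))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
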