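#' ROI importance maps
#'
#' Aggregates per-iteration classifier parameters into one importance value
#' per schema feature, min-max normalized to the unit interval so that 1 marks the
#' most influential ROI. SVC importance averages absolute weight-vector
#' entries; DLC importance backtracks absolute connection weights from the
#' output contrast through both hidden layers to the input nodes.
#'
#' @name importance
NULL

normalize01 <- function(v) {
  rng <- max(v) - min(v)
  if (rng < 1e-15) {
    warning("all importances equal; returning a flat all-ones map",
            call. = FALSE)
    return(rep(1, length(v)))
  }
  (v - min(v)) / rng
}

extract_classifier <- function(m, class) {
  if (inherits(m, "pipeline_model")) m <- m$classifier
  if (!inherits(m, class)) stopf("expected a %s model", class)
  m
}

#' SVC coefficient importance map
#'
#' Per feature, the mean over iterations of the absolute SVC weight,
#' min-max normalized.
#'
#' @param models List of `svc_model` or SVC `pipeline_model` objects.
#' @param schema The [roi_schema] the models were trained on.
#' @return An `importance_map`: data frame `name`, `roi_name`, `measure`,
#'   `hemisphere`, `importance`, with attributes `kind` and `n_models`.
#' @export
svc_importance <- function(models, schema) {
  if (!length(models)) stopf("need at least one model")
  W <- vapply(models, function(m) {
    w <- extract_classifier(m, "svc_model")$w
    if (length(w) != nrow(schema))
      stopf("weight vector length %d does not match schema (%d)",
            length(w), nrow(schema))
    abs(w)
  }, numeric(nrow(schema)))
  new_importance_map(normalize01(rowMeans(W)), schema, "svc",
                     length(models))
}

# Absolute connection-weight backtracking: relevance of input g is the sum
# over all hidden paths of |W1[g,h1]| * |W2[h1,h2]| * |c[h2]|, where c is
# the difference between the two output nodes' incoming weights.
dlc_backtrack <- function(m) {
  contrast <- abs(m$W3[, 2] - m$W3[, 1])
  as.numeric(abs(m$W1) %*% (abs(m$W2) %*% contrast))
}

#' DLC backtracking importance map
#'
#' @param models List of `dlc_model` or DLC `pipeline_model` objects.
#' @param schema The [roi_schema] the models were trained on.
#' @return An `importance_map`; see [svc_importance()].
#' @export
dlc_importance <- function(models, schema) {
  if (!length(models)) stopf("need at least one model")
  Rv <- vapply(models, function(m) {
    m <- extract_classifier(m, "dlc_model")
    if (nrow(m$W1) != nrow(schema))
      stopf("input layer width %d does not match schema (%d)",
            nrow(m$W1), nrow(schema))
    dlc_backtrack(m)
  }, numeric(nrow(schema)))
  new_importance_map(normalize01(rowMeans(Rv)), schema, "dlc",
                     length(models))
}

new_importance_map <- function(values, schema, kind, n_models) {
  structure(data.frame(name = schema$name, roi_name = schema$roi_name,
                       measure = schema$measure,
                       hemisphere = schema$hemisphere,
                       importance = values, stringsAsFactors = FALSE),
            kind = kind, n_models = n_models,
            class = c("importance_map", "data.frame"))
}

#' Export an importance map as a sorted table
#'
#' @param map An `importance_map`.
#' @param path Optional CSV output path.
#' @return The map sorted by descending importance (data frame).
#' @export
export_importance <- function(map, path = NULL) {
  out <- map[order(-map$importance), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) data.table::fwrite(out, path)
  out
}
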