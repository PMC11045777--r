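#' Finite feature space
#'
#' A feature space is the ordered, finite set of feature identifiers an image
#' varifold distributes its mass over: atlas region labels (an ontology), gene
#' names, cell types, or intensity bins. The index of a label is stable for the
#' lifetime of any varifold referencing the space.
#'
#' @param labels character vector of distinct feature identifiers.
#' @return An object of class `feature_space` with elements `labels` and
#'   `size`.
#' @examples
#' fs <- feature_space(c("geneA", "geneB"))
#' fs$size
#' @export
feature_space <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("feature space needs at least one label")
  if (anyDuplicated(labels)) stop("feature space labels must be unique")
  structure(list(labels = labels, size = length(labels)),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat("<feature_space> ", x$size, " labels: ",
      paste(utils::head(x$labels, 8L), collapse = ", "),
      if (x$size > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.feature_space <- function(x) x$size

same_feature_space <- function(a, b) {
  identical(a$labels, b$labels)
}

# index of labels in a feature space, erroring on unknown labels
feature_index <- function(fs, labels) {
  idx <- match(as.character(labels), fs$labels)
  if (anyNA(idx)) {
    bad <- unique(as.character(labels)[is.na(idx)])
    stop("unknown feature label(s): ", paste(bad, collapse = ", "))
  }
  idx
}
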