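#' Canonical tissue vocabulary
#'
#' The eleven tissue samples used to build spatial expression profiles:
#' female and male cerebrum, cerebellum, heart, kidney and liver, plus
#' testis. The order is fixed and is used to break argmax ties in
#' [tissue_specificity()] and to order shared-tissue intersections.
#'
#' @return Character vector of the 11 canonical tissue labels, in canonical
#'   order.
#' @export
#' @examples
#' canonical_tissues()
canonical_tissues <- function() {
  c("cerebrum-F", "cerebrum-M", "cerebellum-F", "cerebellum-M",
    "heart-F", "heart-M", "kidney-F", "kidney-M",
    "liver-F", "liver-M", "testis")
}

# Validate a set of tissue labels against the controlled vocabulary.
# Returns the labels invisibly; errors on unknown or duplicated labels.
check_tissue_labels <- function(labels, vocabulary = canonical_tissues()) {
  if (anyDuplicated(labels)) {
    stop("duplicated tissue labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  unknown <- setdiff(labels, vocabulary)
  if (length(unknown)) {
    stop("unknown tissue label(s): ", paste(unknown, collapse = ", "))
  }
  invisible(labels)
}

# Order a label set by the canonical vocabulary; labels outside the
# vocabulary (not expected in practice) keep their input order at the end.
order_tissues <- function(labels, vocabulary = canonical_tissues()) {
  known <- vocabulary[vocabulary %in% labels]
  c(known, setdiff(labels, vocabulary))
}
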