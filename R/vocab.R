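#' Affect annotation vocabularies
#'
#' The three affect domains used in the mental status examination analysis and
#' their fixed label vocabularies: quality (3 classes), range (4 classes) and
#' subtype (12 classes). Label order is fixed and used throughout for
#' deterministic tie-breaking.
#'
#' @return `affect_domains()` returns the three domain names.
#' @export
affect_domains <- function() c("quality", "range", "subtype")

#' @rdname affect_domains
#' @param domain One of `"quality"`, `"range"`, `"subtype"`.
#' @return `affect_labels()` returns the label vocabulary of a domain, in its
#'   fixed order.
#' @export
affect_labels <- function(domain) {
  domain <- match.arg(domain, affect_domains())
  switch(domain,
    quality = c("dysphoric", "euthymic", "manic"),
    range   = c("full", "restricted", "blunt", "flat"),
    subtype = c("unknown", "stupid", "euphoria", "empathetic",
                "self_contempt", "anxious", "suspicious", "hopeless",
                "frightened", "irritable", "vacancy", "sense_of_guilt")
  )
}

#' @rdname affect_domains
#' @return `expression_classes()` returns the seven facial-expression classes
#'   scored per frame, in their fixed order.
#' @export
expression_classes <- function() {
  c("norm", "anger", "disgust", "fear", "happiness", "sadness", "surprise")
}

#' Facial partition part names
#'
#' The six facial parts used for region-wise motion analysis, and the four
#' composite groups assembled from them.
#'
#' @return Character vectors of part / group names.
#' @export
face_parts <- function() {
  c("left_eye", "right_eye", "left_cheek", "right_cheek", "mouth", "nose")
}

#' @rdname face_parts
#' @export
face_part_groups <- function() {
  c("eyes", "mouth_and_nose", "cheeks", "all_parts")
}

#' @rdname face_parts
#' @return `face_regions()` returns the ten region names (groups then single
#'   parts) in the order used by the region-wise regression grid.
#' @export
face_regions <- function() {
  c("eyes", "mouth_and_nose", "cheeks", "all_parts",
    "left_eye", "right_eye", "nose", "mouth", "left_cheek", "right_cheek")
}
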