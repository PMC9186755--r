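#' @keywords internal
"_PACKAGE"

# Effects that alter protein sequence; everything else is silent/noncoding.
NONSILENT_EFFECTS <- c("missense", "nonsense", "frameshift_indel",
                       "inframe_indel", "splice")
EFFECT_LEVELS <- c(NONSILENT_EFFECTS, "silent", "noncoding")

#' Is an effect annotation non-silent?
#'
#' Non-silent effects are the coding changes that can give rise to
#' neoantigens: missense, nonsense, frameshift/in-frame indels and splice
#' variants. Synonymous (silent) and non-coding changes are excluded.
#'
#' @param effect character vector of effect annotations.
#' @return logical vector.
#' @export
is_nonsilent <- function(effect) {
  effect %in% NONSILENT_EFFECTS
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a positive-class label vector to logical, accepting logicals,
# 0/1 numerics and the clinical label pairs used throughout the package.
as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stopf("numeric labels must be 0/1")
    }
    return(labels == 1)
  }
  labels <- as.character(labels)
  if (is.null(positive)) {
    known <- c("positive", "pos", "ORR", "DCB", "responder", "TRUE", "1")
    positive <- known[known %in% labels]
    if (length(positive) == 0) {
      stopf("cannot infer the positive class from labels %s; supply `positive`",
            paste(unique(labels), collapse = ", "))
    }
  }
  labels %in% positive
}
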