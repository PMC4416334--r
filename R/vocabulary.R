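#' Sign/symptom vocabulary
#'
#' A vocabulary names the interview items a record schema carries: the
#' child's own illness signs per age group and the maternal signs used by
#' the maternal-infection algorithm for neonatal deaths. Rule sets are
#' validated against the active vocabulary at load time, so a predicate can
#' never reference an item the schema does not define.
#'
#' @param path Path to a vocabulary YAML file. The default is the
#'   vocabulary shipped with the package.
#' @return An object of class `va_vocab`: a list with character vectors
#'   `neonate`, `child` and `maternal`, plus a `version` string.
#' @examples
#' vocab <- defaultVocabulary()
#' head(vocab$neonate)
#' @export
readVocabulary <- function(path) {
  raw <- yaml::read_yaml(path)
  for (grp in c("neonate", "child", "maternal")) {
    if (is.null(raw[[grp]]) || !is.character(unlist(raw[[grp]])))
      stop("vocabulary file lacks a '", grp, "' sign list: ", path)
  }
  structure(
    list(
      version = as.character(raw$version %||% "unversioned"),
      neonate = as.character(unlist(raw$neonate)),
      child = as.character(unlist(raw$child)),
      maternal = as.character(unlist(raw$maternal))
    ),
    class = "va_vocab"
  )
}

#' @rdname readVocabulary
#' @export
defaultVocabulary <- function() {
  readVocabulary(system.file("extdata", "vasa_vocabulary.yaml",
                             package = "vacause", mustWork = TRUE))
}

#' @export
print.va_vocab <- function(x, ...) {
  cat("VA sign vocabulary (version ", x$version, ")\n", sep = "")
  cat("  neonatal signs: ", length(x$neonate), "\n", sep = "")
  cat("  child signs:    ", length(x$child), "\n", sep = "")
  cat("  maternal signs: ", length(x$maternal), "\n", sep = "")
  invisible(x)
}

#' Signs applicable to an age group
#' @noRd
vocabSigns <- function(vocab, age_group) {
  switch(age_group,
    neonate = vocab$neonate,
    child = vocab$child,
    stop("unknown age group: ", age_group)
  )
}
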