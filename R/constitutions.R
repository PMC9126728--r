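#' The nine TCM constitution types
#'
#' Fixed label set used throughout the package. `Pinghe` (balanced) is the
#' reference constitution; the remaining eight are the "biased" types. The
#' order is also the deterministic tie-break order for classifier votes:
#' Pinghe first, then the biased types.
#'
#' @return Character vector of the nine constitution names.
#' @export
#' @examples
#' constitution_types()
constitution_types <- function() {
  c("Pinghe", "Qixu", "Yangxu", "Yinxu", "Tanshi",
    "Shire", "Qiyu", "Xueyu", "Tebing")
}

#' @rdname constitution_types
#' @export
biased_types <- function() setdiff(constitution_types(), "Pinghe")

# shared validation helper: stop with the offending field name
.check <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
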