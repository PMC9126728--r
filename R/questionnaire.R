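#' Constitution questionnaire scale scoring
#'
#' Each of the nine constitution subscales is a set of items scored on a
#' 5-grade scale (1–5). The original score of a subscale is the plain sum of
#' its item scores; the conversion score rescales it to 0–100:
#' \deqn{\mathrm{conversion} = \frac{\mathrm{original} - n}{4n} \times 100}
#' where `n` is the number of items, so an all-1 subscale scores 0 and an
#' all-5 subscale scores 100.
#'
#' @param items Integer vector of item scores, each in 1..5, non-empty.
#' @return `original_score()`: integer sum; `conversion_score()`: value in
#'   \[0, 100\].
#' @export
#' @examples
#' original_score(c(2, 4, 3, 5))   # 14
#' conversion_score(c(3, 3, 3, 3)) # 50
original_score <- function(items) {
  .check(length(items) >= 1, "items", "must be non-empty")
  .check(all(items %in% 1:5), "items", "every score must be an integer in 1..5")
  as.integer(sum(items))
}

#' @rdname original_score
#' @export
conversion_score <- function(items) {
  n <- length(items)
  (original_score(items) - n) / (4 * n) * 100
}

#' Score a full questionnaire response
#'
#' @param response A `questionnaire_response`: named list of item-score
#'   vectors, one per constitution subscale (all nine required).
#' @return A `scale_scores` data.frame with columns `subscale`,
#'   `original_score`, `conversion_score`.
#' @export
score_questionnaire <- function(response) {
  .check(setequal(names(response), constitution_types()),
         "response", "must contain all nine subscales")
  out <- data.frame(
    subscale = constitution_types(),
    original_score = vapply(constitution_types(),
                            function(s) original_score(response[[s]]), integer(1)),
    conversion_score = vapply(constitution_types(),
                              function(s) conversion_score(response[[s]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("scale_scores", class(out))
  out
}

#' Determine the constitution type from conversion scores
#'
#' Applies the determination standard literally. With Pinghe conversion
#' score >= 60: Pinghe is "yes" if every biased subscale is < 30 and
#' "probably_yes" if every biased subscale is < 40; each biased subscale is
#' "yes" at >= 40 and "probably_yes" in \[30, 40). With Pinghe < 60 no rule
#' applies and every verdict is "no". The final type is the unique biased
#' "yes" (or Pinghe when its strict rule holds), `"mixed"` when two or more
#' biased subscales reach "yes" (such subjects are excluded from single-type
#' cohorts rather than forced to a label), and `"undetermined"` otherwise.
#'
#' @param scores A `scale_scores` data.frame from [score_questionnaire()], or
#'   a named numeric vector of conversion scores over all nine subscales.
#' @return A list of class `determination`: `verdicts` (named character,
#'   values `"yes"`, `"probably_yes"`, `"no"`) and `final_type`.
#' @export
determine_constitution <- function(scores) {
  conv <- if (inherits(scores, "scale_scores") ||
              (is.data.frame(scores) && "conversion_score" %in% names(scores)))
    setNames(scores$conversion_score, scores$subscale)
  else scores
  .check(all(constitution_types() %in% names(conv)),
         "scores", "conversion scores required for all nine subscales")
  conv <- conv[constitution_types()]
  .check(!anyNA(conv), "scores", "conversion scores must not be missing")

  pinghe <- conv[["Pinghe"]]
  biased <- conv[biased_types()]
  verdicts <- setNames(rep("no", 9), constitution_types())
  if (pinghe >= 60) {
    verdicts["Pinghe"] <- if (all(biased < 30)) "yes"
                          else if (all(biased < 40)) "probably_yes" else "no"
    verdicts[biased_types()] <- ifelse(biased >= 40, "yes",
                                ifelse(biased >= 30, "probably_yes", "no"))
  }
  biased_yes <- names(which(verdicts[biased_types()] == "yes"))
  final_type <- if (length(biased_yes) >= 2) "mixed"
                else if (length(biased_yes) == 1) biased_yes
                else if (verdicts[["Pinghe"]] == "yes") "Pinghe"
                else "undetermined"
  structure(list(verdicts = verdicts, final_type = final_type),
            class = "determination")
}

#' @export
print.determination <- function(x, ...) {
  cat("<determination> final type:", x$final_type, "\n")
  yes <- names(which(x$verdicts != "no"))
  if (length(yes))
    cat("  ", paste(sprintf("%s=%s", yes, x$verdicts[yes]), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write questionnaire responses as delimited text
#'
#' Long tab-delimited format: columns `subject_id`, `subscale`, `item`,
#' `score`, one row per item.
#'
#' @param path File path.
#' @return `read_questionnaires()`: named list of `questionnaire_response`
#'   objects keyed by subject ID.
#' @export
read_questionnaires <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  .check(all(c("subject_id", "subscale", "item", "score") %in% names(d)),
         "file", "needs columns subject_id, subscale, item, score")
  lapply(split(d, d$subject_id), function(ds) {
    resp <- lapply(split(ds, ds$subscale), function(dss)
      as.integer(dss$score[order(dss$item)]))
    structure(resp, class = "questionnaire_response")
  })
}

#' @rdname read_questionnaires
#' @param responses Named list of `questionnaire_response` objects.
#' @export
write_questionnaires <- function(responses, path) {
  if (is.null(names(responses)))
    names(responses) <- sprintf("S%03d", seq_along(responses))
  rows <- do.call(rbind, lapply(names(responses), function(id) {
    r <- responses[[id]]
    do.call(rbind, lapply(names(r), function(sub)
      data.frame(subject_id = id, subscale = sub,
                 item = seq_along(r[[sub]]), score = r[[sub]],
                 stringsAsFactors = FALSE)))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
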