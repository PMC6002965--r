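#' Recode a Clarke frequency category into episodes per month
#'
#' The questionnaire's question 5 (symptomatic episodes with glucose
#' < 3.5 mmol/l in the last month) and question 6 (asymptomatic
#' episodes) record frequency in categories.  For rate analysis each
#' category is assigned an approximate monthly count: none -> 0,
#' 1-3 per month -> 2, one per week -> 1 x 4 = 4, two or three per
#' week -> 2.5 x 4 = 10, four or five per week -> 4.5 x 4 = 18, and
#' almost daily -> 25.
#'
#' Labels are matched case-insensitively and a few common synonyms
#' (e.g. "never", "one episode per week", en-dash ranges) are accepted.
#'
#' @param category character vector of category labels.
#' @return numeric vector of episodes per month.
#' @export
recode_frequency <- function(category) {
  map <- c("none" = 0, "never" = 0,
           "1-3 per month" = 2, "1-3 episodes per month" = 2,
           "1-3 in the last month" = 2,
           "1 per week" = 4, "one episode per week" = 4, "one per week" = 4,
           "2-3 per week" = 10, "two or three episodes per week" = 10,
           "two or three per week" = 10,
           "4-5 per week" = 18, "four or five episodes per week" = 18,
           "four or five per week" = 18,
           "almost daily" = 25)
  key <- tolower(trimws(as.character(category)))
  key <- gsub("–|—", "-", key)   # en/em dash -> hyphen
  bad <- !(key %in% names(map))
  if (any(bad))
    stop("input error: unknown frequency category: ",
         paste(unique(category[bad]), collapse = ", "))
  unname(map[key])
}

#' Score a Clarke hypoglycaemia awareness questionnaire response
#'
#' Each of the seven awareness items scores 0 (aware) or 1 (reduced
#' awareness); the Clarke score is their sum and a score of 4 or more
#' classifies the respondent as having reduced awareness.  Question 5 and
#' question 6 frequency categories are recoded to monthly rates with
#' [recode_frequency()]; question 3 / question 4 yearly counts become
#' any-episode indicators.
#'
#' @param resp one-row data frame (or list) with fields `subject_id`,
#'   `item1`..`item7` (binary), `q3_count`, `q4_count`, `q5_category`,
#'   `q6_category`.  Missing items are an error; nothing is imputed.
#' @return one-row data frame: `subject_id`, `clarke_score`,
#'   `reduced_awareness`, `q5_rate_month`, `q6_rate_month`, `q3_any`,
#'   `q4_any`.
#' @export
score_clarke <- function(resp) {
  items <- unlist(resp[paste0("item", 1:7)], use.names = FALSE)
  if (length(items) != 7 || anyNA(items))
    stop("input error: all seven awareness items must be present")
  if (!all(items %in% c(0, 1)))
    stop("input error: awareness items must be 0 (aware) or 1 (reduced)")
  score <- as.integer(sum(items))
  data.frame(subject_id = resp$subject_id,
             clarke_score = score,
             reduced_awareness = score >= 4,
             q5_rate_month = recode_frequency(resp$q5_category),
             q6_rate_month = recode_frequency(resp$q6_category),
             q3_any = !is.na(resp$q3_count) && resp$q3_count >= 1,
             q4_any = !is.na(resp$q4_count) && resp$q4_count >= 1)
}

#' Score a whole questionnaire table
#'
#' @param responses data frame of responses, one row per subject, in the
#'   format written by [generate_cohort()] / read from `clarke.csv`.
#' @return data frame of [score_clarke()] results, one row per subject.
#' @export
score_clarke_table <- function(responses) {
  do.call(rbind, lapply(seq_len(nrow(responses)),
                        function(i) score_clarke(responses[i, ])))
}
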