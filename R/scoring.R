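#' Score one child's dietary diversity
#'
#' The 7-group score counts the food groups (grains/roots/tubers,
#' legumes/nuts, dairy, flesh foods, eggs, vitamin-A-rich fruits and
#' vegetables, other fruits and vegetables) consumed in the previous 24 h;
#' the 8-group score adds breastmilk as an eighth group.  The two minimum
#' dietary diversity classifications use inclusive thresholds:
#' MDD-7 is `score7 >= 4`, MDD-8 is `score8 >= 5`.  Because
#' `score8 = score7 + breastfed`, meeting MDD-8 implies meeting MDD-7 for
#' every child.  The thresholds are fixed by the indicator definitions and
#' deliberately not configurable.
#'
#' @param record a one-row child record (list or single-row data frame)
#'   with `breastfed` and the seven group indicator fields.
#' @return List with `score7`, `score8`, `mdd7`, `mdd8`.
#' @export
#' @examples
#' score_child(list(breastfed = 0, grains = 1, legumes = 1, dairy = 1,
#'                  flesh = 1, eggs = 0, vita_fruit_veg = 0,
#'                  other_fruit_veg = 0))
score_child <- function(record) {
  s7 <- sum(vapply(group_names(), function(g) as.integer(record[[g]]),
                   integer(1)))
  s8 <- s7 + as.integer(record$breastfed)
  list(score7 = s7, score8 = s8, mdd7 = s7 >= 4L, mdd8 = s8 >= 5L)
}

#' Score a cohort of child records
#'
#' Element-wise [score_child()] over a record collection; output rows align
#' with input rows.
#'
#' @param records record `data.frame` (e.g. from [generate_cohort()] or
#'   [read_child_records()]).
#' @return `data.frame` with columns `score7`, `score8`, `mdd7`, `mdd8`.
#' @export
score_cohort <- function(records) {
  g <- as.matrix(records[, group_names(), drop = FALSE])
  storage.mode(g) <- "integer"
  if (any(is.na(g)) || any(g != 0L & g != 1L))
    stop("food-group indicators must be 0/1", call. = FALSE)
  bf <- as.integer(records$breastfed)
  if (any(is.na(bf)) || any(bf != 0L & bf != 1L))
    stop("'breastfed' must be 0/1", call. = FALSE)
  s7 <- as.integer(rowSums(g))
  s8 <- s7 + bf
  data.frame(score7 = s7, score8 = s8, mdd7 = s7 >= 4L, mdd8 = s8 >= 5L)
}
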