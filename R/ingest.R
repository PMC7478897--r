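#' Describe how survey columns map onto the child-record schema
#'
#' Surveys name their diet variables differently and often record
#' item-level rather than group-level consumption (e.g. separate milk,
#' cheese and yogurt items all belonging to the dairy group).  A column
#' mapping names the design columns, the age and breastmilk columns, and
#' for each of the seven food groups one or more source item columns; a
#' group counts as consumed when ANY of its mapped items is truthy.
#'
#' @param cluster,weight,age names of the cluster, weight and age columns.
#' @param stratum stratum column, or `NULL` for a single implicit stratum.
#' @param age_unit unit of the age column; only `"months"` is supported.
#' @param breastmilk name of the breastmilk-in-previous-24h column.
#' @param groups named list with elements `grains`, `legumes`, `dairy`,
#'   `flesh`, `eggs`, `vita_fruit_veg`, `other_fruit_veg`, each a character
#'   vector of at least one source item column; no column may serve two
#'   groups.
#' @param truthy values (compared as trimmed lowercase strings) read as
#'   "consumed"; everything else, including missing codes, is "not
#'   consumed".
#' @param na_codes values treated as missing for the
#'   all-diet-items-missing exclusion rule.
#' @param household_id optional household column enabling
#'   [dedupe_youngest()].
#' @param country_label optional column carrying a survey/country label.
#' @return An object of class `column_mapping`.
#' @seealso [default_mapping()], [read_mapping()], [read_child_records()]
#' @export
column_mapping <- function(cluster, stratum = NULL, weight, age,
                           age_unit = "months", breastmilk,
                           groups, truthy = c("1", "yes"),
                           na_codes = c("", "NA", ".", "9", "99"),
                           household_id = NULL, country_label = NULL) {
  if (!identical(age_unit, "months"))
    stop("age_unit must be \"months\"", call. = FALSE)
  need <- group_names()
  if (!is.list(groups) || !setequal(names(groups), need))
    stop("'groups' must be a named list with exactly the elements: ",
         paste(need, collapse = ", "), call. = FALSE)
  groups <- lapply(groups[need], as.character)
  if (any(lengths(groups) == 0))
    stop("every food group must map to at least one source column",
         call. = FALSE)
  all_items <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_items))
    stop("source column(s) assigned to more than one group: ",
         paste(unique(all_items[duplicated(all_items)]), collapse = ", "),
         call. = FALSE)
  structure(
    list(cluster = cluster, stratum = stratum, weight = weight,
         age = age, age_unit = age_unit, breastmilk = breastmilk,
         groups = groups, truthy = tolower(trimws(as.character(truthy))),
         na_codes = tolower(trimws(as.character(na_codes))),
         household_id = household_id, country_label = country_label),
    class = "column_mapping")
}

#' Mapping for the canonical synthetic-cohort layout
#'
#' Maps the column names written by [write_child_records()] one-to-one, so
#' that generated cohorts round-trip through [read_child_records()].
#'
#' @return A `column_mapping`.
#' @export
default_mapping <- function() {
  g <- group_names()
  column_mapping(cluster = "cluster_id", stratum = "stratum_id",
                 weight = "weight", age = "age_months",
                 breastmilk = "breastfed",
                 groups = stats::setNames(as.list(g), g),
                 country_label = "country_label")
}

#' Read a column mapping from a configuration file
#'
#' Flat YAML: scalar keys for the design/age/breastmilk columns, a `groups`
#' block with one sequence per food group, optional `truthy`, `na_codes`,
#' `household_id` and `country_label`.  An annotated example mapping for
#' DHS-style child-recode variable names ships in
#' `system.file("extdata", "mapping_dhs_style.yaml", package = "mddcompare")`.
#'
#' @param path path to the mapping file.
#' @return A `column_mapping`.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(column_mapping))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown mapping field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(column_mapping, vals)
}

truthy01 <- function(x, truthy) {
  as.integer(tolower(trimws(as.character(x))) %in% truthy)
}

is_missing_code <- function(x, na_codes) {
  x <- tolower(trimws(as.character(x)))
  is.na(x) | x %in% na_codes
}

#' Read child-level microdata through a column mapping
#'
#' Reads a delimited text file (comma default; tab detected from the
#' header), applies the mapping, aggregates item columns to the seven food
#' groups by OR, and returns validated child records together with an
#' ingest report.  Exclusion rules: age outside 6-23 completed months;
#' non-positive or unparseable weight; all diet items (the seven groups'
#' items and breastmilk) missing.  Missing individual diet items are read
#' as "not consumed"; only the all-missing case drops a record.  Every
#' exclusion is counted by reason in the report.
#'
#' @param path input file path.
#' @param mapping a [column_mapping()]; default [default_mapping()].
#' @return The record `data.frame` with an `"ingest_report"` attribute
#'   (also of class `ingest_report`, printable).
#' @export
read_child_records <- function(path, mapping = default_mapping()) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  stopifnot(inherits(mapping, "column_mapping"))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  m <- mapping
  needed <- c(m$cluster, m$stratum, m$weight, m$age, m$breastmilk,
              unlist(m$groups, use.names = FALSE), m$household_id,
              m$country_label)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  n_read <- nrow(raw)
  drop_reason <- character(n_read)          # "" = keep

  age <- suppressWarnings(as.numeric(raw[[m$age]]))
  weight <- suppressWarnings(as.numeric(raw[[m$weight]]))
  bad_parse <- (is.na(age) & !is_missing_code(raw[[m$age]], m$na_codes)) |
    (is.na(weight) & !is_missing_code(raw[[m$weight]], m$na_codes))
  drop_reason[bad_parse] <- "parse"

  free <- drop_reason == ""
  bad_age <- free & (is.na(age) | age < 6 | age > 23 | age != round(age))
  drop_reason[bad_age] <- "age"
  free <- drop_reason == ""
  bad_w <- free & (is.na(weight) | weight <= 0)
  drop_reason[bad_w] <- "weight"

  diet_cols <- c(unlist(m$groups, use.names = FALSE), m$breastmilk)
  diet_missing <- Reduce(`&`, lapply(diet_cols, function(cl)
    is_missing_code(raw[[cl]], m$na_codes)))
  free <- drop_reason == ""
  drop_reason[free & diet_missing] <- "diet_missing"

  keep <- drop_reason == ""
  grp <- matrix(0L, nrow = sum(keep), ncol = 7,
                dimnames = list(NULL, group_names()))
  for (g in group_names()) {
    items <- m$groups[[g]]
    any_truthy <- Reduce(`|`, lapply(items, function(cl)
      truthy01(raw[[cl]][keep], m$truthy) == 1L))
    grp[, g] <- as.integer(any_truthy)
  }

  out <- data.frame(
    child_id = if ("child_id" %in% names(raw)) raw$child_id[keep]
               else sprintf("r%06d", which(keep)),
    cluster_id = raw[[m$cluster]][keep],
    stratum_id = if (is.null(m$stratum)) "all" else raw[[m$stratum]][keep],
    weight = weight[keep],
    age_months = as.integer(age[keep]),
    breastfed = truthy01(raw[[m$breastmilk]][keep], m$truthy),
    grp,
    country_label = if (is.null(m$country_label)) NA_character_
                    else raw[[m$country_label]][keep],
    stringsAsFactors = FALSE)
  if (!is.null(m$household_id)) out$household_id <- raw[[m$household_id]][keep]

  report <- structure(
    list(path = path, n_read = n_read, n_kept = sum(keep),
         excluded = c(age = sum(drop_reason == "age"),
                      weight = sum(drop_reason == "weight"),
                      diet_missing = sum(drop_reason == "diet_missing"),
                      parse = sum(drop_reason == "parse"))),
    class = "ingest_report")
  attr(out, "ingest_report") <- report
  out
}

#' @export
print.ingest_report <- function(x, ...) {
  cat("Ingest of", x$path, "\n")
  cat(sprintf("  rows read: %d, records kept: %d\n", x$n_read, x$n_kept))
  ex <- x$excluded
  cat(sprintf("  excluded: %d age-ineligible, %d non-positive weight, %d all diet items missing, %d unparseable\n",
              ex[["age"]], ex[["weight"]], ex[["diet_missing"]], ex[["parse"]]))
  invisible(x)
}

#' Keep the youngest eligible child per household
#'
#' Survey diet modules typically interview the caretaker about the youngest
#' child aged 6-23 months in each household.  When the sampling frame has
#' not already applied that selection, this reduces the records to one per
#' household: the minimum `age_months`, ties broken by the smallest
#' `child_id` (lexicographic).
#'
#' @param records record `data.frame` containing a `household_id` column
#'   (mapped at ingest).
#' @return The de-duplicated records, in original row order.
#' @export
dedupe_youngest <- function(records) {
  if (is.null(records$household_id))
    stop("records carry no 'household_id' column; map one at ingest",
         call. = FALSE)
  ord <- order(records$household_id, records$age_months, records$child_id)
  first <- !duplicated(records$household_id[ord])
  keep_rows <- sort(ord[first])
  records[keep_rows, , drop = FALSE]
}
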