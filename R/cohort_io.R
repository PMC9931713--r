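#' Write / read a cohort as long-format CSV
#'
#' The on-disk format is one row per (subject, variable, month) with header
#' `subject_id,group,variable_id,month,value`, UTF-8, `.` decimal separator.
#' Values are printed with 17 significant digits so the round trip is
#' bit-lossless.
#'
#' @param dataset a `cohort_dataset`.
#' @param path file path.
#' @return `read_cohort` returns a validated `cohort_dataset`.
#' @export
write_cohort <- function(dataset, path) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  long <- cohort_to_long(dataset)
  long$value <- sprintf("%.17g", long$value)
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

cohort_to_long <- function(dataset) {
  dm <- dim(dataset$values)
  long <- data.frame(
    subject_id = rep(dataset$subject_id, times = dm[2] * dm[3]),
    group = rep(as.character(dataset$group), times = dm[2] * dm[3]),
    variable_id = rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
    month = rep(dataset$visit_months, each = dm[1] * dm[2]),
    value = as.vector(dataset$values),
    stringsAsFactors = FALSE
  )
  long[order(match(long$subject_id, dataset$subject_id),
             long$variable_id, long$month), , drop = FALSE]
}

#' @rdname write_cohort
#' @param catalog variable catalogue the file must cover.
#' @export
read_cohort <- function(path, catalog = variable_catalog()) {
  long <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(subject_id = "character", group = "character",
                                  variable_id = "integer", month = "numeric",
                                  value = "numeric"))
  required <- c("subject_id", "group", "variable_id", "month", "value")
  if (!all(required %in% names(long)))
    stop("cohort CSV must have columns ", paste(required, collapse = ", "))

  bad_group <- !(long$group %in% GROUP_LEVELS)
  if (any(bad_group))
    stop("unknown group label '", long$group[which(bad_group)[1]],
         "' at row ", which(bad_group)[1])
  if (any(!is.finite(long$value)))
    stop("non-finite value at row ", which(!is.finite(long$value))[1])

  key <- paste(long$subject_id, long$variable_id, long$month, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (subject, variable, month) at row ",
         which(duplicated(key))[1])

  months <- sort(unique(long$month))
  vids <- sort(unique(long$variable_id))
  if (!identical(vids, catalog$variable_id))
    stop("variable ids in file do not match the catalogue")
  subjects <- unique(long$subject_id)

  expected <- length(vids) * length(months)
  counts <- table(long$subject_id)
  short <- names(counts)[counts != expected]
  if (length(short))
    stop("subject ", short[1], " does not have a value for every variable ",
         "at every visit month")

  values <- array(NA_real_,
                  dim = c(length(subjects), length(vids), length(months)),
                  dimnames = list(subjects, vids, months))
  values[cbind(match(long$subject_id, subjects),
               match(long$variable_id, vids),
               match(long$month, months))] <- long$value

  group <- long$group[match(subjects, long$subject_id)]
  structure(
    list(values = values, subject_id = subjects,
         group = factor(group, levels = GROUP_LEVELS),
         visit_months = months, catalog = catalog),
    class = "cohort_dataset"
  )
}
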