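#' Validate a subject metadata table
#'
#' The metadata table has one row per subject with columns `subject_id`,
#' `group` (one of control, VS, MCS), `crs_r` (integer Coma Recovery
#' Scale-Revised total; required for patients, may be empty for controls) and
#' `imagery` (logical command-following flag from functional imaging; may be
#' empty for controls).
#'
#' @param table data.frame, or path to a CSV file with those columns.
#' @return data.frame of typed subject records (`subject_id` character,
#'   `group` factor with levels control/VS/MCS, `crs_r` integer, `imagery`
#'   logical).
#' @export
validate_subject_table <- function(table) {
  if (is.character(table) && length(table) == 1) {
    if (!file.exists(table)) stop("metadata file not found: ", table)
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  need <- c("subject_id", "group", "crs_r", "imagery")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("metadata table missing column(s): ",
                         paste(miss, collapse = ", "))
  grp <- as.character(table$group)
  bad <- setdiff(unique(grp), c("control", "VS", "MCS"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  crs <- table$crs_r
  crs[crs %in% c("", "NA")] <- NA
  crs_num <- suppressWarnings(as.numeric(crs))
  if (any(!is.na(crs) & is.na(crs_num)))
    stop("non-numeric crs_r value(s)")
  if (any(!is.na(crs_num) & crs_num != round(crs_num)))
    stop("non-integer crs_r value(s)")
  is_patient <- grp %in% c("VS", "MCS")
  if (any(is_patient & is.na(crs_num)))
    stop("crs_r is required for every patient (VS/MCS) record")
  img <- table$imagery
  if (!is.logical(img)) {
    img <- tolower(as.character(img))
    img[img %in% c("", "na")] <- NA
    img_l <- rep(NA, length(img))
    img_l[img %in% c("yes", "true", "1")] <- TRUE
    img_l[img %in% c("no", "false", "0")] <- FALSE
    if (any(!is.na(img) & is.na(img_l)))
      stop("imagery must be yes/no (or TRUE/FALSE)")
    img <- img_l
  }
  out <- data.frame(
    subject_id = as.character(table$subject_id),
    group = factor(grp, levels = c("control", "VS", "MCS")),
    crs_r = as.integer(crs_num),
    imagery = img,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$subject_id)) stop("duplicate subject_id values")
  out
}

#' Is a subject record a patient?
#' @param group group labels (character or factor).
#' @return logical vector.
#' @export
is_patient_group <- function(group) as.character(group) %in% c("VS", "MCS")
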