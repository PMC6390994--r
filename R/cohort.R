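#' Construct a JointCohort from per-visit matrices
#'
#' @param catalog a \linkS4class{JointCatalog}.
#' @param X named list of joints x patients binary matrices; names are
#'   months from baseline as character; must include \code{"0"}.
#' @param labels optional named character vector of per-patient labels.
#' @return a validated \linkS4class{JointCohort}.
#' @export
JointCohort <- function(catalog, X, labels = character(0)) {
  months <- as.integer(names(X))
  o <- order(months)
  X <- X[o]
  months <- months[o]
  names(X) <- as.character(months)
  patients <- colnames(X[[which(months == 0L)[1]]])
  new("JointCohort", catalog = catalog, patients = patients,
      visits = months, X = X, labels = labels)
}

setMethod("show", "JointCohort", function(object) {
  cat("JointCohort:", length(object@patients), "patients,",
      nJoints(object@catalog), "joints,",
      length(object@visits), "visits (months",
      paste(object@visits, collapse = ", "), ")\n")
  if (length(object@labels))
    cat("  labels:", paste(names(table(object@labels)), collapse = ", "), "\n")
})

#' Accessors for JointCohort
#'
#' @param cohort a \linkS4class{JointCohort}.
#' @param month visit month.
#' @return \code{visitMatrix}: the joints x patients binary matrix for a
#'   visit (patients missing at that visit are absent as columns);
#'   \code{baselineMatrix}: the month-0 matrix; \code{cohortPatients},
#'   \code{visitMonths}, \code{cohortLabels}: the corresponding slots;
#'   \code{lastVisit}: named integer vector of each patient's last observed
#'   visit month.
#' @export
visitMatrix <- function(cohort, month) {
  nm <- as.character(month)
  if (!nm %in% names(cohort@X)) stop("no visit at month ", month)
  cohort@X[[nm]]
}

#' @rdname visitMatrix
#' @export
baselineMatrix <- function(cohort) cohort@X[["0"]]

#' @rdname visitMatrix
#' @export
cohortPatients <- function(cohort) cohort@patients

#' @rdname visitMatrix
#' @export
visitMonths <- function(cohort) cohort@visits

#' @rdname visitMatrix
#' @export
cohortLabels <- function(cohort) cohort@labels

#' @rdname visitMatrix
#' @export
lastVisit <- function(cohort) {
  out <- stats::setNames(rep(0L, length(cohort@patients)), cohort@patients)
  for (i in seq_along(cohort@visits)) {
    p <- colnames(cohort@X[[i]])
    out[p] <- cohort@visits[i]
  }
  out
}

## The default visit schedule: six-month intervals for the first 18 months
## and yearly thereafter out to five years.
#' @rdname visitMatrix
#' @export
defaultSchedule <- function() c(0L, 6L, 12L, 18L, 24L, 36L, 48L, 60L)

## sentinel joint id marking an assessed visit with zero active joints in
## the long dialect (which otherwise encodes only active joints)
.LONG_ZERO <- "."

#' Read a cohort from disk
#'
#' Two dialects are supported. \code{wide_csv}: comma-separated with header
#' \code{patient_id,visit_month,<joint_id_1>,...}; one row per patient-visit,
#' 0/1 cells. \code{long_tsv}: tab-separated with header
#' \code{patient_id  visit_month  joint_id}; presence of a row means the
#' joint is active; the reserved joint id \code{"."} records an assessed
#' visit at which no joint was active (so such visits survive a round trip).
#' Duplicate (patient, visit, joint) rows collapse to a single activation.
#'
#' @param path input file.
#' @param catalog a \linkS4class{JointCatalog}; unknown joint ids are
#'   rejected.
#' @param dialect \code{"wide_csv"} or \code{"long_tsv"}.
#' @param labels optional named character vector of per-patient labels.
#' @return a validated \linkS4class{JointCohort}.
#' @export
readCohort <- function(path, catalog, dialect = c("wide_csv", "long_tsv"),
                       labels = character(0)) {
  dialect <- match.arg(dialect)
  ids <- jointIds(catalog)
  if (dialect == "wide_csv") {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("patient_id", "visit_month") %in% names(tab)))
      stop("wide_csv requires patient_id and visit_month columns")
    joints <- setdiff(names(tab), c("patient_id", "visit_month"))
    unknown <- setdiff(joints, ids)
    if (length(unknown))
      stop("unknown joint ids: ", paste(unknown, collapse = ", "))
    cells <- as.matrix(tab[, joints, drop = FALSE])
    bad <- which(!(cells %in% c(0, 1)))
    if (length(bad)) {
      r <- ((bad[1] - 1) %% nrow(cells)) + 1
      c <- ((bad[1] - 1) %/% nrow(cells)) + 1
      stop("non-binary cell at patient ", tab$patient_id[r],
           ", visit ", tab$visit_month[r], ", joint ", joints[c],
           ": ", cells[bad[1]])
    }
    key <- paste(tab$patient_id, tab$visit_month)
    if (anyDuplicated(key))
      stop("duplicated patient-visit rows: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    long <- data.frame(
      patient_id  = rep(as.character(tab$patient_id), length(joints)),
      visit_month = rep(as.integer(tab$visit_month), length(joints)),
      joint_id    = rep(joints, each = nrow(tab)),
      active      = as.vector(cells),
      stringsAsFactors = FALSE
    )
    seen <- unique(long[c("patient_id", "visit_month")])
    long <- long[long$active == 1, c("patient_id", "visit_month", "joint_id")]
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!all(c("patient_id", "visit_month", "joint_id") %in% names(tab)))
      stop("long_tsv requires patient_id, visit_month, joint_id columns")
    tab$visit_month <- as.integer(tab$visit_month)
    unknown <- setdiff(tab$joint_id, c(ids, .LONG_ZERO))
    if (length(unknown))
      stop("unknown joint ids: ", paste(unknown, collapse = ", "))
    seen <- unique(tab[c("patient_id", "visit_month")])
    long <- tab[tab$joint_id != .LONG_ZERO, ]
    long <- unique(long[c("patient_id", "visit_month", "joint_id")])
  }
  .cohort_from_long(long, seen, catalog, labels)
}

.cohort_from_long <- function(long, seen, catalog, labels) {
  ids <- jointIds(catalog)
  months <- sort(unique(seen$visit_month))
  X <- lapply(months, function(m) {
    pats <- sort(unique(seen$patient_id[seen$visit_month == m]))
    M <- matrix(0, nrow = length(ids), ncol = length(pats),
                dimnames = list(ids, pats))
    rows <- long[long$visit_month == m, ]
    if (nrow(rows)) M[cbind(rows$joint_id, rows$patient_id)] <- 1
    M
  })
  names(X) <- as.character(months)
  JointCohort(catalog, X, labels = labels)
}

#' Write a cohort to disk
#'
#' Inverse of \code{\link{readCohort}}: \code{readCohort(writeCohort(c))}
#' reproduces \code{c} in either dialect. Visits at which a patient was not
#' assessed are omitted entirely, never zero-filled.
#'
#' @param cohort a \linkS4class{JointCohort}.
#' @param path output file.
#' @param dialect \code{"wide_csv"} or \code{"long_tsv"}.
#' @export
writeCohort <- function(cohort, path, dialect = c("wide_csv", "long_tsv")) {
  dialect <- match.arg(dialect)
  ids <- jointIds(cohort@catalog)
  if (dialect == "wide_csv") {
    rows <- list()
    for (i in seq_along(cohort@visits)) {
      M <- cohort@X[[i]]
      if (!ncol(M)) next
      df <- data.frame(patient_id = colnames(M),
                       visit_month = cohort@visits[i],
                       t(M), check.names = FALSE,
                       stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- df
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$patient_id, out$visit_month), , drop = FALSE]
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    rec <- list()
    for (i in seq_along(cohort@visits)) {
      M <- cohort@X[[i]]
      for (p in colnames(M)) {
        act <- ids[M[, p] == 1]
        if (!length(act)) act <- .LONG_ZERO
        rec[[length(rec) + 1L]] <- data.frame(
          patient_id = p, visit_month = cohort@visits[i], joint_id = act,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rec)
    out <- out[order(out$patient_id, out$visit_month, out$joint_id), ]
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
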