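#' Accessors for JointCatalog
#'
#' @param catalog a \linkS4class{JointCatalog}.
#' @return \code{jointIds}: character vector of joint identifiers in catalog
#'   order. \code{jointTable}: the underlying data.frame. \code{nJoints}:
#'   integer count.
#' @export
jointIds <- function(catalog) catalog@joints$joint_id

#' @rdname jointIds
#' @export
jointTable <- function(catalog) catalog@joints

#' @rdname jointIds
#' @export
nJoints <- function(catalog) nrow(catalog@joints)

setMethod("show", "JointCatalog", function(object) {
  j <- object@joints
  cat("JointCatalog with", nrow(j), "joints,",
      length(unique(j$joint_type)), "joint types (",
      sum(j$side == "midline"), "midline )\n")
})

#' Build a JointCatalog from a joint table
#'
#' @param joints data.frame with columns \code{joint_id}, \code{label},
#'   \code{side}, \code{joint_type}, \code{axis_rank}.
#' @return a validated \linkS4class{JointCatalog}.
#' @export
JointCatalog <- function(joints) {
  joints <- as.data.frame(joints, stringsAsFactors = FALSE)
  joints$joint_id <- as.character(joints$joint_id)
  rownames(joints) <- NULL
  new("JointCatalog", joints = joints)
}

## One row per site of a bilateral pair.
.pair_rows <- function(type, label, rank) {
  data.frame(
    joint_id   = paste0(type, c("_l", "_r")),
    label      = paste(c("Left", "Right"), label),
    side       = c("left", "right"),
    joint_type = type,
    axis_rank  = rank,
    stringsAsFactors = FALSE
  )
}

#' The default 71-joint homunculus catalog
#'
#' The standard homunculus of assessable joints used in pediatric arthritis
#' cohorts: the cervical spine (midline) plus 35 bilateral joint types --
#' temporomandibular, sternoclavicular, shoulder, elbow, wrist, finger MCPs
#' 1-5, thumb IP, finger PIPs 2-5, finger DIPs 2-5, sacroiliac, hip, knee,
#' ankle, subtalar, midfoot, MTPs 1-5 and toe IPs 1-5 -- for 71 sites in
#' total. The main text does not enumerate the sites one by one, so the
#' catalog is reconstructed from the standard homunculus figure axis labels;
#' supply your own table through \code{\link{loadCatalog}} to override it.
#'
#' @return a \linkS4class{JointCatalog} of 71 joints.
#' @export
defaultCatalog <- function() {
  rows <- list(
    data.frame(joint_id = "cervical_spine", label = "Cervical spine",
               side = "midline", joint_type = "cervical_spine",
               axis_rank = 0L, stringsAsFactors = FALSE),
    .pair_rows("tmj", "TMJ", 1L),
    .pair_rows("sternoclavicular", "sternoclavicular", 2L),
    .pair_rows("shoulder", "shoulder", 3L),
    .pair_rows("elbow", "elbow", 4L),
    .pair_rows("wrist", "wrist", 5L)
  )
  for (i in 1:5)
    rows <- c(rows, list(.pair_rows(paste0("mcp", i), paste("MCP", i), 6L)))
  rows <- c(rows, list(.pair_rows("thumb_ip", "thumb IP", 7L)))
  for (i in 2:5)
    rows <- c(rows, list(.pair_rows(paste0("pip", i), paste("finger PIP", i), 7L)))
  for (i in 2:5)
    rows <- c(rows, list(.pair_rows(paste0("dip", i), paste("finger DIP", i), 8L)))
  rows <- c(rows, list(
    .pair_rows("sacroiliac", "sacroiliac", 9L),
    .pair_rows("hip", "hip", 10L),
    .pair_rows("knee", "knee", 11L),
    .pair_rows("ankle", "ankle", 12L),
    .pair_rows("subtalar", "subtalar", 13L),
    .pair_rows("midfoot", "midfoot", 14L)
  ))
  for (i in 1:5)
    rows <- c(rows, list(.pair_rows(paste0("mtp", i), paste("MTP", i), 15L)))
  for (i in 1:5)
    rows <- c(rows, list(.pair_rows(paste0("toe_ip", i), paste("toe IP", i), 16L)))
  JointCatalog(do.call(rbind, rows))
}

#' Load a joint catalog from a TSV file or the built-in default
#'
#' The file format is tab-separated with header
#' \code{joint_id  label  side  joint_type  axis_rank}. Passing the sentinel
#' \code{"default"} returns \code{\link{defaultCatalog}}.
#'
#' @param path path to a catalog TSV, or \code{"default"}.
#' @return a validated \linkS4class{JointCatalog}.
#' @export
loadCatalog <- function(path = "default") {
  if (identical(path, "default")) return(defaultCatalog())
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  JointCatalog(tab)
}

#' Write a catalog to the TSV dialect read by loadCatalog
#'
#' @param catalog a \linkS4class{JointCatalog}.
#' @param path output file path.
#' @export
writeCatalog <- function(catalog, path) {
  utils::write.table(catalog@joints, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

## joint ids of the contralateral partner, NA for midline
.partner_ids <- function(catalog) {
  j <- catalog@joints
  out <- rep(NA_character_, nrow(j))
  for (i in seq_len(nrow(j))) {
    if (j$side[i] == "midline") next
    out[i] <- j$joint_id[j$joint_type == j$joint_type[i] &
                         j$joint_id != j$joint_id[i]]
  }
  names(out) <- j$joint_id
  out
}

## bilateral joint types with their left/right member ids
.bilateral_types <- function(catalog) {
  j <- catalog@joints
  types <- unique(j$joint_type[j$side != "midline"])
  lapply(stats::setNames(types, types), function(tp) {
    c(left  = j$joint_id[j$joint_type == tp & j$side == "left"],
      right = j$joint_id[j$joint_type == tp & j$side == "right"])
  })
}
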