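#' @import methods
NULL

#' JointCatalog: the site vocabulary of assessable joints
#'
#' A validated table of joint sites: identifier, human-readable label,
#' body side (\code{left}, \code{right} or \code{midline}), the joint type
#' (the left/right pair of corresponding joints, e.g. both knees share type
#' \code{"knee"}), and an integer rank ordering sites along the vertical
#' body axis (0 = most cranial).
#'
#' Validity requires unique identifiers, and that the non-midline joints of
#' each type form exactly one left/right pair. Midline sites (e.g. the
#' cervical spine) are their own type.
#'
#' @slot joints data.frame with columns \code{joint_id}, \code{label},
#'   \code{side}, \code{joint_type}, \code{axis_rank}.
#' @export
setClass("JointCatalog", representation(joints = "data.frame"))

setValidity("JointCatalog", function(object) {
  j <- object@joints
  req <- c("joint_id", "label", "side", "joint_type", "axis_rank")
  if (!all(req %in% names(j)))
    return(paste("missing columns:", paste(setdiff(req, names(j)), collapse = ", ")))
  if (anyDuplicated(j$joint_id))
    return(paste("duplicate joint_id:",
                 paste(unique(j$joint_id[duplicated(j$joint_id)]), collapse = ", ")))
  if (!all(j$side %in% c("left", "right", "midline")))
    return("side must be one of left/right/midline")
  if (any(j$axis_rank < 0) || any(j$axis_rank != round(j$axis_rank)))
    return("axis_rank must be a non-negative integer")
  bad <- character(0)
  for (tp in unique(j$joint_type)) {
    sides <- j$side[j$joint_type == tp]
    if (any(sides == "midline")) {
      if (length(sides) != 1L) bad <- c(bad, tp)
    } else if (!(sum(sides == "left") == 1L && sum(sides == "right") == 1L &&
                 length(sides) == 2L)) {
      bad <- c(bad, tp)
    }
  }
  if (length(bad))
    return(paste("joint types without exactly one left/right pair:",
                 paste(bad, collapse = ", ")))
  TRUE
})

#' JointCohort: per-visit binary involvement matrices
#'
#' Holds one joints-by-patients 0/1 matrix per visit. Visits are labelled by
#' months from baseline; a patient absent from a visit's matrix is missing at
#' that visit (missingness is encoded by absence, never by a zero-filled
#' column). Every patient must appear at baseline with at least one active
#' joint, since enrollment requires arthritis.
#'
#' @slot catalog a \linkS4class{JointCatalog}.
#' @slot patients character vector of patient identifiers.
#' @slot visits integer vector of months from baseline, strictly increasing,
#'   starting at 0 (baseline).
#' @slot X named list of binary matrices (joints x patients), one per visit,
#'   names \code{as.character(visits)}; columns are a subset of
#'   \code{patients}.
#' @slot labels optional named character vector of per-patient labels
#'   (e.g. ILAR subtype); zero-length when absent.
#' @export
setClass("JointCohort", representation(
  catalog  = "JointCatalog",
  patients = "character",
  visits   = "integer",
  X        = "list",
  labels   = "character"
))

setValidity("JointCohort", function(object) {
  v <- object@visits
  if (length(v) < 1L || v[1] != 0L) return("visits must start at baseline month 0")
  if (is.unsorted(v, strictly = TRUE)) return("visit months must be strictly increasing")
  if (!identical(names(object@X), as.character(v)))
    return("names(X) must equal as.character(visits)")
  ids <- jointIds(object@catalog)
  for (nm in names(object@X)) {
    M <- object@X[[nm]]
    if (!is.matrix(M)) return(paste0("X[['", nm, "']] is not a matrix"))
    if (!identical(rownames(M), ids))
      return(paste0("X[['", nm, "']] rows must match catalog joint ids"))
    if (length(M) && !all(M %in% c(0, 1)))
      return(paste0("X[['", nm, "']] has non-binary entries"))
    if (anyDuplicated(colnames(M)))
      return(paste0("X[['", nm, "']] has duplicated patient columns"))
    if (!all(colnames(M) %in% object@patients))
      return(paste0("X[['", nm, "']] has unknown patients"))
  }
  base <- object@X[["0"]]
  if (!setequal(colnames(base), object@patients))
    return("every patient must be present at baseline")
  if (ncol(base) && any(colSums(base) < 1))
    return(paste("baseline patients with no active joint:",
                 paste(colnames(base)[colSums(base) < 1], collapse = ", ")))
  if (length(object@labels) &&
      !all(names(object@labels) %in% object@patients))
    return("labels name unknown patients")
  TRUE
})

#' FactorModel: a single non-negative factorization layer
#'
#' The result of fitting \code{X ~ W H} with non-negative \code{W}
#' (features x factors; loadings) and \code{H} (factors x patients; scores).
#' Columns of \code{W} are normalized to unit maximum so loadings read as
#' 0--100\% contributions; the per-factor normalizing constants are kept in
#' \code{scale} and the compensation is folded into \code{H}.
#'
#' @slot W,H non-negative matrices.
#' @slot k integer rank.
#' @slot alpha L1 penalty weight on \code{W}.
#' @slot scale numeric per-factor column scales removed from \code{W}.
#' @slot sparsifyThreshold fraction of a column's maximum below which
#'   loadings were zeroed (0 when the model is unsparsified).
#' @slot sparsified logical.
#' @slot scoreCor per-factor Spearman correlation between pre- and
#'   post-sparsification patient scores (NA when unsparsified).
#' @slot converged logical.
#' @slot objectiveTrace per-iteration penalized objective of the winning
#'   restart.
#' @slot seed integer seed that produced the winning restart.
#' @export
setClass("FactorModel", representation(
  W = "matrix", H = "matrix", k = "integer", alpha = "numeric",
  scale = "numeric", sparsifyThreshold = "numeric", sparsified = "logical",
  scoreCor = "numeric", converged = "logical", objectiveTrace = "numeric",
  seed = "integer"
))

setValidity("FactorModel", function(object) {
  if (any(object@W < 0) || any(object@H < 0)) return("W and H must be non-negative")
  if (ncol(object@W) != object@k || nrow(object@H) != object@k)
    return("rank inconsistent with W/H dimensions")
  if (object@alpha < 0) return("alpha must be >= 0")
  TRUE
})

#' MultilayerModel: two composed factorization layers
#'
#' Layer 1 factorizes the joints-by-patients matrix into low-level factors
#' (tight joint groupings); layer 2 factorizes the (rescaled) low-level
#' score matrix into high-level factors (groupings of groupings). The
#' composite loading \code{C = W1_sparse \%*\% W2_sparse}, column-normalized
#' to unit maximum, maps high-level factors back onto joints; the key joints
#' of a high-level factor are the joints with strictly positive composite
#' loading.
#'
#' @slot layer1,layer2 sparsified \linkS4class{FactorModel}s.
#' @slot composite joints x k2 matrix, columns normalized to unit maximum.
#' @slot keyJoints named list: per high-level factor, the character vector of
#'   key joint ids.
#' @slot h1RowScale per-low-level-factor scale applied to layer-1 scores
#'   before layer-2 fitting (each score row rescaled to unit maximum);
#'   frozen for projection.
#' @slot jointIds feature space of layer 1.
#' @export
setClass("MultilayerModel", representation(
  layer1 = "FactorModel", layer2 = "FactorModel",
  composite = "matrix", keyJoints = "list", h1RowScale = "numeric",
  jointIds = "character"
))

setValidity("MultilayerModel", function(object) {
  if (any(object@composite < 0)) return("composite must be non-negative")
  if (length(object@keyJoints) != ncol(object@composite))
    return("one key-joint set per high-level factor required")
  if (any(!lengths(object@keyJoints)))
    return("every high-level factor must have a nonempty key-joint set")
  TRUE
})

#' GroupAssignment: mixed-membership scores and hard group labels
#'
#' @slot scores k2 x patients matrix of high-level factor scores.
#' @slot group character per-patient assigned group (the highest-scoring
#'   factor; ties broken towards the lowest factor index; all-zero score
#'   vectors get the reserved group \code{"unscored"}).
#' @slot tie logical per-patient tie flag.
#' @export
setClass("GroupAssignment", representation(
  scores = "matrix", group = "character", tie = "logical"
))

setValidity("GroupAssignment", function(object) {
  n <- ncol(object@scores)
  if (length(object@group) != n || length(object@tie) != n)
    return("group/tie length must equal number of patients")
  TRUE
})

#' BiCVGrid: bi-cross-validation results over a (rank, alpha) grid
#'
#' @slot grid data.frame with columns \code{k}, \code{alpha},
#'   \code{replicate}, \code{q2}.
#' @slot folds,replicates,seed integers.
#' @export
setClass("BiCVGrid", representation(
  grid = "data.frame", folds = "integer", replicates = "integer",
  seed = "integer"
))

setValidity("BiCVGrid", function(object) {
  if (object@folds < 2L) return("folds must be >= 2")
  if (object@replicates < 1L) return("replicates must be >= 1")
  if (!all(c("k", "alpha", "replicate", "q2") %in% names(object@grid)))
    return("grid must have columns k, alpha, replicate, q2")
  if (any(!is.finite(object@grid$q2))) return("q2 entries must be finite")
  TRUE
})

#' PlantedModel: ground-truth generative model for synthetic cohorts
#'
#' @slot catalog a \linkS4class{JointCatalog}.
#' @slot lowSupports list of character vectors: joint ids per low-level
#'   factor (bilateral pairs / small vertical neighborhoods).
#' @slot highSupports list of integer vectors: low-level factor indices per
#'   high-level pattern.
#' @slot groupWeights probability per high-level pattern (sums to 1).
#' @slot noiseRate per-joint symmetric flip probability.
#' @slot localizationMix target proportions (localized, partial, extended).
#' @slot resolutionHazard matrix (k2 x 3): per-visit probability that an
#'   active joint resolves, by (group, localization category).
#' @slot bilateralCoupling probability that the contralateral partner of an
#'   activated key joint is activated with it.
#' @slot keyActivation probability that each key joint pair of the drawn
#'   pattern is activated at baseline.
#' @slot seed integer.
#' @export
setClass("PlantedModel", representation(
  catalog = "JointCatalog", lowSupports = "list", highSupports = "list",
  groupWeights = "numeric", noiseRate = "numeric",
  localizationMix = "numeric", resolutionHazard = "matrix",
  bilateralCoupling = "numeric", keyActivation = "numeric", seed = "integer"
))

setValidity("PlantedModel", function(object) {
  if (any(!lengths(object@lowSupports))) return("empty low-level support")
  if (any(!lengths(object@highSupports))) return("empty high-level support")
  if (abs(sum(object@groupWeights) - 1) > 1e-8) return("groupWeights must sum to 1")
  rates <- c(object@noiseRate, object@localizationMix, object@resolutionHazard,
             object@bilateralCoupling, object@keyActivation)
  if (any(rates < 0 | rates > 1)) return("all rates must lie in [0,1]")
  if (abs(sum(object@localizationMix) - 1) > 1e-8)
    return("localizationMix must sum to 1")
  TRUE
})
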