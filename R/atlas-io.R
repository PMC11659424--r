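#' @useDynLib metconn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor quantile rnorm rlnorm runif rbinom sd var coef predict setNames
#' @importFrom utils read.csv write.csv head
NULL

GROUP_LEVELS <- c("CTRL", "nTRS", "TRS")
OPTIONAL_COVARIATES <- c("age", "sex", "education", "duration", "onset")

#' Construct a validated region atlas
#'
#' A region atlas carries the identity and grouping metadata of every volume
#' of interest (VOI): a unique id, a display name, hemisphere, an anatomical
#' module label (lobe-level community used for colouring and community average
#' degree), and membership flags for the two a-priori subnetworks considered
#' throughout the package — the default mode network (DMN) and the dorsal
#' dopamine pathway (DDP).
#'
#' @param df data.frame with columns `region_id`, `name`, `hemisphere`
#'   (one of `"L"`, `"R"`, `"bilateral"`), `module_label`, `in_dmn`, `in_ddp`
#'   (logical or 0/1).
#' @return A `region_atlas` object (a validated data.frame). Row order is
#'   canonical: every matrix produced downstream uses this region order.
#' @export
region_atlas <- function(df) {
  required <- c("region_id", "name", "hemisphere", "module_label", "in_dmn", "in_ddp")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("atlas is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) < 2) stop("atlas must contain at least 2 regions")
  df$region_id <- as.character(df$region_id)
  dup <- df$region_id[duplicated(df$region_id)]
  if (length(dup) > 0) {
    stop("duplicate region_id in atlas: ", paste(unique(dup), collapse = ", "))
  }
  bad_hemi <- setdiff(unique(df$hemisphere), c("L", "R", "bilateral"))
  if (length(bad_hemi) > 0) {
    stop("invalid hemisphere value(s): ", paste(bad_hemi, collapse = ", "))
  }
  for (fl in c("in_dmn", "in_ddp")) {
    v <- df[[fl]]
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1))) stop(fl, " must be logical or 0/1")
      v <- v == 1
    }
    if (!is.logical(v) || anyNA(v)) stop(fl, " must be logical or 0/1 with no missing values")
    df[[fl]] <- v
  }
  df <- df[, required]
  rownames(df) <- NULL
  class(df) <- c("region_atlas", "data.frame")
  df
}

#' Read a region atlas from CSV
#'
#' @param path CSV file with columns
#'   `region_id,name,hemisphere,module_label,in_dmn,in_ddp` (flags as 0/1).
#' @return A [region_atlas()] with file row order preserved as the canonical
#'   region order.
#' @export
load_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file does not exist: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("atlas file is empty: ", path)
  region_atlas(df)
}

#' Construct an uptake study
#'
#' The central data container: an n-subjects x p-regions matrix of mean
#' FDG uptake per VOI, plus per-subject metadata (group label,
#' chlorpromazine-equivalent dose, optional clinical covariates) and the
#' region atlas. `normalized` records whether per-subject global-mean
#' normalization has been applied.
#'
#' @param values numeric matrix, subjects x regions; columns must align with
#'   `atlas$region_id`.
#' @param subjects data.frame with columns `subject_id`, `group`
#'   (CTRL/nTRS/TRS), `cpz_equiv`, and optionally
#'   `age`, `sex`, `education`, `duration`, `onset`.
#' @param atlas a [region_atlas()].
#' @param normalized logical flag.
#' @param allow_zero_dose_patients permit `cpz_equiv = 0` outside CTRL.
#' @return An `uptake_study` object.
#' @export
uptake_study <- function(values, subjects, atlas, normalized = FALSE,
                         allow_zero_dose_patients = FALSE) {
  stopifnot(inherits(atlas, "region_atlas"))
  values <- as.matrix(values)
  if (ncol(values) != nrow(atlas)) {
    stop("values has ", ncol(values), " columns but atlas has ", nrow(atlas), " regions")
  }
  if (nrow(values) != nrow(subjects)) {
    stop("values has ", nrow(values), " rows but subjects has ", nrow(subjects))
  }
  if (anyNA(values)) stop("uptake values contain missing entries")
  if (!normalized && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive uptake value for subject '", subjects$subject_id[bad[1]],
         "', region '", atlas$region_id[bad[2]], "'")
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject_id")
  bad_grp <- setdiff(unique(as.character(subjects$group)), GROUP_LEVELS)
  if (length(bad_grp) > 0) {
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "),
         " (expected ", paste(GROUP_LEVELS, collapse = "/"), ")")
  }
  subjects$group <- as.character(subjects$group)
  if (is.null(subjects$cpz_equiv)) stop("subjects must carry a cpz_equiv column")
  if (any(subjects$cpz_equiv < 0)) stop("cpz_equiv must be non-negative")
  if (!allow_zero_dose_patients &&
      any(subjects$cpz_equiv == 0 & subjects$group != "CTRL")) {
    stop("cpz_equiv = 0 found for non-CTRL subject(s); ",
         "set allow_zero_dose_patients = TRUE to permit this")
  }
  dimnames(values) <- list(subjects$subject_id, atlas$region_id)
  rownames(subjects) <- NULL
  structure(list(values = values, subjects = subjects, atlas = atlas,
                 normalized = isTRUE(normalized)),
            class = "uptake_study")
}

#' Read a subject-by-region uptake table
#'
#' @param path CSV with columns `subject_id,group,cpz_equiv` (optionally
#'   `age,sex,education,duration,onset`) followed by one column per atlas
#'   `region_id`. Extra columns are ignored with a warning; region column
#'   order in the file is irrelevant (columns are re-aligned to atlas order).
#' @param atlas a [region_atlas()].
#' @inheritParams uptake_study
#' @return An [uptake_study()] with `normalized = FALSE`.
#' @export
load_uptake_table <- function(path, atlas, allow_zero_dose_patients = FALSE) {
  if (!file.exists(path)) stop("uptake file does not exist: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "group", "cpz_equiv")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("uptake table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  missing_regions <- setdiff(atlas$region_id, names(df))
  if (length(missing_regions) > 0) {
    stop("uptake table is missing region column(s): ",
         paste(head(missing_regions, 5), collapse = ", "),
         if (length(missing_regions) > 5) ", ...")
  }
  meta_cols <- c(required, intersect(OPTIONAL_COVARIATES, names(df)))
  extra <- setdiff(names(df), c(meta_cols, atlas$region_id))
  if (length(extra) > 0) {
    warning("ignoring unused column(s): ", paste(extra, collapse = ", "))
  }
  values <- as.matrix(df[, atlas$region_id, drop = FALSE])
  storage.mode(values) <- "double"
  uptake_study(values, df[, meta_cols, drop = FALSE], atlas,
               normalized = FALSE,
               allow_zero_dose_patients = allow_zero_dose_patients)
}

#' Write an uptake study back to CSV
#'
#' Inverse of [load_uptake_table()]; the values matrix round-trips exactly
#' (full double precision).
#'
#' @param study an [uptake_study()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_uptake_table <- function(study, path) {
  stopifnot(inherits(study, "uptake_study"))
  df <- cbind(study$subjects, as.data.frame(study$values, check.names = FALSE))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize uptake to the per-subject global mean
#'
#' Each subject's row is divided by its own mean over all atlas regions (the
#' region-level proxy for the "global gray matter average"), removing the
#' subject-specific global scaling of uptake. Afterwards every row has mean
#' exactly 1. Calling this twice is a state error: the transform is
#' deliberately not idempotent-silent, since double-normalizing signals a
#' pipeline bug.
#'
#' @param study an unnormalized [uptake_study()].
#' @return The normalized study (`normalized = TRUE`).
#' @export
normalize_global_mean <- function(study) {
  stopifnot(inherits(study, "uptake_study"))
  if (study$normalized) stop("study is already normalized")
  gm <- rowMeans(study$values)
  study$values <- study$values / gm
  study$normalized <- TRUE
  study
}

#' Slice a study by group and/or regions
#'
#' @param study an [uptake_study()].
#' @param group optional group label (CTRL/nTRS/TRS) or vector of labels.
#' @param regions optional character vector of region ids (atlas order is
#'   preserved regardless of the order given).
#' @return The sliced [uptake_study()]; the atlas is sliced consistently.
#' @export
subset_study <- function(study, group = NULL, regions = NULL) {
  stopifnot(inherits(study, "uptake_study"))
  keep_subj <- rep(TRUE, nrow(study$subjects))
  if (!is.null(group)) {
    bad <- setdiff(group, GROUP_LEVELS)
    if (length(bad) > 0) stop("unknown group label(s): ", paste(bad, collapse = ", "))
    keep_subj <- study$subjects$group %in% group
    if (!any(keep_subj)) stop("no subjects in group(s): ", paste(group, collapse = ", "))
  }
  keep_reg <- rep(TRUE, nrow(study$atlas))
  if (!is.null(regions)) {
    bad <- setdiff(regions, study$atlas$region_id)
    if (length(bad) > 0) stop("unknown region id(s): ", paste(bad, collapse = ", "))
    keep_reg <- study$atlas$region_id %in% regions
    if (!any(keep_reg)) stop("empty region selection")
  }
  atlas <- study$atlas[keep_reg, , drop = FALSE]
  rownames(atlas) <- NULL
  class(atlas) <- c("region_atlas", "data.frame")
  subjects <- study$subjects[keep_subj, , drop = FALSE]
  rownames(subjects) <- NULL
  structure(list(values = study$values[keep_subj, keep_reg, drop = FALSE],
                 subjects = subjects, atlas = atlas,
                 normalized = study$normalized),
            class = "uptake_study")
}

#' Region ids flagged as belonging to a named subnetwork
#'
#' @param atlas a [region_atlas()].
#' @param subnetwork `"dmn"` or `"ddp"`.
#' @return Character vector of region ids.
#' @export
subnetwork_regions <- function(atlas, subnetwork = c("dmn", "ddp")) {
  subnetwork <- match.arg(subnetwork)
  flag <- if (subnetwork == "dmn") atlas$in_dmn else atlas$in_ddp
  atlas$region_id[flag]
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("<region_atlas> ", nrow(x), " regions, ",
      length(unique(x$module_label)), " modules; DMN ", sum(x$in_dmn),
      ", DDP ", sum(x$in_ddp), "\n", sep = "")
  invisible(x)
}

#' @export
print.uptake_study <- function(x, ...) {
  tab <- table(factor(x$subjects$group, levels = GROUP_LEVELS))
  cat("<uptake_study> ", nrow(x$values), " subjects x ", ncol(x$values),
      " regions (", paste(names(tab), tab, sep = "=", collapse = ", "),
      "); normalized=", x$normalized, "\n", sep = "")
  invisible(x)
}
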