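#' Built-in 65-region synthetic atlas
#'
#' A programmatically constructed stand-in for a lobe-merged AAL-style
#' parcellation: 65 VOIs organised into seven anatomical modules (frontal,
#' limbic, temporal, parietal, occipital, subcortical, cerebellum) with
#' default-mode-network (DMN) and dorsal-dopamine-pathway (DDP) membership
#' flags. Region names follow common anatomical nomenclature but the table is
#' synthetic: it ships no coordinates and is meant for simulation and testing,
#' not spatial analysis.
#'
#' @return A [region_atlas()] with 65 rows.
#' @export
example_atlas <- function() {
  pair <- function(base, module, dmn = FALSE, ddp = FALSE) {
    data.frame(region_id = paste0(base, c("_L", "_R")),
               name = paste(gsub("_", " ", base), c("left", "right")),
               hemisphere = c("L", "R"), module_label = module,
               in_dmn = dmn, in_ddp = ddp, stringsAsFactors = FALSE)
  }
  df <- rbind(
    pair("precentral", "frontal", ddp = TRUE),
    pair("frontal_sup", "frontal", dmn = TRUE),
    pair("frontal_mid", "frontal"),
    pair("frontal_inf", "frontal"),
    pair("rolandic_oper", "frontal"),
    pair("supp_motor_area", "frontal", ddp = TRUE),
    pair("rectus", "frontal"),
    pair("cingulate_ant", "limbic", dmn = TRUE),
    pair("cingulate_mid", "limbic"),
    pair("cingulate_post", "limbic", dmn = TRUE),
    pair("hippocampus", "limbic", dmn = TRUE),
    pair("amygdala", "limbic"),
    pair("insula", "limbic"),
    pair("temporal_sup", "temporal"),
    pair("temporal_mid", "temporal", dmn = TRUE),
    pair("heschl", "temporal"),
    pair("fusiform", "temporal"),
    pair("postcentral", "parietal", ddp = TRUE),
    pair("parietal_sup", "parietal"),
    pair("supramarginal", "parietal"),
    pair("angular", "parietal", dmn = TRUE),
    pair("precuneus", "parietal", dmn = TRUE),
    pair("calcarine", "occipital"),
    pair("cuneus", "occipital"),
    pair("lingual", "occipital"),
    pair("occipital_mid", "occipital"),
    pair("caudate", "subcortical", ddp = TRUE),
    pair("putamen", "subcortical", ddp = TRUE),
    pair("pallidum", "subcortical", ddp = TRUE),
    pair("thalamus", "subcortical"),
    pair("cerebellum_crus", "cerebellum"),
    pair("cerebellum_lob", "cerebellum"),
    data.frame(region_id = "vermis", name = "cerebellar vermis",
               hemisphere = "bilateral", module_label = "cerebellum",
               in_dmn = FALSE, in_ddp = FALSE, stringsAsFactors = FALSE))
  region_atlas(df)
}

#' Generic synthetic atlas of arbitrary size
#'
#' For small-scale simulation tests. Regions are split into contiguous
#' modules; the first module is flagged DMN and the second (if any) DDP.
#'
#' @param p number of regions (>= 2).
#' @param module_sizes integer vector summing to `p`; default splits `p` into
#'   modules of size at most 5.
#' @return A [region_atlas()].
#' @export
synthetic_atlas <- function(p, module_sizes = NULL) {
  if (is.null(module_sizes)) {
    k <- max(1L, ceiling(p / 5))
    module_sizes <- rep(p %/% k, k)
    if (p %% k > 0) module_sizes[seq_len(p %% k)] <- module_sizes[seq_len(p %% k)] + 1L
  }
  if (sum(module_sizes) != p) stop("module_sizes must sum to p")
  module <- rep(paste0("M", seq_along(module_sizes)), module_sizes)
  region_atlas(data.frame(
    region_id = sprintf("region_%03d", seq_len(p)),
    name = sprintf("synthetic region %d", seq_len(p)),
    hemisphere = rep(c("L", "R"), length.out = p),
    module_label = module,
    in_dmn = module == "M1",
    in_ddp = module == "M2" & length(module_sizes) > 1,
    stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Defaults mirror the emulated study design: 16 controls, 28
#' antipsychotic-responsive (nTRS) and 26 treatment-resistant (TRS) patients
#' over 65 regions; within-module partial correlations of 0.3; patient
#' hypoconnectivity implanted as attenuation of DMN/DDP/frontal edges; a
#' right-skewed lognormal chlorpromazine-equivalent dose
#' (meanlog 5.5, sdlog 0.5, i.e. median ~245 mg/day); per-subject global
#' scaling with sd 0.1 that the normalization step must remove.
#'
#' @param n_per_group named integer vector (CTRL/nTRS/TRS sample sizes).
#' @param p number of regions.
#' @param within_module_partial target partial correlation on within-module
#'   edges (before any positive-definiteness diagonal inflation).
#' @param patient_edge_attenuation multiplier `1 - a` applied to designated
#'   DMN/DDP/frontal edges in patient groups; `a` in `[0, 1]`.
#' @param connect_subnetworks also implant edges between DMN regions (and DDP
#'   regions) that sit in different anatomical modules, so the functional
#'   subnetworks are coherent structures rather than fragments of lobes.
#' @param dose_confounder list: `enabled`, `target_regions` (region ids; NULL
#'   = first two DDP regions), `effect_size` (uptake shift per SD of dose),
#'   `meanlog`, `sdlog` of the lognormal dose; optionally `meanlog_by_group`,
#'   a named list overriding `meanlog` per patient group (to simulate groups
#'   that differ only in medication load).
#' @param global_scale_sd sd of the per-subject multiplicative global factor.
#' @param seed integer RNG seed.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_per_group = c(CTRL = 16, nTRS = 28, TRS = 26),
                              p = 65,
                              within_module_partial = 0.3,
                              patient_edge_attenuation = 0.4,
                              connect_subnetworks = TRUE,
                              dose_confounder = list(enabled = FALSE,
                                                     target_regions = NULL,
                                                     effect_size = 0.5,
                                                     meanlog = 5.5, sdlog = 0.5),
                              global_scale_sd = 0.1,
                              seed = 1L) {
  stopifnot(p >= 2, all(n_per_group >= 3),
            patient_edge_attenuation >= 0, patient_edge_attenuation <= 1,
            global_scale_sd >= 0)
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% GROUP_LEVELS)) {
    stop("n_per_group must be named with group labels ",
         paste(GROUP_LEVELS, collapse = "/"))
  }
  dc <- utils::modifyList(list(enabled = FALSE, target_regions = NULL,
                               effect_size = 0.5, meanlog = 5.5, sdlog = 0.5,
                               meanlog_by_group = NULL),
                          dose_confounder)
  structure(list(n_per_group = n_per_group, p = p,
                 within_module_partial = within_module_partial,
                 patient_edge_attenuation = patient_edge_attenuation,
                 connect_subnetworks = isTRUE(connect_subnetworks),
                 dose_confounder = dc,
                 global_scale_sd = global_scale_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Construct a ground-truth sparse precision matrix for one group
#'
#' Builds a modular precision matrix: unit diagonal, off-diagonal `-r` for
#' every within-module pair (the `within_module_partial` value), optionally also for
#' cross-module pairs within the DMN and within the DDP. For patient groups
#' (nTRS/TRS) the designated DMN/DDP/frontal edges are multiplied by
#' `1 - patient_edge_attenuation`. The diagonal is then inflated to strict
#' diagonal dominance (`theta_ii = max(1, 1.05 * sum_j |theta_ij|)`) so the
#' matrix is guaranteed positive definite; the true partial correlations are
#' recomputed exactly from the final matrix (they equal `r` only when no
#' inflation was needed, e.g. small modules).
#'
#' @param atlas a [region_atlas()].
#' @param config a [simulation_config()].
#' @param group group label; attenuation applies when not `"CTRL"`.
#' @return A `precision_spec`: list with `group`, `precision`, `true_partial`,
#'   `true_edges` (two-column matrix of region ids, lower id first by atlas
#'   order) and the `atlas`.
#' @export
build_ground_truth_precision <- function(atlas, config, group) {
  stopifnot(inherits(atlas, "region_atlas"), inherits(config, "sim_config"))
  if (!group %in% GROUP_LEVELS) stop("unknown group label: ", group)
  p <- nrow(atlas)
  if (p != config$p) stop("atlas has ", p, " regions but config$p = ", config$p)
  r <- config$within_module_partial
  ids <- atlas$region_id

  theta <- diag(p)
  same_module <- outer(atlas$module_label, atlas$module_label, "==")
  support <- same_module
  if (config$connect_subnetworks) {
    support <- support | outer(atlas$in_dmn, atlas$in_dmn, "&") |
      outer(atlas$in_ddp, atlas$in_ddp, "&")
  }
  diag(support) <- FALSE
  theta[support] <- -r

  if (group != "CTRL" && config$patient_edge_attenuation > 0) {
    is_frontal <- grepl("frontal", atlas$module_label, ignore.case = TRUE) |
      atlas$module_label == "M1"  # generic-atlas stand-in for the frontal module
    designated <- outer(atlas$in_dmn, atlas$in_dmn, "&") |
      outer(atlas$in_ddp, atlas$in_ddp, "&") |
      outer(is_frontal, is_frontal, "&")
    diag(designated) <- FALSE
    att <- designated & support
    theta[att] <- theta[att] * (1 - config$patient_edge_attenuation)
  }

  # diagonal-dominance rescaling; partials recomputed exactly afterwards
  attempts <- 0
  repeat {
    rowsum_off <- rowSums(abs(theta)) - abs(diag(theta))
    diag(theta) <- pmax(diag(theta), 1.05 * rowsum_off, 1)
    ev_min <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min > 1e-8) break
    attempts <- attempts + 1
    if (attempts > 50) {
      stop("could not reach positive definiteness after 50 rescaling attempts; ",
           "reduce within_module_partial")
    }
    diag(theta) <- diag(theta) * 1.1
  }
  dimnames(theta) <- list(ids, ids)

  d <- sqrt(diag(theta))
  partial <- -theta / outer(d, d)
  diag(partial) <- 1

  nz <- which(upper.tri(theta) & abs(theta) > 1e-12, arr.ind = TRUE)
  true_edges <- cbind(ids[nz[, 1]], ids[nz[, 2]])
  colnames(true_edges) <- c("from", "to")

  structure(list(group = group, precision = theta, true_partial = partial,
                 true_edges = true_edges, atlas = atlas),
            class = "precision_spec")
}

#' Simulate a multi-group uptake study from known precision matrices
#'
#' Per subject, a p-vector is drawn from the group's multivariate normal
#' (mean 10, covariance the inverse of the group precision). Doses are drawn
#' for every subject regardless of the confounder switch (patients lognormal,
#' CTRL zero) so that toggling the confounder with `effect_size = 0` leaves
#' the uptake values bit-identical. When the confounder is enabled,
#' `effect_size * standardized(dose)` is added to the target regions. Values
#' are shifted to strict positivity if needed, then every subject row is
#' multiplied by an (accept-reject positive) `N(1, global_scale_sd)` global
#' factor — the nuisance that [normalize_global_mean()] removes.
#'
#' @param specs named list mapping group label to a
#'   [build_ground_truth_precision()] result; all must share the atlas.
#' @param config a [simulation_config()].
#' @return List with `study` (an [uptake_study()], `normalized = FALSE`) and
#'   `truth` (the `specs` passed in). Deterministic given `config$seed`.
#' @export
simulate_study <- function(specs, config) {
  stopifnot(inherits(config, "sim_config"), length(specs) >= 1)
  groups <- intersect(GROUP_LEVELS, names(specs))
  if (length(groups) != length(specs)) stop("specs must be named by group label")
  atlas <- specs[[1]]$atlas
  p <- nrow(atlas)
  for (g in groups) {
    if (!identical(specs[[g]]$atlas$region_id, atlas$region_id)) {
      stop("all precision specs must share the same atlas")
    }
    ev <- min(eigen(specs[[g]]$precision, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("precision for group ", g, " is not positive definite")
  }

  set.seed(config$seed)
  values <- NULL
  subjects <- NULL
  for (g in groups) {
    n <- unname(config$n_per_group[[g]])
    if (is.null(n)) stop("config$n_per_group has no entry for group ", g)
    sigma <- solve(specs[[g]]$precision)
    x <- MASS::mvrnorm(n, mu = rep(10, p), Sigma = sigma)
    ml <- config$dose_confounder$meanlog
    if (!is.null(config$dose_confounder$meanlog_by_group[[g]])) {
      ml <- config$dose_confounder$meanlog_by_group[[g]]
    }
    dose <- if (g == "CTRL") rep(0, n) else
      rlnorm(n, meanlog = ml, sdlog = config$dose_confounder$sdlog)
    age <- round(runif(n, 20, 55))
    sex <- rbinom(n, 1, 0.5)
    education <- pmax(5, round(rnorm(n, 13, 3)))
    duration <- if (g == "CTRL") rep(0, n) else round(runif(n, 2, 20))
    sub <- data.frame(
      subject_id = sprintf("%s_%03d", g, seq_len(n)),
      group = g, cpz_equiv = dose, age = age, sex = sex,
      education = education, duration = duration,
      onset = pmax(16, age - duration), stringsAsFactors = FALSE)
    values <- rbind(values, x)
    subjects <- rbind(subjects, sub)
  }

  if (config$dose_confounder$enabled) {
    targets <- config$dose_confounder$target_regions
    if (is.null(targets)) targets <- head(subnetwork_regions(atlas, "ddp"), 2)
    if (length(targets) == 0) targets <- atlas$region_id[1:2]
    bad <- setdiff(targets, atlas$region_id)
    if (length(bad) > 0) stop("unknown confounder target region(s): ",
                              paste(bad, collapse = ", "))
    dose <- subjects$cpz_equiv
    z <- if (sd(dose) > 0) (dose - mean(dose)) / sd(dose) else dose * 0
    idx <- match(targets, atlas$region_id)
    values[, idx] <- values[, idx] +
      config$dose_confounder$effect_size * z
  }

  if (min(values) <= 0) values <- values + (0.001 - min(values))

  scale_f <- rnorm(nrow(values), mean = 1, sd = config$global_scale_sd)
  while (any(scale_f <= 0)) {
    bad <- scale_f <= 0
    scale_f[bad] <- rnorm(sum(bad), mean = 1, sd = config$global_scale_sd)
  }
  values <- values * scale_f

  study <- uptake_study(values, subjects, atlas, normalized = FALSE,
                        allow_zero_dose_patients = TRUE)
  list(study = study, truth = specs)
}

#' Write a simulated study and its ground truth as a plain-text fixture
#'
#' Writes `atlas.csv` and `uptake.csv` (round-trippable through
#' [load_atlas()] / [load_uptake_table()]) plus `truth.json` holding each
#' group's true edge list and partial-correlation matrix.
#'
#' @param study an [uptake_study()].
#' @param truth named list of `precision_spec`s (as from [simulate_study()]).
#' @param dir output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(study, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  atlas_path <- file.path(dir, "atlas.csv")
  uptake_path <- file.path(dir, "uptake.csv")
  truth_path <- file.path(dir, "truth.json")
  adf <- as.data.frame(study$atlas)
  adf$in_dmn <- as.integer(adf$in_dmn)
  adf$in_ddp <- as.integer(adf$in_ddp)
  write.csv(adf, atlas_path, row.names = FALSE, quote = FALSE)
  write_uptake_table(study, uptake_path)
  tr <- lapply(truth, function(sp) {
    list(edges = unname(sp$true_edges),     # serializes as [[from, to], ...]
         region_ids = sp$atlas$region_id,
         partial = unname(sp$true_partial))
  })
  jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(atlas = atlas_path, uptake = uptake_path, truth = truth_path))
}
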